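# Archive serialization.
#
# Layout inside the container (ZIP file or unpacked directory):
#   archive.xml                      archive-level metadata
#   bibliography.bib                 optional provenance record
#   compounds/compounds.xml          registry XML, one per registry
#   properties/properties.xml, descriptors/descriptors.xml,
#   models/models.xml, predictions/predictions.xml
#   <registry>/<container-id>/<cargo-name>   cargo payloads
#
# The writer is deterministic: fixed entry order (archive.xml, bibliography,
# registries in canonical order, cargos sorted by path) and fixed
# timestamps, so identical archives yield byte-identical files. The reader
# is lenient -- declared-but-missing cargos load as NULL payloads and are
# left for the validator to report.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

xml_elem <- function(tag, text) {
  if (is.null(text)) return(character(0))
  sprintf("    <%s>%s</%s>", tag, xml_escape(as.character(text)), tag)
}

container_xml <- function(cont) {
  lines <- sprintf("  <container id=\"%s\">", cont$id)
  lines <- c(lines, xml_elem("name", cont$name),
             xml_elem("description", cont$description))
  if (length(cont$labels))
    lines <- c(lines, xml_elem("labels", paste(cont$labels, collapse = " ")))
  if (inherits(cont, "qdb_compound")) {
    lines <- c(lines, xml_elem("cas", cont$cas), xml_elem("inchi", cont$inchi))
  } else if (inherits(cont, "qdb_property")) {
    if (!is.null(cont$endpoint_category) || !is.null(cont$endpoint_name))
      lines <- c(lines, sprintf("    <endpoint category=\"%s\" name=\"%s\"/>",
                                xml_escape(cont$endpoint_category %||% ""),
                                xml_escape(cont$endpoint_name %||% "")))
  } else if (inherits(cont, "qdb_descriptor")) {
    lines <- c(lines, xml_elem("application", cont$application))
  } else if (inherits(cont, "qdb_model")) {
    lines <- c(lines, xml_elem("property-ref", cont$property_id))
    for (d in cont$descriptor_ids)
      lines <- c(lines, xml_elem("descriptor-ref", d))
  } else if (inherits(cont, "qdb_prediction")) {
    lines <- c(lines, xml_elem("model-ref", cont$model_id),
               xml_elem("set-kind", cont$set_kind),
               xml_elem("application", cont$application))
  }
  for (nm in names(cont$cargos))
    lines <- c(lines, sprintf("    <cargo name=\"%s\"/>", xml_escape(nm)))
  c(lines, "  </container>")
}

registry_xml <- function(kind, containers) {
  body <- unlist(lapply(containers, container_xml), use.names = FALSE)
  paste0(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           sprintf("<%s>", kind), body, sprintf("</%s>", kind), ""),
         collapse = "\n")
}

archive_xml <- function(archive) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<archive>")
  if (!is.null(archive$name))
    lines <- c(lines, sprintf("  <name>%s</name>", xml_escape(archive$name)))
  if (!is.null(archive$description))
    lines <- c(lines, sprintf("  <description>%s</description>",
                              xml_escape(archive$description)))
  paste0(c(lines, "</archive>", ""), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_bibtex <- function(bib) {
  lines <- sprintf("@%s{%s,", bib$entry_type, bib$key)
  for (nm in names(bib$fields))
    lines <- c(lines, sprintf("  %s = {%s},", nm, bib$fields[[nm]]))
  paste0(c(lines, "}", ""), collapse = "\n")
}

parse_bibtex <- function(text) {
  m <- regmatches(text, regexec("@([A-Za-z]+)\\{([^,[:space:]]+),", text))[[1]]
  if (length(m) != 3)
    qdb_stop("format_error", "unparseable bibliography record")
  field_m <- gregexpr("([A-Za-z]+)[ \t]*=[ \t]*\\{([^}]*)\\}", text)[[1]]
  fields <- list()
  if (field_m[1] != -1) {
    for (i in seq_along(field_m)) {
      frag <- substr(text, field_m[i],
                     field_m[i] + attr(field_m, "match.length")[i] - 1)
      key <- sub("[ \t]*=.*$", "", frag)
      val <- sub("^[^{]*\\{", "", sub("\\}$", "", frag))
      fields[[tolower(key)]] <- val
    }
  }
  bibliography_record(entry_type = m[2], key = m[3], fields = fields)
}

#' Write a QDB archive
#'
#' Serializes an archive to a ZIP container (when `path` ends in `.qdb` or
#' `.zip`) or to an unpacked directory with the same layout. The byte
#' layout is deterministic: writing the same archive twice yields identical
#' files.
#'
#' @param archive a `qdb_archive`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "qdb_archive"))
  for (kind in REGISTRY_KINDS)
    for (cont in archive[[kind]])
      if (!is_valid_id(cont$id))
        qdb_stop("invalid_id", sprintf("invalid container id '%s'", cont$id))
  entries <- list("archive.xml" = archive_xml(archive))
  if (!is.null(archive$bibliography))
    entries[["bibliography.bib"]] <- format_bibtex(archive$bibliography)
  for (kind in REGISTRY_KINDS)
    entries[[sprintf("%s/%s.xml", kind, kind)]] <-
      registry_xml(kind, archive[[kind]])
  cargo_entries <- list()
  for (kind in REGISTRY_KINDS) {
    for (cont in archive[[kind]]) {
      for (nm in names(cont$cargos)) {
        payload <- cont$cargos[[nm]]
        if (is.null(payload)) next  # declared but absent
        cargo_entries[[sprintf("%s/%s/%s", kind, cont$id, nm)]] <- payload
      }
    }
  }
  if (length(cargo_entries))
    cargo_entries <- cargo_entries[order(names(cargo_entries), method = "radix")]
  entries <- c(entries, cargo_entries)
  if (grepl("\\.(qdb|zip)$", path)) {
    zip_write(entries, path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (nm in names(entries)) {
      f <- file.path(path, nm)
      dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
      payload <- entries[[nm]]
      if (is.character(payload)) payload <- charToRaw(payload)
      writeBin(payload, f)
    }
  }
  invisible(path)
}

read_text_entry <- function(entries, name) {
  if (!name %in% names(entries)) return(NULL)
  rawToChar(entries[[name]])
}

parse_container_node <- function(kind, node) {
  id <- xml2::xml_attr(node, "id")
  if (is.na(id) || !is_valid_id(id))
    qdb_stop("format_error",
             sprintf("container in registry '%s' has invalid id '%s'", kind, id))
  child_text <- function(tag) {
    n <- xml2::xml_find_first(node, tag)
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  child_texts <- function(tag) {
    ns <- xml2::xml_find_all(node, tag)
    vapply(ns, xml2::xml_text, "")
  }
  labels <- child_text("labels")
  labels <- if (is.null(labels)) character(0)
            else strsplit(labels, " ", fixed = TRUE)[[1]]
  cargo_nodes <- xml2::xml_find_all(node, "cargo")
  cargo_names <- vapply(cargo_nodes, function(n) xml2::xml_attr(n, "name"), "")
  cargos <- if (length(cargo_names))
    stats::setNames(rep(list(NULL), length(cargo_names)), cargo_names)
  else list()
  common <- list(id = id, name = child_text("name"),
                 description = child_text("description"),
                 labels = labels, cargos = cargos)
  switch(kind,
    compounds = do.call(qdb_compound,
      c(common, list(cas = child_text("cas"), inchi = child_text("inchi")))),
    properties = {
      ep <- xml2::xml_find_first(node, "endpoint")
      cat_ <- nam_ <- NULL
      if (!inherits(ep, "xml_missing")) {
        cat_ <- xml2::xml_attr(ep, "category")
        nam_ <- xml2::xml_attr(ep, "name")
        if (is.na(cat_) || !nzchar(cat_)) cat_ <- NULL
        if (is.na(nam_) || !nzchar(nam_)) nam_ <- NULL
      }
      do.call(qdb_property,
              c(common, list(endpoint_category = cat_, endpoint_name = nam_)))
    },
    descriptors = do.call(qdb_descriptor,
      c(common, list(application = child_text("application")))),
    models = do.call(qdb_model,
      c(common, list(property_id = child_text("property-ref"),
                     descriptor_ids = child_texts("descriptor-ref")))),
    predictions = do.call(qdb_prediction,
      c(common, list(model_id = child_text("model-ref"),
                     set_kind = child_text("set-kind"),
                     application = child_text("application"))))
  )
}

#' Read a QDB archive
#'
#' Accepts a ZIP container or an unpacked directory with the archive
#' layout. The read is lenient: declared cargos whose payload entries are
#' absent load with `NULL` payloads, leaving [qdb_validate] to report them.
#' Malformed registry XML or duplicate container ids abort the read.
#'
#' @param path archive path (`.qdb`/`.zip` file or directory).
#' @return a `qdb_archive`.
#' @export
read_archive <- function(path) {
  if (!file.exists(path))
    qdb_stop("io_error", sprintf("no such file or directory: %s", path))
  if (dir.exists(path)) {
    files <- list.files(path, recursive = TRUE)
    entries <- stats::setNames(lapply(files, function(f) {
      fp <- file.path(path, f)
      readBin(fp, "raw", n = file.info(fp)$size)
    }), files)
  } else {
    entries <- zip_read(path)
  }
  if (!"archive.xml" %in% names(entries))
    qdb_stop("missing_registry", "archive.xml not found: not a QDB archive")
  root <- tryCatch(xml2::read_xml(read_text_entry(entries, "archive.xml")),
                   error = function(e)
                     qdb_stop("format_error",
                              paste("malformed archive.xml:",
                                    conditionMessage(e))))
  get_text <- function(node, tag) {
    n <- xml2::xml_find_first(node, tag)
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  archive <- qdb_archive(name = get_text(root, "name"),
                         description = get_text(root, "description"))
  bib_text <- read_text_entry(entries, "bibliography.bib")
  if (!is.null(bib_text)) archive$bibliography <- parse_bibtex(bib_text)
  for (kind in REGISTRY_KINDS) {
    reg_entry <- sprintf("%s/%s.xml", kind, kind)
    txt <- read_text_entry(entries, reg_entry)
    if (is.null(txt)) next
    doc <- tryCatch(xml2::read_xml(txt),
                    error = function(e)
                      qdb_stop("format_error",
                               sprintf("malformed registry XML '%s': %s",
                                       reg_entry, conditionMessage(e))))
    for (node in xml2::xml_find_all(doc, "container")) {
      cont <- parse_container_node(kind, node)
      for (nm in names(cont$cargos)) {
        payload_entry <- sprintf("%s/%s/%s", kind, cont$id, nm)
        if (payload_entry %in% names(entries))
          cont$cargos[[nm]] <- rawToChar(entries[[payload_entry]])
      }
      archive <- add_container(archive, kind, cont)
    }
  }
  archive
}

#' Derive the normalized internal variant of an archive
#'
#' Mirrors the repository practice of keeping the deposited archive
#' verbatim while deriving an optimized working copy: values cargos are
#' re-serialized canonically (rows in compound-registry order, value text
#' verbatim as stored) and every model gains a `"derived"` cargo holding
#' precomputed applicability-domain parameters and the training-matrix
#' shape as JSON. The operation never fails: models whose AD parameters
#' cannot be computed are skipped with a warning. Idempotent.
#'
#' @param archive a `qdb_archive` (left unmodified).
#' @return the derived `qdb_archive`.
#' @export
normalize_internal <- function(archive) {
  out <- archive
  reg_order <- names(out$compounds)
  for (kind in c("properties", "descriptors", "predictions")) {
    for (id in names(out[[kind]])) {
      payload <- out[[kind]][[id]]$cargos[["values"]]
      if (is.null(payload)) next
      vt <- tryCatch(parse_values(payload), qdb_error = function(e) NULL)
      if (is.null(vt)) next
      known <- vt$ids[vt$ids %in% reg_order]
      ord <- c(known[order(match(known, reg_order))],
               vt$ids[!vt$ids %in% reg_order])
      idx <- match(ord, vt$ids)
      canon <- structure(list(ids = vt$ids[idx], values = vt$values[idx]),
                         class = "qdb_values")
      out[[kind]][[id]]$cargos[["values"]] <- format_values(canon)
    }
  }
  for (id in names(out$models)) {
    derived <- tryCatch({
      params <- fit_ad(out, id)
      jsonlite::toJSON(list(
        descriptor_ids = params$descriptor_ids,
        training_shape = c(params$n, params$d),
        centroid = params$centroid,
        covariance = params$covariance,
        xtx_inverse = params$xtx_inverse,
        warning_leverage = params$warning_leverage,
        training_rmse = params$training_rmse,
        singular = params$singular
      ), digits = NA, auto_unbox = TRUE, na = "null")
    }, qdb_error = function(e) {
      warning(sprintf("model '%s': %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(derived))
      out$models[[id]]$cargos[["derived"]] <- as.character(derived)
  }
  out
}
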