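# Object model for QDB archives.
#
# An archive holds five ordered registries of "containers": compounds,
# properties, descriptors, models and predictions. A container is an
# identified record with optional name/description/labels and a set of named
# cargo payloads (text). A cargo payload of NULL means the cargo is declared
# but its data is absent -- readers keep such declarations so that the
# validator can report them.

REGISTRY_KINDS <- c("compounds", "properties", "descriptors", "models",
                    "predictions")
SET_KINDS <- c("training", "validation", "testing")

#' Test whether a string is a valid container id
#'
#' Container ids are lowercase tokens matching `^[a-z0-9][a-z0-9-]*$`:
#' filesystem- and URL-safe, so they can name directories inside the
#' archive container.
#'
#' @param id character vector of candidate ids.
#' @return logical vector.
#' @export
is_valid_id <- function(id) {
  is.character(id) & !is.na(id) & grepl("^[a-z0-9][a-z0-9-]*$", id)
}

check_id <- function(id) {
  if (length(id) != 1L || !is_valid_id(id))
    qdb_stop("invalid_id", sprintf("invalid container id: %s",
                                   deparse(substitute(id))), id = id)
  id
}

new_container <- function(kind, id, name = NULL, description = NULL,
                          labels = character(0), cargos = list(), extra = list()) {
  check_id(id)
  if (anyDuplicated(names(cargos)))
    qdb_stop("invalid_id", sprintf("duplicate cargo name in container '%s'", id))
  structure(
    c(list(id = id, name = name, description = description,
           labels = as.character(labels), cargos = cargos),
      extra),
    class = c(paste0("qdb_", kind), "qdb_container")
  )
}

#' Construct a Compound container
#'
#' @param id container id (token).
#' @param name,description free-text attributes (optional).
#' @param labels character vector of label tokens.
#' @param cas CAS Registry Number text, e.g. `"7732-18-5"` (optional).
#' @param inchi InChI identifier text (optional).
#' @param smiles SMILES string stored as the `"smiles"` cargo (optional).
#' @param cargos named list of additional cargo payloads (character, or
#'   `NULL` for a declared-but-missing cargo).
#' @return a `qdb_compound` object.
#' @export
qdb_compound <- function(id, name = NULL, description = NULL,
                         labels = character(0), cas = NULL, inchi = NULL,
                         smiles = NULL, cargos = list()) {
  if (!is.null(smiles)) cargos[["smiles"]] <- smiles
  new_container("compound", id, name, description, labels, cargos,
                extra = list(cas = cas, inchi = inchi))
}

#' Construct a Property container
#'
#' A property describes the modelled endpoint. Its experimental values live
#' in the `"values"` cargo; the unit of measure is stored verbatim in the
#' `"ucum"` cargo.
#'
#' @inheritParams qdb_compound
#' @param endpoint_category,endpoint_name endpoint classification texts.
#' @param values a [qdb_values] table (stored as the `"values"` cargo).
#' @param ucum unit text, stored verbatim.
#' @return a `qdb_property` object.
#' @export
qdb_property <- function(id, name = NULL, description = NULL,
                         labels = character(0), endpoint_category = NULL,
                         endpoint_name = NULL, values = NULL, ucum = NULL,
                         cargos = list()) {
  if (!is.null(values)) cargos[["values"]] <- format_values(values)
  if (!is.null(ucum)) cargos[["ucum"]] <- ucum
  new_container("property", id, name, description, labels, cargos,
                extra = list(endpoint_category = endpoint_category,
                             endpoint_name = endpoint_name))
}

#' Construct a Descriptor container
#'
#' @inheritParams qdb_property
#' @param application software provenance text, conventionally
#'   `"software-name/version"`.
#' @return a `qdb_descriptor` object.
#' @export
qdb_descriptor <- function(id, name = NULL, description = NULL,
                           labels = character(0), application = NULL,
                           values = NULL, cargos = list()) {
  if (!is.null(values)) cargos[["values"]] <- format_values(values)
  new_container("descriptor", id, name, description, labels, cargos,
                extra = list(application = application))
}

#' Construct a Model container
#'
#' A model refers to one property (the dependent variable) and an ordered
#' list of descriptors (the independent variables) through strong
#' references. Its mathematical representation is stored in the
#' `"equation"` cargo (see [parse_equation] for the dialect).
#'
#' @inheritParams qdb_compound
#' @param property_id id of the modelled property (strong reference).
#' @param descriptor_ids ordered character vector of descriptor ids.
#' @param equation equation cargo text (optional at construction time).
#' @return a `qdb_model` object.
#' @export
qdb_model <- function(id, property_id = NULL, descriptor_ids = character(0),
                      name = NULL, description = NULL, labels = character(0),
                      equation = NULL, cargos = list()) {
  if (!is.null(equation)) cargos[["equation"]] <- equation
  new_container("model", id, name, description, labels, cargos,
                extra = list(property_id = property_id,
                             descriptor_ids = as.character(descriptor_ids)))
}

#' Construct a Prediction container
#'
#' Predictions carry the values a model produced for one data subset and the
#' subset's membership kind (`training`, `validation` or `testing`).
#'
#' @inheritParams qdb_property
#' @param model_id id of the owning model (strong reference).
#' @param set_kind one of `"training"`, `"validation"`, `"testing"`.
#' @param application software provenance text (optional).
#' @return a `qdb_prediction` object.
#' @export
qdb_prediction <- function(id, model_id = NULL, set_kind = NULL,
                           name = NULL, description = NULL,
                           labels = character(0), application = NULL,
                           values = NULL, cargos = list()) {
  if (!is.null(values)) cargos[["values"]] <- format_values(values)
  new_container("prediction", id, name, description, labels, cargos,
                extra = list(model_id = model_id, set_kind = set_kind,
                             application = application))
}

#' Construct an empty or populated QDB archive
#'
#' @param name,description archive-level metadata texts.
#' @param compounds,properties,descriptors,models,predictions lists of the
#'   corresponding container objects (insertion order is preserved).
#' @param bibliography an optional [bibliography_record].
#' @return a `qdb_archive` object.
#' @export
qdb_archive <- function(name = NULL, description = NULL,
                        compounds = list(), properties = list(),
                        descriptors = list(), models = list(),
                        predictions = list(), bibliography = NULL) {
  arc <- structure(
    list(name = name, description = description,
         compounds = list(), properties = list(), descriptors = list(),
         models = list(), predictions = list(),
         bibliography = bibliography),
    class = "qdb_archive"
  )
  for (kind in REGISTRY_KINDS) {
    for (cont in get(kind)) arc <- add_container(arc, kind, cont)
  }
  arc
}

add_container <- function(archive, kind, container) {
  kind <- match.arg(kind, REGISTRY_KINDS)
  id <- container$id
  if (id %in% names(archive[[kind]]))
    qdb_stop("duplicate_id",
             sprintf("duplicate id '%s' in registry '%s'", id, kind),
             id = id, kind = kind)
  archive[[kind]][[id]] <- container
  archive
}

#' Resolve a strong reference
#'
#' Strong references are attribute-level links (model to property, model to
#' descriptor, prediction to model) that must resolve to an existing
#' container; an unresolved strong reference is a structural error.
#'
#' @param archive a `qdb_archive`.
#' @param kind registry name: one of `"compounds"`, `"properties"`,
#'   `"descriptors"`, `"models"`, `"predictions"`.
#' @param id container id to look up.
#' @param referrer path text identifying the referring container, used in
#'   the error message.
#' @return the container object.
#' @export
resolve_strong <- function(archive, kind, id, referrer = NULL) {
  kind <- match.arg(kind, REGISTRY_KINDS)
  if (is.null(id) || length(id) != 1L || !id %in% names(archive[[kind]]))
    qdb_stop("unresolved_reference",
             sprintf("unresolved strong reference to %s '%s'%s", kind,
                     if (is.null(id)) "<missing>" else id,
                     if (is.null(referrer)) "" else paste0(" from ", referrer)),
             kind = kind, id = id, referrer = referrer)
  archive[[kind]][[id]]
}

#' Resolve the weak references of a values table
#'
#' The compound-id keys of a values cargo are weak references: resolution
#' status is data for the validator, not an error.
#'
#' @param values a [qdb_values] table.
#' @param archive a `qdb_archive`.
#' @return a data frame with columns `compound_id` and `resolved`.
#' @export
weak_targets <- function(values, archive) {
  ids <- values$ids
  data.frame(compound_id = ids,
             resolved = ids %in% names(archive$compounds),
             stringsAsFactors = FALSE)
}

container_path <- function(kind, id) paste0(kind, "/", id)

#' @export
print.qdb_archive <- function(x, ...) {
  cat("QDB archive:", if (is.null(x$name)) "<unnamed>" else x$name, "\n")
  for (kind in REGISTRY_KINDS)
    cat(sprintf("  %-12s %d\n", kind, length(x[[kind]])))
  if (!is.null(x$bibliography))
    cat("  bibliography:", x$bibliography$entry_type, "\n")
  invisible(x)
}

#' @export
print.qdb_container <- function(x, ...) {
  cat(sprintf("<%s> id=%s", class(x)[1], x$id))
  if (!is.null(x$name)) cat(" name=", x$name, sep = "")
  cat("\n  cargos:", if (length(x$cargos)) paste(names(x$cargos), collapse = ", ")
      else "<none>", "\n")
  invisible(x)
}

#' Construct a bibliography record
#'
#' Archive-level provenance modelled after the BibTeX entry format: an entry
#' type plus a set of key/value fields. Keys are case-insensitive and
#' stored lowercase.
#'
#' @param entry_type BibTeX entry type token, e.g. `"article"`.
#' @param key citation key.
#' @param fields named character vector or list of fields
#'   (author, title, journal, year, doi, ...).
#' @return a `qdb_bibliography` object.
#' @export
bibliography_record <- function(entry_type = "article", key = "ref1",
                                fields = list()) {
  nm <- tolower(names(fields))
  if (anyDuplicated(nm))
    qdb_stop("invalid_id", "duplicate bibliography field (case-insensitive)")
  fields <- stats::setNames(as.list(vapply(fields, as.character, "")), nm)
  structure(list(entry_type = tolower(entry_type), key = key, fields = fields),
            class = "qdb_bibliography")
}
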