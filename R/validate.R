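# Three-level archive validation.
#
# basic        "sanity testing":     structure and well-formedness
# intermediate "reusability":        containers uniquely identifiable
# advanced     "reproducibility":    stored predictions re-derivable from
#                                    the stored descriptor data
#
# Each level includes every lower level. Problems never raise: they become
# findings (ERROR or WARNING) in a validation report whose outcome is
# "failed" when any ERROR is present, "warnings" when only warnings are,
# and "clean" otherwise.

VALIDATION_LEVELS <- c("basic", "intermediate", "advanced")

finding <- function(severity, level, check_id, kind, id, message) {
  data.frame(severity = severity, level = level, check_id = check_id,
             path = if (is.null(kind)) "archive" else container_path(kind, id),
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(severity = character(0), level = character(0),
             check_id = character(0), path = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

bind_findings <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (!length(lst)) return(no_findings())
  do.call(rbind, lst)
}

# Deterministic finding order: registry, container position within its
# registry, then check id; emission order breaks remaining ties.
order_findings <- function(findings, archive) {
  if (!nrow(findings)) return(findings)
  kind <- sub("/.*$", "", findings$path)
  id <- sub("^[^/]*/", "", findings$path)
  reg_idx <- match(kind, REGISTRY_KINDS, nomatch = 0L)
  pos <- mapply(function(k, i) {
    if (k == 0L) 0L else match(i, names(archive[[REGISTRY_KINDS[k]]]),
                               nomatch = .Machine$integer.max)
  }, reg_idx, id)
  findings[order(reg_idx, pos, findings$check_id), , drop = FALSE]
}

derive_outcome <- function(findings) {
  if (any(findings$severity == "ERROR")) "failed"
  else if (any(findings$severity == "WARNING")) "warnings"
  else "clean"
}

#' Validate a QDB archive
#'
#' Runs all checks of the requested compliance level and every lower level
#' and assembles a validation report. All problems become findings;
#' `qdb_validate` itself never signals an error for archive content.
#'
#' @param archive a `qdb_archive`.
#' @param level target compliance level: `"basic"`, `"intermediate"` or
#'   `"advanced"`.
#' @param tolerance absolute tolerance for the advanced
#'   prediction-reproduction comparison; the default `NULL` uses half a
#'   unit in the last decimal place of each stored value's text, with an
#'   absolute floor of `1e-8`.
#' @return a `qdb_validation_report`: list with `target_level`, `findings`
#'   (ordered data frame) and `outcome` (`"clean"`, `"warnings"` or
#'   `"failed"`).
#' @export
qdb_validate <- function(archive, level = "basic", tolerance = NULL) {
  level <- match.arg(level, VALIDATION_LEVELS)
  findings <- check_basic(archive)
  if (level %in% c("intermediate", "advanced"))
    findings <- rbind(findings, check_intermediate(archive))
  if (level == "advanced")
    findings <- rbind(findings, check_advanced(archive, tolerance = tolerance))
  findings <- order_findings(findings, archive)
  rownames(findings) <- NULL
  structure(list(target_level = level, findings = findings,
                 outcome = derive_outcome(findings)),
            class = "qdb_validation_report")
}

#' @export
print.qdb_validation_report <- function(x, ...) {
  cat(sprintf("QDB validation (%s level): %s\n", x$target_level, x$outcome))
  if (nrow(x$findings)) {
    for (i in seq_len(nrow(x$findings)))
      cat(sprintf("  %-7s [%s] %s: %s\n", x$findings$severity[i],
                  x$findings$check_id[i], x$findings$path[i],
                  x$findings$message[i]))
  }
  invisible(x)
}

cargo_payload <- function(container, name) {
  if (!name %in% names(container$cargos)) return(NULL)
  container$cargos[[name]]
}

parsed_values_or_null <- function(container) {
  payload <- cargo_payload(container, "values")
  if (is.null(payload)) return(NULL)
  tryCatch(parse_values(payload), qdb_error = function(e) NULL)
}

#' Basic-level checks ("sanity testing")
#'
#' Structural and well-formedness checks: required attributes, presence of
#' declared cargos, parseability of system cargos, CAS check digits, InChI
#' syntax, presence of the model equation, strong and weak reference
#' resolution. Missing optional attributes (name, description, labels)
#' yield warnings.
#'
#' @param archive a `qdb_archive`.
#' @return data frame of findings.
#' @export
check_basic <- function(archive) {
  out <- list()
  emit <- function(severity, check_id, kind, id, message)
    out[[length(out) + 1L]] <<- finding(severity, "basic", check_id, kind, id,
                                        message)
  for (kind in REGISTRY_KINDS) {
    for (cont in archive[[kind]]) {
      id <- cont$id
      for (attr_name in c("name", "description")) {
        if (is.null(cont[[attr_name]]))
          emit("WARNING", "optional-attribute-missing", kind, id,
               sprintf("optional attribute '%s' is missing", attr_name))
      }
      if (!length(cont$labels))
        emit("WARNING", "optional-attribute-missing", kind, id,
             "optional attribute 'labels' is missing")
      for (nm in names(cont$cargos)) {
        if (is.null(cont$cargos[[nm]]))
          emit("ERROR", "cargo-missing", kind, id,
               sprintf("declared cargo '%s' is absent from the archive", nm))
      }
      if (kind %in% c("properties", "descriptors", "predictions")) {
        payload <- cargo_payload(cont, "values")
        if (!"values" %in% names(cont$cargos)) {
          emit("ERROR", "values-cargo-missing", kind, id,
               "required 'values' cargo is not declared")
        } else if (!is.null(payload)) {
          vt <- tryCatch(parse_values(payload), qdb_error = function(e) e)
          if (inherits(vt, "qdb_error")) {
            emit("ERROR", "values-cargo-unparseable", kind, id,
                 conditionMessage(vt))
          } else {
            wt <- weak_targets(vt, archive)
            for (bad in wt$compound_id[!wt$resolved])
              emit("ERROR", "weak-ref-unresolved", kind, id,
                   sprintf("value refers to unknown compound '%s'", bad))
            if (kind == "descriptors" && !values_is_numeric(vt))
              emit("ERROR", "descriptor-values-nonnumeric", kind, id,
                   "descriptor values must be finite numbers or N/A")
          }
        }
      }
      if (kind == "compounds") {
        if (!is.null(cont$cas) && !validate_cas(cont$cas))
          emit("ERROR", "cas-checksum", kind, id,
               sprintf("CAS number '%s' fails shape or check-digit validation",
                       cont$cas))
        if (!is.null(cont$inchi) && !validate_inchi_syntax(cont$inchi))
          emit("ERROR", "inchi-syntax", kind, id,
               sprintf("InChI '%s' does not match the layered grammar",
                       cont$inchi))
      }
      if (kind == "models") {
        if (is.null(cont$property_id)) {
          emit("ERROR", "property-ref-missing", kind, id,
               "model does not declare a property reference")
        } else if (!cont$property_id %in% names(archive$properties)) {
          emit("ERROR", "strong-ref-unresolved", kind, id,
               sprintf("property reference '%s' does not resolve",
                       cont$property_id))
        }
        for (d in cont$descriptor_ids) {
          if (!d %in% names(archive$descriptors))
            emit("ERROR", "strong-ref-unresolved", kind, id,
                 sprintf("descriptor reference '%s' does not resolve", d))
        }
        eq <- cargo_payload(cont, "equation")
        if (!"equation" %in% names(cont$cargos) || is.null(eq)) {
          if (!"equation" %in% names(cont$cargos))
            emit("ERROR", "equation-missing", kind, id,
                 "model has no mathematical representation ('equation' cargo)")
        } else {
          spec <- tryCatch(parse_equation(eq), qdb_error = function(e) e)
          if (inherits(spec, "qdb_error"))
            emit("ERROR", "equation-unparseable", kind, id,
                 conditionMessage(spec))
        }
      }
      if (kind == "predictions") {
        if (is.null(cont$model_id)) {
          emit("ERROR", "model-ref-missing", kind, id,
               "prediction does not declare a model reference")
        } else if (!cont$model_id %in% names(archive$models)) {
          emit("ERROR", "strong-ref-unresolved", kind, id,
               sprintf("model reference '%s' does not resolve", cont$model_id))
        }
        if (is.null(cont$set_kind) || !cont$set_kind %in% SET_KINDS)
          emit("ERROR", "set-kind-invalid", kind, id,
               sprintf("set kind '%s' is not one of %s",
                       cont$set_kind %||% "<missing>",
                       paste(SET_KINDS, collapse = "/")))
      }
    }
  }
  bind_findings(out)
}

#' Intermediate-level checks ("reusability testing")
#'
#' Ensures compounds, properties and descriptors are uniquely identifiable:
#' every compound needs an InChI, every property both endpoint attributes
#' and a unit ("ucum") cargo, every descriptor an application attribute.
#' Two compounds sharing one InChI are ambiguous and yield a warning.
#'
#' @param archive a `qdb_archive`.
#' @return data frame of findings (intermediate level only).
#' @export
check_intermediate <- function(archive) {
  out <- list()
  emit <- function(severity, check_id, kind, id, message)
    out[[length(out) + 1L]] <<- finding(severity, "intermediate", check_id,
                                        kind, id, message)
  seen_inchi <- character(0)
  for (cont in archive$compounds) {
    if (is.null(cont$inchi)) {
      emit("ERROR", "inchi-missing", "compounds", cont$id,
           "compound has no InChI attribute")
    } else {
      if (cont$inchi %in% seen_inchi)
        emit("WARNING", "inchi-duplicate", "compounds", cont$id,
             "another compound carries an identical InChI")
      seen_inchi <- c(seen_inchi, cont$inchi)
    }
  }
  for (cont in archive$properties) {
    if (is.null(cont$endpoint_category) || is.null(cont$endpoint_name))
      emit("ERROR", "endpoint-missing", "properties", cont$id,
           "property lacks endpoint category and/or name")
    if (is.null(cargo_payload(cont, "ucum")))
      emit("ERROR", "ucum-missing", "properties", cont$id,
           "property has no unit ('ucum') cargo")
  }
  for (cont in archive$descriptors) {
    if (is.null(cont$application))
      emit("ERROR", "descriptor-application-missing", "descriptors", cont$id,
           "descriptor has no application attribute")
  }
  bind_findings(out)
}

# Half a unit in the last printed decimal place of the stored text, with an
# absolute floor of 1e-8. Stored values carry finite precision, so exact
# float equality is not a meaningful reproduction criterion.
tolerance_for_text <- function(txt) {
  tol <- if (grepl("^-?[0-9]+$", txt)) {
    0.5
  } else if (grepl("^-?[0-9]*\\.[0-9]+$", txt)) {
    frac <- sub("^-?[0-9]*\\.", "", txt)
    0.5 * 10^(-nchar(frac))
  } else if (grepl("^-?[0-9]*\\.?[0-9]*[eE][+-]?[0-9]+$", txt)) {
    expo <- as.numeric(sub("^.*[eE]", "", txt))
    mant <- sub("[eE].*$", "", txt)
    ndec <- if (grepl("\\.", mant)) nchar(sub("^-?[0-9]*\\.", "", mant)) else 0
    0.5 * 10^(expo - ndec)
  } else {
    1e-8
  }
  max(tol, 1e-8)
}

#' Advanced-level checks ("reproducibility testing")
#'
#' Re-evaluates every model on the descriptor data stored in the archive
#' and compares the recomputed predictions with the stored ones. A
#' numeric disagreement beyond the tolerance (or any label disagreement
#' for classification models) is a `prediction-mismatch` error; a
#' predicted compound lacking a descriptor value is a
#' `descriptor-value-missing` error. Models that failed basic checks are
#' skipped with a warning.
#'
#' @inheritParams qdb_validate
#' @return data frame of findings (advanced level only).
#' @export
check_advanced <- function(archive, tolerance = NULL) {
  out <- list()
  emit <- function(severity, check_id, kind, id, message)
    out[[length(out) + 1L]] <<- finding(severity, "advanced", check_id,
                                        kind, id, message)
  for (model in archive$models) {
    eq_text <- cargo_payload(model, "equation")
    spec <- if (is.null(eq_text)) NULL
            else tryCatch(parse_equation(eq_text), qdb_error = function(e) NULL)
    desc_ok <- all(model$descriptor_ids %in% names(archive$descriptors))
    if (is.null(spec) || !desc_ok) {
      emit("WARNING", "model-skipped", "models", model$id,
           "model skipped: equation or descriptor data unusable (see basic findings)")
      next
    }
    desc_tables <- lapply(archive$descriptors[model$descriptor_ids],
                          parsed_values_or_null)
    if (any(vapply(desc_tables, is.null, TRUE))) {
      emit("WARNING", "model-skipped", "models", model$id,
           "model skipped: descriptor values cargo unusable (see basic findings)")
      next
    }
    desc_num <- lapply(desc_tables, values_numeric)
    preds <- Filter(function(p) identical(p$model_id, model$id),
                    archive$predictions)
    for (pred in preds) {
      vt <- parsed_values_or_null(pred)
      if (is.null(vt)) {
        emit("WARNING", "model-skipped", "predictions", pred$id,
             "prediction skipped: values cargo unusable (see basic findings)")
        next
      }
      for (i in seq_along(vt$ids)) {
        cid <- vt$ids[i]
        stored_txt <- vt$values[i]
        if (stored_txt == NA_MARKER) next
        bindings <- vapply(desc_num, function(v)
          if (cid %in% names(v)) v[[cid]] else NA_real_, numeric(1))
        names(bindings) <- model$descriptor_ids
        if (anyNA(bindings)) {
          emit("ERROR", "descriptor-value-missing", "predictions", pred$id,
               sprintf("compound '%s' lacks a value for descriptor '%s'",
                       cid, model$descriptor_ids[which(is.na(bindings))[1]]))
          next
        }
        recomputed <- tryCatch(evaluate_equation(spec, bindings),
                               qdb_error = function(e) e)
        if (inherits(recomputed, "qdb_error")) {
          emit("ERROR", "equation-evaluation-error", "predictions", pred$id,
               sprintf("compound '%s': %s", cid, conditionMessage(recomputed)))
          next
        }
        if (spec$model_type == "classification") {
          if (!identical(as.character(recomputed), stored_txt))
            emit("ERROR", "prediction-mismatch", "predictions", pred$id,
                 sprintf("compound '%s': stored label '%s', recomputed '%s'",
                         cid, stored_txt, recomputed))
        } else {
          stored_num <- suppressWarnings(as.numeric(stored_txt))
          tol <- if (is.null(tolerance)) tolerance_for_text(stored_txt)
                 else tolerance
          if (is.na(stored_num) || abs(recomputed - stored_num) > tol)
            emit("ERROR", "prediction-mismatch", "predictions", pred$id,
                 sprintf("compound '%s': stored %s, recomputed %s (tol %g)",
                         cid, stored_txt, format_qdb_number(recomputed), tol))
        }
      }
    }
  }
  bind_findings(out)
}
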