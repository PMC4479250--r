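# Prediction engine.
#
# Three ways in: a chemical structure (SMILES or InChI, handed to a
# pluggable descriptor calculator), manually entered descriptor values, or
# the raw descriptor row stored in the archive for a dataset compound.
# Every route ends in the same evaluation step and decorates the result
# with applicability-domain context (leverage-based domain flag) and the
# Euclidean nearest neighbours.

#' Construct a table-driven descriptor calculator
#'
#' Descriptor calculators are plugins identified by an application text
#' (`"name/version"`). This built-in one serves fixed values: either one
#' set for any structure, or a per-structure lookup table. A calculator
#' declines a descriptor id by omitting it from its result -- never by
#' returning a silent zero.
#'
#' @param values named numeric vector served for any structure, or a named
#'   list mapping structure text to such vectors.
#' @param application identification text.
#' @return a `qdb_calculator`: list with `application` and
#'   `compute(structure, ids)`.
#' @export
mock_calculator <- function(values, application = "mock/1.0") {
  compute <- if (is.list(values)) {
    function(structure, ids) {
      row <- values[[structure]]
      if (is.null(row))
        qdb_stop("format_error",
                 sprintf("calculator cannot parse structure '%s'", structure))
      row[names(row) %in% ids]
    }
  } else {
    function(structure, ids) values[names(values) %in% ids]
  }
  structure(list(application = application, compute = compute),
            class = "qdb_calculator")
}

new_prediction_result <- function(archive, model, bindings, provenance, k) {
  spec <- parse_equation(cargo_payload(model, "equation"))
  missing <- setdiff(spec$identifiers, names(bindings))
  if (length(missing))
    qdb_stop("missing_binding",
             sprintf("no value for descriptor(s): %s",
                     paste(missing, collapse = ", ")),
             identifiers = missing)
  value <- evaluate_equation(spec, bindings)
  x <- as.numeric(bindings[model$descriptor_ids])
  ad <- tryCatch(fit_ad(archive, model), qdb_error = function(e) NULL)
  ad_info <- if (is.null(ad)) {
    list(leverage = NA_real_, mahalanobis = NA_real_,
         warning_leverage = NA_real_, inside_domain = NA)
  } else {
    lev <- ad_leverage(ad, x)
    list(leverage = lev, mahalanobis = ad_mahalanobis(ad, x),
         warning_leverage = ad$warning_leverage,
         inside_domain = lev <= ad$warning_leverage)
  }
  neighbours <- tryCatch(similar_compounds(archive, model, x, k = k),
                         qdb_error = function(e)
                           data.frame(compound_id = character(0),
                                      distance = numeric(0),
                                      experimental = numeric(0),
                                      predicted = numeric(0)))
  structure(list(model_id = model$id, value = value,
                 descriptor_values = bindings[model$descriptor_ids],
                 ad = ad_info, neighbours = neighbours,
                 provenance = stats::setNames(
                   rep(provenance, length(model$descriptor_ids)),
                   model$descriptor_ids)),
            class = "qdb_prediction_result")
}

#' @export
print.qdb_prediction_result <- function(x, ...) {
  cat(sprintf("model %s -> %s\n", x$model_id,
              if (is.numeric(x$value)) format_qdb_number(x$value) else x$value))
  cat(sprintf("  leverage %.4g (h* = %.4g, %s)\n", x$ad$leverage,
              x$ad$warning_leverage,
              if (isTRUE(x$ad$inside_domain)) "inside domain"
              else if (isFALSE(x$ad$inside_domain)) "OUTSIDE domain"
              else "domain undefined"))
  if (nrow(x$neighbours))
    cat(sprintf("  nearest: %s\n",
                paste(sprintf("%s (%.3g)", x$neighbours$compound_id,
                              x$neighbours$distance), collapse = ", ")))
  invisible(x)
}

#' Predict from a chemical structure
#'
#' The three-step pipeline: normalize the structure text, compute the
#' model's descriptors with the supplied calculator, evaluate the
#' equation. The result carries applicability-domain context and the
#' nearest dataset compounds.
#'
#' @param archive a `qdb_archive`.
#' @param model a `qdb_model` or model id.
#' @param structure SMILES or InChI text (passed verbatim to the
#'   calculator).
#' @param calculator a `qdb_calculator` (see [mock_calculator]).
#' @param k neighbour count for the similarity analysis.
#' @return a `qdb_prediction_result`.
#' @export
predict_structure <- function(archive, model, structure, calculator, k = 5) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  if (missing(calculator) || is.null(calculator))
    qdb_stop("calculator_unavailable",
             "no descriptor calculator available for this model")
  structure_text <- trimws(structure)
  computed <- calculator$compute(structure_text, model$descriptor_ids)
  missing_ids <- setdiff(model$descriptor_ids, names(computed))
  if (length(missing_ids))
    qdb_stop("descriptor_not_computable",
             sprintf("calculator cannot compute descriptor(s): %s",
                     paste(missing_ids, collapse = ", ")),
             identifiers = missing_ids)
  new_prediction_result(archive, model, as.list(computed)[model$descriptor_ids],
                        "computed", k)
}

#' Predict from manually entered descriptor values
#'
#' @inheritParams predict_structure
#' @param values named numeric vector or list covering all model
#'   descriptors.
#' @return a `qdb_prediction_result`.
#' @export
predict_manual <- function(archive, model, values, k = 5) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  new_prediction_result(archive, model, as.list(values), "manual", k)
}

#' Repeat a prediction from the raw data stored in the archive
#'
#' @inheritParams predict_structure
#' @param compound_id id of a dataset compound with a complete descriptor
#'   row.
#' @return a `qdb_prediction_result`.
#' @export
predict_stored <- function(archive, model, compound_id, k = 5) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  resolve_strong(archive, "compounds", compound_id)
  desc_num <- model_descriptor_numeric(archive, model)
  x <- descriptor_row(desc_num, compound_id)
  if (anyNA(x))
    qdb_stop("descriptor_value_missing",
             sprintf("compound '%s' lacks stored value(s) for descriptor(s): %s",
                     compound_id,
                     paste(model$descriptor_ids[is.na(x)], collapse = ", ")))
  new_prediction_result(archive, model,
                        stats::setNames(as.list(x), model$descriptor_ids),
                        "stored", k)
}

#' Batch prediction
#'
#' Applies the appropriate single-prediction route to each input record.
#' One failing record never aborts the batch; output order equals input
#' order.
#'
#' @inheritParams predict_structure
#' @param inputs list of records; each record is a list with exactly one of
#'   `structure` (SMILES/InChI text), `values` (named descriptor values) or
#'   `compound` (dataset compound id).
#' @param calculator calculator for `structure` records (may be `NULL` if
#'   none occur).
#' @return list, in input order, of elements `list(ok = TRUE, result = ...)`
#'   or `list(ok = FALSE, error = <message>)`.
#' @export
predict_batch <- function(archive, model, inputs, calculator = NULL, k = 5) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  lapply(inputs, function(rec) {
    tryCatch({
      result <- if (!is.null(rec$structure)) {
        predict_structure(archive, model, rec$structure, calculator, k = k)
      } else if (!is.null(rec$values)) {
        predict_manual(archive, model, rec$values, k = k)
      } else if (!is.null(rec$compound)) {
        predict_stored(archive, model, rec$compound, k = k)
      } else {
        qdb_stop("format_error",
                 "record has none of structure/values/compound")
      }
      list(ok = TRUE, result = result)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  })
}
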