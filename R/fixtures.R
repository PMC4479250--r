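# Deterministic synthetic archives.
#
# The generator emulates a deposited QSAR archive end to end: compounds
# with checksum-valid CAS numbers and grammar-valid InChIs, independent
# normally distributed descriptors, a linear property with optional
# Gaussian noise, a model whose equation cargo encodes the exact
# generating coefficients, and per-subset predictions computed by
# re-evaluating that equation on the stored (text-rounded) descriptor
# values -- so a defect-free fixture passes advanced validation by
# construction. Defect tokens break exactly one validation level each.

FIXTURE_DEFECTS <- c("drop-inchi", "bad-cas", "tamper-prediction",
                     "orphan-cargo", "dangling-weak-ref")

#' Describe a synthetic archive
#'
#' @param n_compounds number of compounds (`>= 4`).
#' @param descriptors list of descriptor definitions, each
#'   `list(id =, mean =, sd =)`; ids must be usable in equations
#'   (letters/digits/underscore).
#' @param coefficients numeric vector `c(intercept, w1, ..., wd)` of the
#'   generating linear model.
#' @param noise_sd standard deviation of the Gaussian noise linking the
#'   linear score to the experimental property (0 for an exactly linear
#'   property).
#' @param split fractions of compounds assigned to the training,
#'   validation and testing subsets (must sum to 1).
#' @param model_type `"regression"` or `"classification"`.
#' @param cut_points,labels classification thresholds and category labels
#'   (defaults: one cut at the intercept, labels inactive/active).
#' @param seed integer seed; the same spec always yields a byte-identical
#'   archive.
#' @param defects character vector of defect tokens to apply, drawn from
#'   `"drop-inchi"`, `"bad-cas"`, `"tamper-prediction"`, `"orphan-cargo"`,
#'   `"dangling-weak-ref"`.
#' @return a `qdb_fixture_spec`.
#' @export
fixture_spec <- function(n_compounds = 30,
                         descriptors = list(
                           list(id = "d1", mean = 2, sd = 1),
                           list(id = "d2", mean = 0, sd = 0.5)),
                         coefficients = c(1.2, 0.55, -0.75),
                         noise_sd = 0.2,
                         split = c(training = 0.7, validation = 0.15,
                                   testing = 0.15),
                         model_type = "regression",
                         cut_points = NULL, labels = NULL,
                         seed = 42, defects = character(0)) {
  if (n_compounds < 4)
    qdb_stop("spec_error", "n_compounds must be at least 4")
  if (length(coefficients) != length(descriptors) + 1L)
    qdb_stop("spec_error",
             "coefficients must be c(intercept, one weight per descriptor)")
  if (any(split < 0) || any(split > 1) || abs(sum(split) - 1) > 1e-9)
    qdb_stop("spec_error", "split fractions must lie in [0,1] and sum to 1")
  if (!model_type %in% c("regression", "classification"))
    qdb_stop("spec_error", "model_type must be regression or classification")
  bad <- setdiff(defects, FIXTURE_DEFECTS)
  if (length(bad))
    qdb_stop("spec_error",
             sprintf("unknown defect token(s): %s", paste(bad, collapse = ", ")))
  structure(list(n_compounds = as.integer(n_compounds),
                 descriptors = descriptors,
                 coefficients = as.numeric(coefficients),
                 noise_sd = noise_sd, split = split, model_type = model_type,
                 cut_points = cut_points, labels = labels,
                 seed = as.integer(seed), defects = defects),
            class = "qdb_fixture_spec")
}

# Grammar-valid, pairwise-distinct InChIs: the alkane formula series.
fixture_inchi <- function(i) {
  sprintf("InChI=1S/C%sH%d", if (i > 1) as.character(i) else "", 2 * i + 2)
}

fixture_cas <- function(i) {
  body <- sprintf("%d-%02d", 100 + i, i %% 100)
  sprintf("%s-%d", body, cas_check_digit(body))
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

set_null <- function(lst, name) {
  lst[name] <- list(NULL)
  lst
}

#' Generate a synthetic QDB archive
#'
#' @param spec a [fixture_spec].
#' @return a `qdb_archive`; with no defects it validates clean at every
#'   level.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "qdb_fixture_spec"))
  with_preserved_rng(spec$seed, {
    n <- spec$n_compounds
    d <- length(spec$descriptors)
    ids <- sprintf("c%d", seq_len(n))
    desc_ids <- vapply(spec$descriptors, `[[`, "", "id")
    # Descriptor values, rendered to text then re-parsed: the stored text
    # is the single source of truth for everything downstream.
    desc_txt <- lapply(spec$descriptors, function(dd)
      format_qdb_number(stats::rnorm(n, dd$mean, dd$sd)))
    X <- do.call(cbind, lapply(desc_txt, as.numeric))
    score <- spec$coefficients[1] + drop(X %*% spec$coefficients[-1])
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd)
             else numeric(n)
    y <- score + noise
    shuffle <- sample.int(n)
    n_tr <- max(2L, round(spec$split[[1]] * n))
    n_va <- round(spec$split[[2]] * n)
    n_te <- n - n_tr - n_va
    subset_ids <- list(training = ids[sort(shuffle[seq_len(n_tr)])],
                       validation = ids[sort(shuffle[n_tr + seq_len(n_va)])],
                       testing = if (n_te > 0)
                         ids[sort(shuffle[n_tr + n_va + seq_len(n_te)])]
                       else character(0))
    coef_txt <- format_qdb_number(spec$coefficients)
    terms <- c(coef_txt[1],
               sprintf("%s*%s", coef_txt[-1], desc_ids))
    expr <- paste(terms, collapse = " + ")
    expr <- gsub("\\+ -", "- ", expr)
    header <- if (spec$model_type == "regression") {
      "type=regression"
    } else {
      cuts <- spec$cut_points %||% spec$coefficients[1]
      labels <- spec$labels %||% c("inactive", "active")
      sprintf("type=classification; cuts=%s; labels=%s",
              paste(format_qdb_number(cuts), collapse = ","),
              paste(labels, collapse = ","))
    }
    equation <- paste0(header, "\n", expr, "\n")
    eq_spec <- parse_equation(equation)
    # Predictions: re-evaluate the parsed equation on the stored
    # descriptor text, exactly as advanced validation will.
    predicted <- vapply(seq_len(n), function(i) {
      b <- stats::setNames(as.list(X[i, ]), desc_ids)
      v <- evaluate_equation(eq_spec, b)
      if (is.character(v)) v else format_qdb_number(v)
    }, "")
    names(predicted) <- ids
    experimental <- if (spec$model_type == "regression") {
      stats::setNames(format_qdb_number(y), ids)
    } else {
      cuts <- eq_spec$cuts
      labs <- eq_spec$labels
      stats::setNames(vapply(y, function(v) {
        idx <- which(v <= cuts)
        if (length(idx)) labs[idx[1]] else labs[length(labs)]
      }, ""), ids)
    }
    compounds <- lapply(seq_len(n), function(i)
      qdb_compound(ids[i], name = sprintf("Alkane %d", i),
                   description = sprintf("synthetic alkane compound %d", i),
                   labels = "synthetic",
                   cas = fixture_cas(i), inchi = fixture_inchi(i),
                   smiles = paste(rep("C", i), collapse = "")))
    property <- qdb_property(
      "p1", name = "Toxic potency",
      description = "synthetic endpoint generated from a linear model",
      labels = "synthetic", endpoint_category = "toxicity",
      endpoint_name = "log(1/IGC50)",
      values = qdb_values(ids, unname(experimental)), ucum = "mol/l")
    descriptors <- lapply(seq_len(d), function(j)
      qdb_descriptor(desc_ids[j], name = sprintf("Descriptor %s", desc_ids[j]),
                     description = sprintf("synthetic descriptor N(%g, %g)",
                                           spec$descriptors[[j]]$mean,
                                           spec$descriptors[[j]]$sd),
                     labels = "synthetic", application = "mock/1.0",
                     values = structure(list(ids = ids,
                                             values = desc_txt[[j]]),
                                        class = "qdb_values")))
    model <- qdb_model("m1", property_id = "p1", descriptor_ids = desc_ids,
                       name = "Linear model",
                       description = "synthetic linear model with exact coefficients",
                       labels = "synthetic", equation = equation)
    predictions <- list()
    for (kind in SET_KINDS) {
      sel <- subset_ids[[kind]]
      if (!length(sel)) next
      predictions[[length(predictions) + 1L]] <- qdb_prediction(
        kind, model_id = "m1", set_kind = kind,
        name = sprintf("%s set", kind),
        description = sprintf("predictions for the %s subset", kind),
        labels = "synthetic", application = "qdbtools/0.1",
        values = structure(list(ids = sel,
                                values = unname(predicted[sel])),
                           class = "qdb_values"))
    }
    archive <- qdb_archive(
      name = "Synthetic linear QSAR archive",
      description = sprintf(
        "generated fixture: %d compounds, %d descriptors, noise sd %g, seed %d",
        n, d, spec$noise_sd, spec$seed),
      compounds = compounds, properties = list(property),
      descriptors = descriptors, models = list(model),
      predictions = predictions,
      bibliography = bibliography_record(
        "article", "synthetic2014",
        fields = list(author = "Doe, J.; Roe, R.",
                      title = "A synthetic linear structure-activity model",
                      journal = "Journal of Synthetic Examples",
                      year = "2014", doi = "10.0000/synthetic.0001")))
    apply_defects(archive, spec$defects)
  })
}

apply_defects <- function(archive, defects) {
  for (def in defects) {
    if (def == "drop-inchi") {
      archive$compounds[[1]] <- set_null(archive$compounds[[1]], "inchi")
    } else if (def == "bad-cas") {
      cas <- archive$compounds[[1]]$cas
      last <- as.integer(substr(cas, nchar(cas), nchar(cas)))
      archive$compounds[[1]]$cas <-
        paste0(substr(cas, 1, nchar(cas) - 1), (last + 1) %% 10)
    } else if (def == "tamper-prediction") {
      pred <- archive$predictions[[1]]
      vt <- parse_values(pred$cargos[["values"]])
      vt$values[1] <- format_qdb_number(as.numeric(vt$values[1]) + 1.0)
      archive$predictions[[1]]$cargos[["values"]] <- format_values(vt)
    } else if (def == "orphan-cargo") {
      archive$compounds[[1]]$cargos <-
        set_null(archive$compounds[[1]]$cargos, "notes")
    } else if (def == "dangling-weak-ref") {
      prop <- archive$properties[[1]]
      archive$properties[[1]]$cargos[["values"]] <-
        paste0(prop$cargos[["values"]], "zz-unknown\t1.0\n")
    }
  }
  archive
}

#' Harvest archive-level metadata
#'
#' Collects the record a repository would index for an archive: the
#' endpoint, the model types, the software applications that produced
#' descriptors and predictions, the registry sizes, and the bibliography
#' record when one is present.
#'
#' @param archive a `qdb_archive`.
#' @return a `qdb_metadata` list.
#' @export
harvest_metadata <- function(archive) {
  endpoints <- unlist(lapply(archive$properties, function(p)
    p$endpoint_name), use.names = FALSE)
  model_types <- unique(unlist(lapply(archive$models, function(m) {
    eq <- cargo_payload(m, "equation")
    if (is.null(eq)) return(NULL)
    spec <- tryCatch(parse_equation(eq), qdb_error = function(e) NULL)
    if (is.null(spec)) NULL else spec$model_type
  }), use.names = FALSE))
  software <- unique(c(
    unlist(lapply(archive$descriptors, function(x) x$application),
           use.names = FALSE),
    unlist(lapply(archive$predictions, function(x) x$application),
           use.names = FALSE)))
  structure(list(
    endpoint = if (length(endpoints)) endpoints[1] else NULL,
    model_types = as.character(model_types %||% character(0)),
    software = as.character(software %||% character(0)),
    n_compounds = length(archive$compounds),
    n_properties = length(archive$properties),
    n_descriptors = length(archive$descriptors),
    n_models = length(archive$models),
    n_predictions = length(archive$predictions),
    bibliography = archive$bibliography), class = "qdb_metadata")
}

#' Training data of a model as a data frame
#'
#' Rows are the model's training compounds with complete descriptor rows
#' and a non-missing experimental value; columns are `compound_id`, `y`
#' (experimental property) and one column per descriptor. Convenient for
#' refitting the model externally (e.g. with `lm`).
#'
#' @param archive a `qdb_archive`.
#' @param model a `qdb_model` or model id.
#' @return a data frame.
#' @export
training_frame <- function(archive, model) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  desc_num <- model_descriptor_numeric(archive, model)
  preds <- Filter(function(p) identical(p$set_kind, "training"),
                  model_predictions(archive, model))
  train_ids <- unique(unlist(lapply(preds, function(p) {
    vt <- parsed_values_or_null(p)
    if (is.null(vt)) character(0) else vt$ids
  })))
  train_ids <- registry_ordered(train_ids, archive)
  prop <- archive$properties[[model$property_id %||% ""]]
  yv <- if (is.null(prop)) NULL else parsed_values_or_null(prop)
  y <- if (is.null(yv)) stats::setNames(numeric(0), character(0))
       else values_numeric(yv)
  rows <- lapply(train_ids, function(cid) {
    x <- descriptor_row(desc_num, cid)
    yy <- if (cid %in% names(y)) y[[cid]] else NA_real_
    if (anyNA(x) || is.na(yy)) return(NULL)
    df <- data.frame(compound_id = cid, y = yy, stringsAsFactors = FALSE)
    for (j in seq_along(model$descriptor_ids))
      df[[model$descriptor_ids[j]]] <- x[j]
    df
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    df <- data.frame(compound_id = character(0), y = numeric(0))
    for (id in model$descriptor_ids) df[[id]] <- numeric(0)
    return(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check recovery of generating coefficients
#'
#' Compares coefficients fitted externally (e.g. ordinary least squares on
#' [training_frame] output) against the generating coefficients of a
#' fixture spec.
#'
#' @param spec the [fixture_spec] that generated the data
#'   (regression type).
#' @param fitted_coefficients numeric vector `c(intercept, w1, ..., wd)`.
#' @return a list: `errors` (per-coefficient absolute error, named
#'   `intercept` then descriptor ids), `max_error`, and `saturated`
#'   (`TRUE` when the training subset has at most `d + 1` rows, i.e. the
#'   fit interpolates).
#' @export
parameter_recovery_check <- function(spec, fitted_coefficients) {
  stopifnot(inherits(spec, "qdb_fixture_spec"))
  if (spec$model_type != "regression")
    qdb_stop("spec_error", "recovery check applies to regression specs only")
  if (length(fitted_coefficients) != length(spec$coefficients))
    qdb_stop("spec_error",
             sprintf("expected %d fitted coefficients, got %d",
                     length(spec$coefficients), length(fitted_coefficients)))
  errors <- abs(as.numeric(fitted_coefficients) - spec$coefficients)
  names(errors) <- c("intercept",
                     vapply(spec$descriptors, `[[`, "", "id"))
  n_tr <- max(2L, round(spec$split[[1]] * spec$n_compounds))
  list(errors = errors, max_error = max(errors),
       saturated = n_tr <= length(spec$descriptors) + 1L)
}
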