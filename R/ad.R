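# Applicability-domain analytics.
#
# The AD of a model is characterized in descriptor space from its training
# compounds only; validation/testing/external points are scored against it.
# Leverage uses the intercept-augmented training design (the Williams-plot
# convention, warning threshold h* = 3(d+1)/n); the Mahalanobis distance
# uses the training sample covariance. Singular designs fall back to the
# Moore-Penrose pseudo-inverse with a singularity flag so degenerate toy
# archives never crash.

model_descriptor_numeric <- function(archive, model) {
  out <- lapply(archive$descriptors[model$descriptor_ids], function(d) {
    if (is.null(d)) return(stats::setNames(numeric(0), character(0)))
    vt <- parsed_values_or_null(d)
    if (is.null(vt)) stats::setNames(numeric(0), character(0))
    else values_numeric(vt)
  })
  names(out) <- model$descriptor_ids
  out
}

descriptor_row <- function(desc_num, cid) {
  vapply(desc_num, function(v) if (cid %in% names(v)) v[[cid]] else NA_real_,
         numeric(1))
}

registry_ordered <- function(ids, archive) {
  known <- ids[ids %in% names(archive$compounds)]
  c(known[order(match(known, names(archive$compounds)))],
    ids[!ids %in% names(archive$compounds)])
}

model_predictions <- function(archive, model)
  Filter(function(p) identical(p$model_id, model$id), archive$predictions)

#' Fit applicability-domain parameters for a model
#'
#' Estimates the AD reference quantities from the model's training
#' compounds (those keyed in its training-set prediction cargo) that have
#' complete descriptor rows: the descriptor centroid, the sample
#' covariance (divisor `n - 1`), the inverse of `X'X` for the
#' intercept-augmented training matrix, the leverage warning threshold
#' `3(d+1)/n`, and the training RMSE (stored experimental vs stored
#' predicted values).
#'
#' @param archive a `qdb_archive`.
#' @param model a `qdb_model` or model id.
#' @return a `qdb_ad_parameters` list: `descriptor_ids`, `n`, `d`,
#'   `training_ids`, `training_matrix`, `centroid`, `covariance`,
#'   `cov_inverse`, `xtx_inverse`, `warning_leverage`, `training_rmse`,
#'   `singular` (TRUE when any pseudo-inverse path was taken).
#' @export
fit_ad <- function(archive, model) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  desc_num <- model_descriptor_numeric(archive, model)
  d <- length(model$descriptor_ids)
  if (d == 0)
    qdb_stop("insufficient_training", "model declares no descriptors")
  preds <- model_predictions(archive, model)
  train_ids <- unique(unlist(lapply(
    Filter(function(p) identical(p$set_kind, "training"), preds),
    function(p) {
      vt <- parsed_values_or_null(p)
      if (is.null(vt)) character(0) else vt$ids
    })))
  train_ids <- registry_ordered(train_ids, archive)
  rows <- lapply(train_ids, descriptor_row, desc_num = desc_num)
  complete <- !vapply(rows, anyNA, TRUE)
  train_ids <- train_ids[complete]
  n <- length(train_ids)
  if (n < 2L)
    qdb_stop("insufficient_training",
             sprintf("only %d complete training descriptor rows (need >= 2)", n))
  X <- do.call(rbind, rows[complete])
  dimnames(X) <- list(train_ids, model$descriptor_ids)
  centroid <- colMeans(X)
  covariance <- stats::cov(X)
  singular <- FALSE
  Xa <- cbind(1, X)
  xtx <- crossprod(Xa)
  xtx_inverse <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(xtx_inverse) || qr(Xa)$rank < d + 1L) {
    xtx_inverse <- MASS::ginv(xtx)
    singular <- TRUE
  }
  cov_inverse <- tryCatch(solve(covariance), error = function(e) NULL)
  if (is.null(cov_inverse) || qr(covariance)$rank < d) {
    cov_inverse <- MASS::ginv(covariance)
    singular <- TRUE
  }
  training_rmse <- NA_real_
  prop <- archive$properties[[model$property_id %||% ""]]
  if (!is.null(prop)) {
    yv <- parsed_values_or_null(prop)
    train_pred <- Filter(function(p) identical(p$set_kind, "training"), preds)
    if (!is.null(yv) && length(train_pred)) {
      pv <- parsed_values_or_null(train_pred[[1]])
      if (!is.null(pv)) {
        st <- tryCatch(regression_stats(yv, pv), qdb_error = function(e) NULL)
        if (!is.null(st)) training_rmse <- st$rmse
      }
    }
  }
  structure(list(descriptor_ids = model$descriptor_ids, n = n, d = d,
                 training_ids = train_ids, training_matrix = X,
                 centroid = centroid, covariance = covariance,
                 cov_inverse = cov_inverse, xtx_inverse = xtx_inverse,
                 warning_leverage = 3 * (d + 1) / n,
                 training_rmse = training_rmse, singular = singular),
            class = "qdb_ad_parameters")
}

check_dim <- function(params, x) {
  if (length(x) != params$d)
    qdb_stop("dimension_mismatch",
             sprintf("descriptor vector has length %d, model expects %d",
                     length(x), params$d))
  as.numeric(x)
}

#' Leverage of a descriptor vector
#'
#' `h = [1, x] (X'X)^-1 [1, x]'` for the intercept-augmented training
#' design; the diagonal of the hat matrix when `x` is a training row.
#'
#' @param params `qdb_ad_parameters` from [fit_ad].
#' @param x numeric descriptor vector (model's descriptor order).
#' @return leverage (non-negative scalar).
#' @export
ad_leverage <- function(params, x) {
  x <- check_dim(params, x)
  xa <- c(1, x)
  as.numeric(xa %*% params$xtx_inverse %*% xa)
}

#' Mahalanobis distance of a descriptor vector
#'
#' Distance from the training centroid under the training sample
#' covariance: `sqrt((x - c)' S^-1 (x - c))`.
#'
#' @inheritParams ad_leverage
#' @return distance (non-negative scalar).
#' @export
ad_mahalanobis <- function(params, x) {
  x <- check_dim(params, x)
  diff <- x - params$centroid
  sqrt(max(0, as.numeric(diff %*% params$cov_inverse %*% diff)))
}

#' Williams-plot data for a model
#'
#' One applicability-domain profile per compound appearing in any
#' prediction of the model, in compound-registry order: leverage and
#' Mahalanobis distance (where the descriptor row is complete), stored
#' predicted value, experimental value, residual and standardized residual
#' (residual / training RMSE) where the experimental value exists, and the
#' subset membership. Compounds without experimental values still carry
#' their distance and prediction -- the points of a Gramatica/Insubria
#' graph.
#'
#' @param archive a `qdb_archive`.
#' @param model a `qdb_model` or model id.
#' @param params optional precomputed [fit_ad] parameters.
#' @return data frame with columns `compound_id`, `set_kind`, `leverage`,
#'   `mahalanobis`, `predicted`, `experimental`, `residual`,
#'   `std_residual`, plus attribute `warning_leverage`.
#' @export
williams_data <- function(archive, model, params = NULL) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  if (is.null(params)) params <- fit_ad(archive, model)
  desc_num <- model_descriptor_numeric(archive, model)
  preds <- model_predictions(archive, model)
  set_of <- character(0)
  pred_val <- numeric(0)
  for (p in preds) {
    vt <- parsed_values_or_null(p)
    if (is.null(vt)) next
    pv <- values_numeric(vt)
    new <- setdiff(vt$ids, names(set_of))
    set_of[new] <- p$set_kind %||% NA_character_
    pred_val[new] <- pv[new]
  }
  ids <- registry_ordered(names(set_of), archive)
  prop <- archive$properties[[model$property_id %||% ""]]
  yv <- if (is.null(prop)) NULL else parsed_values_or_null(prop)
  y <- if (is.null(yv)) stats::setNames(numeric(0), character(0))
       else values_numeric(yv)
  rows <- lapply(ids, function(cid) {
    x <- descriptor_row(desc_num, cid)
    lev <- mah <- NA_real_
    if (!anyNA(x)) {
      lev <- ad_leverage(params, x)
      mah <- ad_mahalanobis(params, x)
    }
    exp_v <- if (cid %in% names(y)) y[[cid]] else NA_real_
    prd_v <- pred_val[[cid]]
    res <- if (!is.na(exp_v) && !is.na(prd_v)) exp_v - prd_v else NA_real_
    std <- if (!is.na(res) && is.finite(params$training_rmse) &&
               params$training_rmse > 0) res / params$training_rmse
           else NA_real_
    data.frame(compound_id = cid, set_kind = set_of[[cid]], leverage = lev,
               mahalanobis = mah, predicted = prd_v, experimental = exp_v,
               residual = res, std_residual = std, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character(0), set_kind = character(0),
               leverage = numeric(0), mahalanobis = numeric(0),
               predicted = numeric(0), experimental = numeric(0),
               residual = numeric(0), std_residual = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "warning_leverage") <- params$warning_leverage
  out
}

#' Euclidean nearest neighbours in descriptor space
#'
#' Ranks the archive's compounds (those with complete descriptor rows for
#' the model) by raw Euclidean distance from a query descriptor vector.
#' Ties are broken by compound-registry order. Each neighbour carries its
#' stored experimental and predicted values where available.
#'
#' @param archive a `qdb_archive`.
#' @param model a `qdb_model` or model id.
#' @param x numeric query vector in the model's descriptor order.
#' @param k number of neighbours (clamped to the dataset size).
#' @param scale if `TRUE`, z-score descriptor columns (and the query) by
#'   the dataset mean and standard deviation before computing distances;
#'   default `FALSE` (raw descriptor values).
#' @return data frame with columns `compound_id`, `distance`,
#'   `experimental`, `predicted`, ordered by increasing distance.
#' @export
similar_compounds <- function(archive, model, x, k = 5, scale = FALSE) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  stopifnot(k >= 1)
  desc_num <- model_descriptor_numeric(archive, model)
  ids <- names(archive$compounds)
  rows <- lapply(ids, descriptor_row, desc_num = desc_num)
  complete <- !vapply(rows, anyNA, TRUE)
  ids <- ids[complete]
  if (!length(ids))
    qdb_stop("insufficient_training",
             "no compound has a complete descriptor row for this model")
  X <- do.call(rbind, rows[complete])
  x <- as.numeric(x)
  if (length(x) != ncol(X))
    qdb_stop("dimension_mismatch",
             sprintf("query vector has length %d, model expects %d",
                     length(x), ncol(X)))
  if (scale) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sd, "/")
    x <- (x - mu) / sd
  }
  dist <- sqrt(rowSums(sweep(X, 2, x)^2))
  ord <- order(dist, seq_along(dist))[seq_len(min(k, length(ids)))]
  prop <- archive$properties[[model$property_id %||% ""]]
  yv <- if (is.null(prop)) NULL else parsed_values_or_null(prop)
  y <- if (is.null(yv)) stats::setNames(numeric(0), character(0))
       else values_numeric(yv)
  pred_val <- stats::setNames(numeric(0), character(0))
  for (p in model_predictions(archive, model)) {
    vt <- parsed_values_or_null(p)
    if (is.null(vt)) next
    pv <- values_numeric(vt)
    new <- setdiff(vt$ids, names(pred_val))
    pred_val[new] <- pv[new]
  }
  data.frame(
    compound_id = ids[ord],
    distance = unname(dist[ord]),
    experimental = vapply(ids[ord], function(i)
      if (i %in% names(y)) y[[i]] else NA_real_, numeric(1)),
    predicted = vapply(ids[ord], function(i)
      if (i %in% names(pred_val)) pred_val[[i]] else NA_real_, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
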