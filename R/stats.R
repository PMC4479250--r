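# Prediction summary statistics: regression fit measures over the key
# intersection of an experimental and a predicted values table, confusion
# matrices for classification models, and residual tables for residual
# plots. These are the "prediction statistics" a repository front end
# displays per model and per data subset.

numeric_overlap <- function(experimental, predicted) {
  y <- values_numeric(experimental)
  yhat <- values_numeric(predicted)
  keys <- intersect(names(y), names(yhat))
  keys <- keys[!is.na(y[keys]) & !is.na(yhat[keys])]
  if (!length(keys))
    qdb_stop("no_overlap",
             "experimental and predicted tables share no scored compounds")
  list(keys = keys, y = unname(y[keys]), yhat = unname(yhat[keys]))
}

#' Regression statistics over paired values tables
#'
#' Computes, over the compounds present and non-missing in both tables:
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `rmse = sqrt(mean((y - yhat)^2))` and `mae = mean(abs(y - yhat))`.
#' `r2` may be negative for external subsets and is reported as computed.
#'
#' @param experimental,predicted numeric [qdb_values] tables.
#' @return a `qdb_regression_stats` list: `n`, `r2`, `rmse`, `mae`.
#' @export
regression_stats <- function(experimental, predicted) {
  ov <- numeric_overlap(experimental, predicted)
  y <- ov$y; yhat <- ov$yhat
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    qdb_stop("zero_variance",
             "experimental values are constant: r2 is undefined")
  sse <- sum((y - yhat)^2)
  structure(list(n = length(y),
                 r2 = 1 - sse / sst,
                 rmse = sqrt(sse / length(y)),
                 mae = mean(abs(y - yhat))),
            class = "qdb_regression_stats")
}

#' @export
print.qdb_regression_stats <- function(x, ...) {
  cat(sprintf("n = %d, r2 = %.4f, rmse = %.4g, mae = %.4g\n",
              x$n, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' Confusion matrix over paired categorical values tables
#'
#' @param experimental,predicted categorical [qdb_values] tables.
#' @return a `qdb_confusion` list: `labels` (sorted union of observed
#'   labels) and `counts` (square actual-by-predicted integer matrix).
#' @export
confusion_matrix <- function(experimental, predicted) {
  actual <- values_labels(experimental)
  pred <- values_labels(predicted)
  keys <- intersect(names(actual), names(pred))
  keys <- keys[!is.na(actual[keys]) & !is.na(pred[keys])]
  if (!length(keys))
    qdb_stop("no_overlap",
             "experimental and predicted tables share no scored compounds")
  labels <- sort(unique(c(actual[keys], pred[keys])))
  counts <- table(factor(actual[keys], levels = labels),
                  factor(pred[keys], levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(actual = labels, predicted = labels))
  structure(list(labels = labels, counts = counts), class = "qdb_confusion")
}

#' Classification accuracy of a confusion matrix
#'
#' @param x a `qdb_confusion`.
#' @return fraction of scored compounds on the diagonal.
#' @export
confusion_accuracy <- function(x) {
  stopifnot(inherits(x, "qdb_confusion"))
  sum(diag(x$counts)) / sum(x$counts)
}

#' @export
print.qdb_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted):\n")
  print(x$counts)
  cat(sprintf("accuracy = %.4f\n", confusion_accuracy(x)))
  invisible(x)
}

#' Residual table over paired numeric values tables
#'
#' Residual = experimental - predicted, per compound present and
#' non-missing in both tables (the data behind a residual plot).
#'
#' @param experimental,predicted numeric [qdb_values] tables.
#' @return a [qdb_values] table of residuals.
#' @export
residuals_table <- function(experimental, predicted) {
  ov <- numeric_overlap(experimental, predicted)
  qdb_values(ov$keys, ov$y - ov$yhat)
}
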