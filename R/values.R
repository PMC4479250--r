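# Values tables: the "values" cargo of Property, Descriptor and Prediction
# containers. A table maps compound ids to values. Values are kept as the
# exact decimal text found in the cargo so that archives round-trip without
# any float re-formatting; "N/A" marks a missing value.

NA_MARKER <- "N/A"

#' Construct a values table
#'
#' @param ids character vector of compound ids (unique, order preserved).
#' @param values vector of values: numbers, category labels, or `NA` for
#'   missing. Numbers are rendered to decimal text with
#'   [format_qdb_number]; character input is stored verbatim.
#' @return a `qdb_values` object: list with elements `ids` and `values`
#'   (both character; missing encoded as `"N/A"`).
#' @export
qdb_values <- function(ids = character(0), values = character(0)) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    qdb_stop("cargo_parse_error", "duplicate compound id in values table")
  if (length(values) != length(ids))
    qdb_stop("cargo_parse_error", "ids and values differ in length")
  if (is.numeric(values)) {
    txt <- ifelse(is.na(values), NA_MARKER, format_qdb_number(values))
  } else {
    txt <- as.character(values)
    txt[is.na(txt)] <- NA_MARKER
  }
  structure(list(ids = ids, values = txt), class = "qdb_values")
}

#' Render numbers as canonical decimal text
#'
#' Values cargos store decimal text; this is the renderer the package uses
#' whenever it has to turn a computed double into cargo text (up to 10
#' significant digits, no scientific notation surprises beyond what
#' `%.10g` produces).
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
format_qdb_number <- function(x) sprintf("%.10g", x)

#' Numeric view of a values table
#'
#' @param values a [qdb_values] table.
#' @return named numeric vector; `"N/A"` entries become `NA`. Text that does
#'   not parse as a number also becomes `NA` (use [values_labels] for
#'   categorical tables).
#' @export
values_numeric <- function(values) {
  out <- suppressWarnings(as.numeric(values$values))
  out[values$values == NA_MARKER] <- NA_real_
  stats::setNames(out, values$ids)
}

#' Categorical view of a values table
#'
#' @param values a [qdb_values] table.
#' @return named character vector with `NA` for missing.
#' @export
values_labels <- function(values) {
  out <- values$values
  out[out == NA_MARKER] <- NA_character_
  stats::setNames(out, values$ids)
}

#' Does a values table hold numbers?
#'
#' A table is numeric when every non-missing entry parses as a finite
#' number.
#'
#' @param values a [qdb_values] table.
#' @return logical scalar (`TRUE` for an empty table).
#' @export
values_is_numeric <- function(values) {
  txt <- values$values[values$values != NA_MARKER]
  if (!length(txt)) return(TRUE)
  num <- suppressWarnings(as.numeric(txt))
  all(!is.na(num) & is.finite(num))
}

#' Parse a values cargo
#'
#' The cargo dialect is two-column TSV, one row per compound:
#' `<compound-id>\t<value>`. An optional header row `id\tvalue` is skipped.
#' `"N/A"` marks a missing value.
#'
#' @param text cargo payload as a single string (UTF-8 text).
#' @return a [qdb_values] table.
#' @export
parse_values <- function(text) {
  if (is.raw(text)) text <- rawToChar(text)
  if (!is.character(text) || length(text) != 1L)
    qdb_stop("cargo_parse_error", "values cargo payload must be text")
  if (!validUTF8(text))
    qdb_stop("cargo_parse_error", "values cargo is not valid UTF-8")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(lines[1], "id\tvalue"))
    lines <- lines[-1]
  if (!length(lines)) return(qdb_values())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol != 2L))
    qdb_stop("cargo_parse_error",
             sprintf("values cargo row %d has %d columns, expected 2",
                     which(ncol != 2L)[1], ncol[ncol != 2L][1]))
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids))
    qdb_stop("cargo_parse_error",
             sprintf("duplicate compound id '%s' in values cargo",
                     ids[duplicated(ids)][1]))
  structure(list(ids = ids, values = vals), class = "qdb_values")
}

#' Serialize a values table to cargo text
#'
#' Inverse of [parse_values]: values are emitted verbatim as stored, so a
#' parse/format round trip is byte-exact.
#'
#' @param values a [qdb_values] table (or cargo text, returned unchanged).
#' @return a single string of TSV lines terminated by `"\n"` (empty string
#'   for an empty table).
#' @export
format_values <- function(values) {
  if (is.character(values) && length(values) == 1L) return(values)
  stopifnot(inherits(values, "qdb_values"))
  if (!length(values$ids)) return("")
  paste0(paste(values$ids, values$values, sep = "\t", collapse = "\n"), "\n")
}

#' @export
print.qdb_values <- function(x, ...) {
  cat(sprintf("<qdb_values> %d entries\n", length(x$ids)))
  n <- min(6L, length(x$ids))
  if (n) cat(paste0("  ", x$ids[seq_len(n)], " = ", x$values[seq_len(n)],
                    collapse = "\n"), if (length(x$ids) > n) "\n  ..." else "",
             "\n", sep = "")
  invisible(x)
}

#' @export
length.qdb_values <- function(x) length(x$ids)
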