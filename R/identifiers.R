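# Chemical identifier checks used by basic validation. Both checks are
# deliberately dependency-free: CAS numbers are verified with the registry
# check-digit algorithm, InChI strings against the layered grammar only (no
# chemistry-semantic verification, which would require a structure engine).

#' Validate a CAS Registry Number
#'
#' Checks both the shape (`2-7 digits "-" 2 digits "-" 1 digit`) and the
#' registry check digit: the last digit must equal the sum of the other
#' digits weighted by their position counted from the right, modulo 10.
#'
#' @param cas character vector of candidate CAS numbers.
#' @return logical vector.
#' @export
validate_cas <- function(cas) {
  vapply(cas, function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    check <- digits[n]
    body <- digits[-n]
    weights <- rev(seq_along(body))
    sum(body * weights) %% 10 == check
  }, logical(1), USE.NAMES = FALSE)
}

#' Compute the CAS check digit for a digit body
#'
#' Utility for constructing valid CAS numbers (used by the fixture
#' generator): given the digits before the check digit (hyphens ignored),
#' returns the digit that makes the number checksum-valid.
#'
#' @param body character scalar of 4-9 digits (optionally hyphenated).
#' @return integer check digit in `0:9`.
#' @export
cas_check_digit <- function(body) {
  digits <- as.integer(strsplit(gsub("-", "", body), "")[[1]])
  sum(digits * rev(seq_along(digits))) %% 10L
}

#' Validate InChI syntax
#'
#' Accepts the layered InChI grammar: prefix `InChI=1` or `InChI=1S`,
#' followed by `/` and a non-empty formula layer, followed by zero or more
#' layers of the form `/<letter><payload>`. Purely syntactic; no
#' chemistry-semantic verification is attempted.
#'
#' @param inchi character vector.
#' @return logical vector.
#' @export
validate_inchi_syntax <- function(inchi) {
  !is.na(inchi) &
    grepl("^InChI=1S?/[A-Za-z0-9.]+(/[a-zA-Z][^/]*)*$", inchi)
}
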