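# Classed conditions used throughout the package. Every error carries the
# class "qdb_error" plus a specific subclass so callers can dispatch with
# tryCatch(..., qdb_unresolved_reference = ...).

qdb_stop <- function(subclass, message, ...) {
  data <- list(...)
  cond <- structure(
    class = c(paste0("qdb_", subclass), "qdb_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}
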