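# Minimal deterministic ZIP container writer.
#
# Archives must be byte-identical for identical content (hash-based tests,
# reproducible deposits), which rules out system zip tools with their
# timestamps and platform quirks. Entries are stored uncompressed (method 0)
# with the DOS epoch timestamp (1980-01-01 00:00:00); the caller fixes entry
# order. Reading uses utils::unzip (internal method), which understands this
# subset.

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L))
        bitwXor(bitwShiftR(crc, 1L), poly) else bitwShiftR(crc, 1L)
    }
    tab[i + 1L] <- crc
  }
  .crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

uint_bytes <- function(x, n) {
  # little-endian raw encoding of a non-negative number
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# DOS date 1980-01-01: day 1, month 1, year offset 0 -> 0x0021; time 0.
DOS_DATE <- uint_bytes(33, 2)
DOS_TIME <- uint_bytes(0, 2)

#' Write a ZIP container deterministically
#'
#' @param entries named list of payloads (raw vectors or single strings);
#'   names are the entry paths, written in list order.
#' @param path output file path.
#' @return `path`, invisibly.
#' @keywords internal
zip_write <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  sizes <- numeric(length(entries))
  offset <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
    offsets[i] <- offset
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    header <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
                uint_bytes(20, 2),          # version needed
                uint_bytes(0, 2),           # flags
                uint_bytes(0, 2),           # method: stored
                DOS_TIME, DOS_DATE,
                uint_bytes(crcs[i], 4),
                uint_bytes(sizes[i], 4),    # compressed size
                uint_bytes(sizes[i], 4),    # uncompressed size
                uint_bytes(length(name), 2),
                uint_bytes(0, 2))           # extra length
    writeBin(header, con)
    writeBin(name, con)
    if (sizes[i]) writeBin(data, con)
    offset <- offset + length(header) + length(name) + sizes[i]
  }
  cd_start <- offset
  cd_size <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    rec <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
             uint_bytes(20, 2), uint_bytes(20, 2),
             uint_bytes(0, 2), uint_bytes(0, 2),
             DOS_TIME, DOS_DATE,
             uint_bytes(crcs[i], 4),
             uint_bytes(sizes[i], 4), uint_bytes(sizes[i], 4),
             uint_bytes(length(name), 2),
             uint_bytes(0, 2), uint_bytes(0, 2),  # extra, comment
             uint_bytes(0, 2), uint_bytes(0, 2),  # disk, internal attrs
             uint_bytes(0, 4),                    # external attrs
             uint_bytes(offsets[i], 4))
    writeBin(rec, con)
    writeBin(name, con)
    cd_size <- cd_size + length(rec) + length(name)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            uint_bytes(0, 2), uint_bytes(0, 2),
            uint_bytes(length(entries), 2), uint_bytes(length(entries), 2),
            uint_bytes(cd_size, 4), uint_bytes(cd_start, 4),
            uint_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

#' List and extract a ZIP container
#'
#' @param path ZIP file path.
#' @return named list of raw payloads keyed by entry path.
#' @keywords internal
zip_read <- function(path) {
  listing <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e)
                        qdb_stop("format_error",
                                 sprintf("not a readable ZIP container: %s", path)))
  names <- listing$Name[!grepl("/$", listing$Name)]
  exdir <- tempfile("qdbzip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir)
  out <- vector("list", length(names))
  names(out) <- names
  for (nm in names) {
    f <- file.path(exdir, nm)
    out[[nm]] <- readBin(f, "raw", n = file.info(f)$size)
  }
  out
}

is_zip_file <- function(path) {
  if (dir.exists(path)) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  length(magic) == 4 && identical(magic[1:2], as.raw(c(0x50, 0x4b)))
}
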