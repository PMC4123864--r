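# Internal helpers: classed error conditions, little-endian binary output,
# and a minimal ZIP container writer (stored entries) used by the packager.

dwca_abort <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "dwca_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

usage_error      <- function(msg) dwca_abort(msg, "dwca_usage_error")
input_error      <- function(msg) dwca_abort(msg, "dwca_input_error")
encoding_error   <- function(msg) dwca_abort(msg, "dwca_encoding_error")
parse_error      <- function(msg) dwca_abort(msg, "dwca_parse_error")
schema_error     <- function(msg) dwca_abort(msg, "dwca_schema_error")
descriptor_error <- function(msg) dwca_abort(msg, "dwca_descriptor_error")
archive_error    <- function(msg) dwca_abort(msg, "dwca_archive_error")
packaging_error  <- function(msg) dwca_abort(msg, "dwca_packaging_error")
metadata_error   <- function(msg) dwca_abort(msg, "dwca_metadata_error")
arity_error      <- function(msg) dwca_abort(msg, "dwca_arity_error")
join_error       <- function(msg) dwca_abort(msg, "dwca_join_error")
io_error         <- function(msg) dwca_abort(msg, "dwca_io_error")

dwca_log <- function(...) {
  if (isTRUE(getOption("dwca.verbose", FALSE))) {
    message("[dwca] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unsigned integer (as double) to n little-endian raw bytes.
uint_le <- function(x, n) {
  x <- as.numeric(x)
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# CRC-32 of a raw vector, read from the trailer of the gzip stream that
# memCompress produces (last 8 bytes: CRC32 then length, both little-endian).
crc32_raw <- function(bytes) {
  gz <- memCompress(bytes, type = "gzip")
  trailer <- gz[(length(gz) - 7L):(length(gz) - 4L)]
  sum(as.numeric(trailer) * 256^(0:3))
}

# Fixed DOS timestamp for zip entries so identical inputs produce
# byte-identical archives.
.zip_dos_date <- bitwOr(bitwOr(bitwShiftL(2014L - 1980L, 9L), bitwShiftL(8L, 5L)), 6L)

# Write a zip file whose entries are stored (uncompressed).  `entries` is a
# named list mapping entry name -> raw vector of file content.  Entry names
# are flat (no directories), matching descriptor locations exactly.
zip_write <- function(path, entries) {
  con <- tryCatch(file(path, "wb"), error = function(e) io_error(
    paste0("cannot open '", path, "' for writing: ", conditionMessage(e))))
  on.exit(close(con), add = TRUE)
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  sizes <- numeric(length(entries))
  pos <- 0
  nm <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    stopifnot(is.raw(data))
    name_raw <- charToRaw(nm[[i]])
    crcs[i] <- crc32_raw(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),  # local file header signature
      uint_le(20, 2),                      # version needed
      uint_le(0, 2),                       # flags
      uint_le(0, 2),                       # method: stored
      uint_le(0, 2),                       # mod time
      uint_le(.zip_dos_date, 2),           # mod date
      uint_le(crcs[i], 4),
      uint_le(sizes[i], 4),                # compressed size
      uint_le(sizes[i], 4),                # uncompressed size
      uint_le(length(name_raw), 2),
      uint_le(0, 2)                        # extra length
    )
    writeBin(c(header, name_raw, data), con)
    pos <- pos + length(header) + length(name_raw) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name_raw <- charToRaw(nm[[i]])
    rec <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),  # central directory signature
      uint_le(20, 2), uint_le(20, 2),      # made by / needed
      uint_le(0, 2), uint_le(0, 2),        # flags, method
      uint_le(0, 2), uint_le(.zip_dos_date, 2),
      uint_le(crcs[i], 4),
      uint_le(sizes[i], 4), uint_le(sizes[i], 4),
      uint_le(length(name_raw), 2),
      uint_le(0, 2), uint_le(0, 2),        # extra, comment
      uint_le(0, 2), uint_le(0, 2),        # disk, internal attrs
      uint_le(0, 4),                       # external attrs
      uint_le(offsets[i], 4)
    )
    writeBin(c(rec, name_raw), con)
    pos <- pos + length(rec) + length(name_raw)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    uint_le(0, 2), uint_le(0, 2),
    uint_le(length(entries), 2), uint_le(length(entries), 2),
    uint_le(pos - cd_start, 4),
    uint_le(cd_start, 4),
    uint_le(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

# Read a whole file as a raw vector.
read_file_raw <- function(path) {
  readBin(path, what = "raw", n = file.info(path)$size)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Deterministic hex digest of a string (md5 over a temp file; base R has no
# in-memory digest).
string_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(charToRaw(x), tf)
  unname(tools::md5sum(tf))
}

# Run code with a temporarily seeded RNG, restoring prior RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
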