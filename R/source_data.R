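# Source-data access: delimited-text dialects, dialect sniffing, and a
# dialect-exact row reader/writer.  Quality problems (ragged rows, bad IDs)
# deliberately pass through here and are surfaced by the validator.

.sniff_candidates <- c("\t", ",", ";", "|")

#' Construct a text dialect
#'
#' Describes how a delimited text file is cut into rows and fields.  The
#' same dialect model backs the archive descriptor's fieldsTerminatedBy /
#' fieldsEnclosedBy / linesTerminatedBy / ignoreHeaderLines / encoding
#' attributes.
#'
#' @param field_delimiter Single delimiter character (default tab).
#' @param quote_character Single quoting character or `NULL` for no quoting.
#'   Inside a quoted field the quote character is doubled.
#' @param line_terminator `"LF"` or `"CRLF"`.
#' @param encoding IANA charset name; `"UTF-8"` unless overridden.
#' @param header_lines Number of leading lines to skip when reading data.
#' @return An object of class `dwca_dialect`.
#' @export
text_dialect <- function(field_delimiter = "\t", quote_character = "\"",
                         line_terminator = c("LF", "CRLF"),
                         encoding = "UTF-8", header_lines = 1L) {
  line_terminator <- match.arg(line_terminator)
  if (!is_string(field_delimiter) || nchar(field_delimiter) != 1L) {
    usage_error("field_delimiter must be a single character")
  }
  if (!is.null(quote_character) &&
      (!is_string(quote_character) || nchar(quote_character) > 1L)) {
    usage_error("quote_character must be a single character or NULL")
  }
  if (!is.null(quote_character) && !nzchar(quote_character)) quote_character <- NULL
  if (identical(field_delimiter, quote_character)) {
    usage_error("field_delimiter and quote_character must differ")
  }
  header_lines <- as.integer(header_lines)
  if (is.na(header_lines) || header_lines < 0L) {
    usage_error("header_lines must be a non-negative integer")
  }
  structure(
    list(field_delimiter = field_delimiter, quote_character = quote_character,
         line_terminator = line_terminator, encoding = encoding,
         header_lines = header_lines),
    class = "dwca_dialect"
  )
}

#' @export
print.dwca_dialect <- function(x, ...) {
  show <- function(ch) switch(ch, "\t" = "\\t", ch)
  cat("<dwca_dialect> delimiter='", show(x$field_delimiter),
      "' quote=", if (is.null(x$quote_character)) "none" else paste0("'", x$quote_character, "'"),
      " lines=", x$line_terminator, " encoding=", x$encoding,
      " header_lines=", x$header_lines, "\n", sep = "")
  invisible(x)
}

# Split one line into fields under a dialect.  Handles doubled quote
# characters inside quoted fields.  Errors on an unterminated quote.
split_fields <- function(line, delim, quote = NULL, line_no = NA) {
  if (is.null(quote) || !grepl(quote, line, fixed = TRUE)) {
    return(strsplit(paste0(line, "\x01"), delim, fixed = TRUE)[[1]] |>
             (\(f) { f[length(f)] <- sub("\x01$", "", f[length(f)]); f })())
  }
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  fields <- character(0)
  buf <- character(0)
  in_quote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == quote) {
        if (i < n && chars[i + 1L] == quote) {  # doubled quote -> literal
          buf <- c(buf, quote)
          i <- i + 1L
        } else {
          in_quote <- FALSE
        }
      } else {
        buf <- c(buf, ch)
      }
    } else if (ch == quote) {
      in_quote <- TRUE
    } else if (ch == delim) {
      fields <- c(fields, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  if (in_quote) {
    parse_error(paste0("unterminated quoted field",
                       if (!is.na(line_no)) paste0(" at line ", line_no) else ""))
  }
  c(fields, paste(buf, collapse = ""))
}

# Quote/escape one row of fields for writing under a dialect.
join_fields <- function(fields, delim, quote = NULL) {
  if (any(grepl("[\r\n]", fields))) {
    packaging_error("field values may not contain line terminators")
  }
  if (!is.null(quote)) {
    needs <- grepl(delim, fields, fixed = TRUE) | grepl(quote, fields, fixed = TRUE)
    fields[needs] <- paste0(quote,
                            gsub(quote, paste0(quote, quote), fields[needs], fixed = TRUE),
                            quote)
  } else if (any(grepl(delim, fields, fixed = TRUE))) {
    packaging_error("field value contains the delimiter and the dialect has no quote character")
  }
  paste(fields, collapse = delim)
}

read_lines_dialect <- function(path, encoding = "UTF-8", n = -1L) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, n = n, warn = FALSE)
  # BOM strip + declared-encoding conversion
  if (length(lines) && substring(lines[1], 1, 1) == "\ufeff") {
    lines[1] <- substring(lines[1], 2)
  }
  if (length(lines) && substr(lines[1], 1, 3) == "\xef\xbb\xbf") {
    lines[1] <- substring(lines[1], 4)
  }
  if (!identical(toupper(encoding), "UTF-8")) {
    lines <- iconv(lines, from = encoding, to = "UTF-8")
  } else {
    bad <- which(!validUTF8(lines))
    if (length(bad)) {
      prior <- if (bad[1] > 1L) sum(nchar(lines[seq_len(bad[1] - 1L)], type = "bytes") + 1L) else 0L
      raw_line <- charToRaw(lines[bad[1]])
      off <- which(raw_line > as.raw(0x7f))[1] %||% 1L
      encoding_error(paste0("input is not valid UTF-8 near byte offset ",
                            prior + off, " (line ", bad[1], ")"))
    }
  }
  gsub("\r$", "", lines)
}

#' Detect the dialect of a delimited text file
#'
#' The delimiter is chosen from tab, comma, semicolon and pipe as the
#' candidate giving the most consistent (and widest) per-line field count
#' over the first 50 lines.  Quoting is assumed to be the double-quote
#' character when quoting changes how sampled lines split.  One header line
#' is assumed.  Encoding is UTF-8 unless a byte-order mark or decode failure
#' indicates otherwise.
#'
#' @param path Path to a non-empty delimited text file.
#' @return A [text_dialect()].
#' @export
sniff_dialect <- function(path) {
  if (!file.exists(path)) input_error(paste0("no such file: ", path))
  if (file.info(path)$size == 0) input_error(paste0("file is empty: ", path))
  first <- readBin(path, what = "raw", n = 4L)
  encoding <- "UTF-8"
  if (length(first) >= 2 &&
      (identical(first[1:2], as.raw(c(0xff, 0xfe))) ||
       identical(first[1:2], as.raw(c(0xfe, 0xff))))) {
    encoding <- "UTF-16"
  }
  lines <- read_lines_dialect(path, encoding = encoding, n = 50L)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) input_error(paste0("file has no content lines: ", path))

  crlf <- {
    head_raw <- readBin(path, what = "raw",
                        n = min(file.info(path)$size, 4096L))
    any(head_raw == as.raw(0x0d))
  }

  score <- function(delim, quote) {
    arity <- vapply(lines, function(l) {
      tryCatch(length(split_fields(l, delim, quote)),
               dwca_parse_error = function(e) -1L)
    }, integer(1), USE.NAMES = FALSE)
    tab <- table(arity[arity > 0L])
    modal <- if (length(tab)) as.integer(names(tab)[which.max(tab)]) else 0L
    list(uniform = length(unique(arity)) == 1L && arity[1] > 0L,
         modal = modal,
         share = if (length(arity)) max(0, sum(arity == modal)) / length(arity) else 0,
         vec = arity)
  }
  # Rank candidates: a delimiter that actually splits lines (modal arity > 1)
  # beats one that does not; then consistency, then width.
  cand_key <- function(s) {
    c(as.numeric(s$modal > 1L && s$uniform), as.numeric(s$modal > 1L),
      s$share, s$modal)
  }
  key_gt <- function(a, b) {
    d <- which(a != b)
    length(d) > 0L && a[d[1]] > b[d[1]]
  }
  best <- NULL
  best_key <- NULL
  for (delim in .sniff_candidates) {
    quoted <- score(delim, "\"")
    plain <- score(delim, NULL)
    uses_quote <- !identical(quoted$vec, plain$vec) ||
      (quoted$uniform && !plain$uniform)
    key <- cand_key(quoted)
    if (is.null(best) || key_gt(key, best_key)) {
      best <- list(delim = delim, quote = if (uses_quote) "\"" else NULL)
      best_key <- key
    }
  }
  text_dialect(field_delimiter = best$delim, quote_character = best$quote,
               line_terminator = if (crlf) "CRLF" else "LF",
               encoding = encoding, header_lines = 1L)
}

#' Describe a delimited source table
#'
#' Binds a file to a dialect (sniffed when not supplied) and records its
#' header names and data row count.  Header names are trimmed; duplicate
#' headers after trimming and case-folding are an error.
#'
#' @param path Path to the delimited file.
#' @param dialect Optional [text_dialect()] override; sniffed when `NULL`.
#' @return An object of class `dwca_source_table` with fields `path`,
#'   `dialect`, `headers` and `row_count`.
#' @export
source_table <- function(path, dialect = NULL) {
  dialect <- dialect %||% sniff_dialect(path)
  lines <- read_lines_dialect(path, encoding = dialect$encoding)
  headers <- character(0)
  if (dialect$header_lines > 0L && length(lines) >= 1L) {
    headers <- trimws(split_fields(lines[1], dialect$field_delimiter,
                                   dialect$quote_character, line_no = 1L))
    norm <- tolower(headers)
    if (anyDuplicated(norm)) {
      input_error(paste0("duplicate column headers after normalization: ",
                         paste(unique(headers[duplicated(norm)]), collapse = ", ")))
    }
  }
  n_data <- max(length(lines) - dialect$header_lines, 0L)
  structure(
    list(path = path, dialect = dialect, headers = headers,
         row_count = n_data),
    class = "dwca_source_table"
  )
}

#' Read the data rows of a source table
#'
#' Splits each data line into fields exactly per the table's dialect,
#' skipping header lines.  Field whitespace is preserved; ragged rows pass
#' through unchanged (see [check_row_arity()]).  The whole table is held in
#' memory, which is comfortable at the desk scale this package targets.
#'
#' @param table A [source_table()].
#' @param callback Optional function called as `callback(fields, row_number)`
#'   for each row; when supplied, rows are not accumulated and `NULL` is
#'   returned invisibly.
#' @return A list of character vectors (one per data row), unless `callback`
#'   is given.
#' @export
read_rows <- function(table, callback = NULL) {
  d <- table$dialect
  lines <- read_lines_dialect(table$path, encoding = d$encoding)
  if (length(lines) <= d$header_lines) {
    return(if (is.null(callback)) list() else invisible(NULL))
  }
  data_lines <- lines[(d$header_lines + 1L):length(lines)]
  out <- split_lines(data_lines, d$field_delimiter, d$quote_character,
                     first_line_no = d$header_lines + 1L)
  if (is.null(callback)) {
    return(out)
  }
  for (i in seq_along(out)) callback(out[[i]], i)
  invisible(NULL)
}

# Split many lines at once: a vectorized strsplit for lines without the
# quote character, a C-level quoted-field parse (scan) for the rest.
split_lines <- function(data_lines, delim, quote, first_line_no = 1L) {
  n <- length(data_lines)
  out <- vector("list", n)
  quoted <- if (is.null(quote)) rep(FALSE, n) else
    grepl(quote, data_lines, fixed = TRUE)
  plain <- which(!quoted)
  if (length(plain)) {
    # sentinel keeps trailing empty fields that strsplit would drop
    sp <- strsplit(paste0(data_lines[plain], "\x01"), delim, fixed = TRUE)
    out[plain] <- lapply(sp, function(f) {
      f[length(f)] <- substr(f[length(f)], 1L, nchar(f[length(f)]) - 1L)
      f
    })
  }
  for (i in which(quoted)) {
    out[[i]] <- withCallingHandlers(
      scan(text = data_lines[i], what = character(), sep = delim,
           quote = quote, quiet = TRUE, na.strings = character(),
           strip.white = FALSE),
      warning = function(w) {
        if (grepl("EOF within quoted string", conditionMessage(w))) {
          parse_error(paste0("unterminated quoted field at line ",
                             first_line_no + i - 1L))
        }
        invokeRestart("muffleWarning")
      })
  }
  out
}

# Serialize rows (list of character vectors) to delimited text under a
# dialect; returns a single string including the trailing line terminator.
format_delimited <- function(rows, dialect, headers = NULL) {
  eol <- if (dialect$line_terminator == "CRLF") "\r\n" else "\n"
  all_rows <- c(if (!is.null(headers)) list(headers) else list(), rows)
  body <- vapply(all_rows, join_fields, character(1),
                 delim = dialect$field_delimiter,
                 quote = dialect$quote_character)
  if (!length(body)) return("")
  paste0(paste(body, collapse = eol), eol)
}

write_delimited <- function(rows, path, dialect, headers = NULL) {
  txt <- format_delimited(rows, dialect, headers)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}
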