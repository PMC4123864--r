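# Validator: the publication-blocking record-identifier checks, archive
# integrity checks and controlled-vocabulary flagging.  Identifier equality
# is exact string comparison — identifiers are opaque, and normalizing them
# would mask exactly the publisher errors these checks exist to surface.

ISSUE_KINDS <- c("missing_id", "duplicate_id", "orphan_extension_row",
                 "arity_mismatch", "vocabulary_flag")

dwca_issue <- function(kind, severity, detail, file = NA_character_,
                       row = NA_integer_, value = NA_character_) {
  stopifnot(kind %in% ISSUE_KINDS, severity %in% c("error", "warning"))
  data.frame(kind = kind, severity = severity, file = file,
             row = as.integer(row), value = value, detail = detail,
             stringsAsFactors = FALSE)
}

#' Assemble a validation report
#'
#' The verdict is `halt` exactly when any issue has severity `error`;
#' otherwise `pass`.
#'
#' @param issues A data frame of issues (columns `kind`, `severity`, `file`,
#'   `row`, `value`, `detail`) or a list of such one-row frames.
#' @return An object of class `dwca_validation_report` with fields `issues`,
#'   `counts` (named integer vector over all issue kinds) and `verdict`.
#' @export
validation_report <- function(issues = NULL) {
  if (is.null(issues) || (is.list(issues) && !is.data.frame(issues) && !length(issues))) {
    issues <- dwca_issue("missing_id", "error", "x")[0, ]
  } else if (!is.data.frame(issues)) {
    issues <- do.call(rbind, issues)
  }
  counts <- vapply(ISSUE_KINDS, function(k) sum(issues$kind == k), integer(1))
  verdict <- if (any(issues$severity == "error")) "halt" else "pass"
  structure(list(issues = issues, counts = counts, verdict = verdict),
            class = "dwca_validation_report")
}

#' @export
print.dwca_validation_report <- function(x, ...) {
  cat("<dwca_validation_report> verdict:", x$verdict, "\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    for (k in names(nz)) cat("  ", k, ": ", nz[[k]], "\n", sep = "")
  } else {
    cat("  no issues\n")
  }
  invisible(x)
}

merge_reports <- function(...) {
  reports <- list(...)
  validation_report(do.call(rbind, lapply(reports, `[[`, "issues")))
}

#' Check record identifiers for missing and duplicate values
#'
#' An empty or whitespace-only identifier yields one `missing_id` error for
#' that row.  An identifier occurring k >= 2 times yields one `duplicate_id`
#' error per involved row (all k of them), so reports are actionable row by
#' row.  Comparison is exact and case-sensitive, with no trimming.
#'
#' @param ids Character vector of record identifiers in row order.
#' @param file Optional file label carried into issues.
#' @return A [validation_report()]; verdict `halt` when any issue was found.
#' @examples
#' check_record_ids(c("a", "b", "b", ""))$counts
#' @export
check_record_ids <- function(ids, file = NA_character_) {
  ids <- as.character(ids)
  missing <- which(is.na(ids) | !nzchar(trimws(ids)))
  present <- setdiff(seq_along(ids), missing)
  tab <- table(ids[present])
  dup_vals <- names(tab)[tab >= 2L]
  dup_rows <- present[ids[present] %in% dup_vals]
  issues <- list()
  for (r in missing) {
    issues[[length(issues) + 1L]] <- dwca_issue(
      "missing_id", "error", "record has no identifier", file = file, row = r)
  }
  for (r in dup_rows) {
    issues[[length(issues) + 1L]] <- dwca_issue(
      "duplicate_id", "error",
      paste0("identifier '", ids[r], "' occurs ", tab[[ids[r]]], " times"),
      file = file, row = r, value = ids[r])
  }
  validation_report(issues)
}

#' Check extension rows against core identifiers
#'
#' Every extension row whose coreid matches no core record id is an
#' `orphan_extension_row` warning; a row with an empty coreid is an
#' `orphan_extension_row` error (the row is structurally meaningless).
#'
#' @param a An open [open_archive()] handle.
#' @return A [validation_report()].
#' @export
check_extension_integrity <- function(a) {
  core <- read_descriptor_file(a, a$descriptor$core)
  id_set <- unique(core$ids)
  issues <- list()
  for (fd in a$descriptor$extensions) {
    ext <- read_descriptor_file(a, fd)
    for (r in seq_along(ext$ids)) {
      cid <- ext$ids[r]
      if (!nzchar(cid)) {
        issues[[length(issues) + 1L]] <- dwca_issue(
          "orphan_extension_row", "error",
          paste0("extension row has an empty coreid (", fd$row_type, ")"),
          file = fd$location, row = r)
      } else if (!(cid %in% id_set)) {
        issues[[length(issues) + 1L]] <- dwca_issue(
          "orphan_extension_row", "warning",
          paste0("coreid '", cid, "' matches no core record (", fd$row_type, ")"),
          file = fd$location, row = r, value = cid)
      }
    }
  }
  validation_report(issues)
}

#' Check row field counts against an expected arity
#'
#' @param rows List of character vectors (one per data row), e.g. from
#'   [read_rows()].
#' @param expected_arity Expected number of fields per row (>= 1).
#' @param file Optional file label carried into issues.
#' @return A [validation_report()] with one `arity_mismatch` error per
#'   deviating row.
#' @export
check_row_arity <- function(rows, expected_arity, file = NA_character_) {
  expected_arity <- as.integer(expected_arity)
  if (is.na(expected_arity) || expected_arity < 1L) {
    usage_error("expected_arity must be >= 1")
  }
  issues <- list()
  for (r in seq_along(rows)) {
    n <- length(rows[[r]])
    if (n != expected_arity) {
      issues[[length(issues) + 1L]] <- dwca_issue(
        "arity_mismatch", "error",
        paste0("row has ", n, " fields, expected ", expected_arity),
        file = file, row = r)
    }
  }
  validation_report(issues)
}

vocab_normalize <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

#' Load a controlled vocabulary
#'
#' A vocabulary is a canonical value list plus a synonym table.  With no
#' arguments, loads the bundled demonstration country vocabulary (ISO
#' 3166-1 alpha-2 codes with common verbatim country-name synonyms).
#'
#' @param canonical_path Plain-text file, one canonical value per line
#'   (`#` comments allowed).
#' @param synonyms_path CSV with columns `synonym,canonical`.
#' @return An object of class `dwca_vocabulary` with fields `canonical` and
#'   `synonyms` (named character vector keyed by normalized synonym).
#' @export
load_vocabulary <- function(canonical_path = NULL, synonyms_path = NULL) {
  canonical_path <- canonical_path %||%
    system.file("extdata", "vocab", "country_codes.txt", package = "dwca",
                mustWork = TRUE)
  synonyms_path <- synonyms_path %||%
    system.file("extdata", "vocab", "country_synonyms.csv", package = "dwca",
                mustWork = TRUE)
  canon <- readLines(canonical_path, warn = FALSE, encoding = "UTF-8")
  canon <- trimws(canon[!grepl("^\\s*(#|$)", canon)])
  syn <- utils::read.csv(synonyms_path, stringsAsFactors = FALSE,
                         encoding = "UTF-8")
  synonyms <- stats::setNames(syn$canonical, vocab_normalize(syn$synonym))
  # canonical values are synonyms of themselves under normalization
  self_syn <- stats::setNames(canon, vocab_normalize(canon))
  synonyms <- c(synonyms, self_syn[!(names(self_syn) %in% names(synonyms))])
  structure(list(canonical = canon, synonyms = synonyms),
            class = "dwca_vocabulary")
}

#' Flag non-canonical values against a controlled vocabulary
#'
#' Each distinct value that is not exactly a canonical vocabulary entry is
#' flagged once (a warning carrying the number of rows using it).  When the
#' value's normalized form (case-folded, punctuation and whitespace removed)
#' matches a synonym, the canonical form is suggested; otherwise the flag
#' carries no suggestion.  Input values are never rewritten.
#'
#' @param values Character vector of field values in row order.
#' @param vocab A [load_vocabulary()] result.
#' @return A list with `report` (a [validation_report()] of
#'   `vocabulary_flag` warnings) and `suggestions` (named character vector
#'   mapping flagged value to suggested canonical form, absent when there is
#'   no suggestion).
#' @export
check_vocabulary <- function(values, vocab) {
  if (!length(vocab$canonical)) usage_error("vocabulary is empty")
  values <- as.character(values)
  keep <- nzchar(values)
  tab <- table(values[keep])
  flagged <- names(tab)[!(names(tab) %in% vocab$canonical)]
  issues <- list()
  suggestions <- character(0)
  for (v in flagged) {
    canon <- unname(vocab$synonyms[vocab_normalize(v)])
    if (!length(canon)) canon <- NA_character_
    if (!is.na(canon)) suggestions[[v]] <- canon
    issues[[length(issues) + 1L]] <- dwca_issue(
      "vocabulary_flag", "warning",
      paste0("non-canonical value used in ", tab[[v]], " row(s)",
             if (!is.na(canon)) paste0("; suggest '", canon, "'") else ""),
      value = v)
  }
  list(report = validation_report(issues), suggestions = suggestions)
}

#' Validate an archive end to end
#'
#' Runs the identifier check on the core, the arity check on every data
#' file, and the extension-integrity check, merging all findings into one
#' report.
#'
#' @param a An open [open_archive()] handle, or a path accepted by
#'   [open_archive()].
#' @return A [validation_report()].
#' @export
validate_archive <- function(a) {
  if (!inherits(a, "dwca_archive")) a <- open_archive(a)
  core_fd <- a$descriptor$core
  core <- read_descriptor_file(a, core_fd)
  reports <- list(check_record_ids(core$ids, file = core_fd$location))
  for (fd in c(list(core_fd), a$descriptor$extensions)) {
    tab <- structure(
      list(path = file.path(a$dir, fd$location), dialect = fd$dialect,
           headers = character(0), row_count = NA_integer_),
      class = "dwca_source_table"
    )
    rows <- read_rows(tab)
    bound <- vapply(fd$bindings, function(b) b$index %||% 0L, integer(1))
    expected <- max(c(fd$id_column, bound)) + 1L
    reports[[length(reports) + 1L]] <-
      check_row_arity(rows, expected, file = fd$location)
  }
  reports[[length(reports) + 1L]] <- check_extension_integrity(a)
  do.call(merge_reports, reports)
}
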