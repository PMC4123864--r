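# Mapping engine: binds source columns to Darwin Core terms and projects
# source rows into standardized records.  Automatic matching follows the
# same-name rule: a header maps to a term when the two names agree after
# case-folding and removal of spaces and underscores — nothing fuzzier.

norm_name <- function(x) gsub("[ _]", "", tolower(trimws(x)))

#' Construct a field mapping
#'
#' Binds one Darwin Core term to either a source column (1-based index) or a
#' constant value — exactly one of the two.  A column binding may carry a
#' default used when the column's field is empty.
#'
#' @param term A [dwc_term()].
#' @param column 1-based column index into the source headers, or `NULL`.
#' @param constant Constant value applied to every record, or `NULL`.
#' @param default Default for empty fields (column bindings only).
#' @return An object of class `dwca_field_mapping`.
#' @export
field_mapping <- function(term, column = NULL, constant = NULL, default = NULL) {
  if (is.null(column) == is.null(constant)) {
    usage_error("exactly one of column or constant must be given")
  }
  if (!is.null(constant) && !is.null(default)) {
    usage_error("a constant-source mapping takes no default_value")
  }
  if (!is.null(column)) {
    column <- as.integer(column)
    if (is.na(column) || column < 1L) usage_error("column index must be >= 1")
  }
  structure(
    list(term = term, column = column, constant = constant, default = default),
    class = "dwca_field_mapping"
  )
}

#' Construct a mapping set
#'
#' @param schema Target [dwc_schema()].
#' @param mappings List of [field_mapping()] objects.
#' @param id_column Optional 1-based index of the record-identifier column.
#' @param n_columns Number of source columns (for range checking); taken
#'   from `headers` when given.
#' @param headers Optional source header names.
#' @param unmapped Headers that matched no term (bookkeeping from
#'   [auto_map()]).
#' @return An object of class `dwca_mapping_set`.
#' @export
mapping_set <- function(schema, mappings = list(), id_column = NULL,
                        n_columns = NULL, headers = NULL, unmapped = character(0)) {
  if (!is.null(headers) && is.null(n_columns)) n_columns <- length(headers)
  structure(
    list(schema = schema, mappings = mappings,
         id_column = if (is.null(id_column)) NULL else as.integer(id_column),
         n_columns = if (is.null(n_columns)) NULL else as.integer(n_columns),
         headers = headers, unmapped = unmapped),
    class = "dwca_mapping_set"
  )
}

#' Automatically map source headers to schema terms
#'
#' Each header whose normalized form (case-fold, spaces and underscores
#' removed) equals a term's normalized simple name is bound to that term.
#' Headers with no same-name term are listed as unmapped, never guessed.
#' When the schema's identifier term is among the matches, its column is
#' also recorded as the record-identifier column.
#'
#' @param headers Character vector of source column names (unique after
#'   normalization).
#' @param schema Target [dwc_schema()].
#' @return A [mapping_set()] whose `unmapped` field lists unmatched headers.
#' @examples
#' ms <- auto_map(c("scientificName", "eventDate", "my_notes"),
#'                builtin_schemas()$occurrence)
#' length(ms$mappings)  # 2
#' ms$unmapped          # "my_notes"
#' @export
auto_map <- function(headers, schema) {
  headers <- as.character(headers)
  norm_h <- norm_name(headers)
  if (anyDuplicated(norm_h)) {
    usage_error("headers are not unique after normalization")
  }
  norm_t <- vapply(schema$terms, function(t) norm_name(t$simple_name), character(1))
  mappings <- list()
  unmapped <- character(0)
  id_column <- NULL
  for (i in seq_along(headers)) {
    hit <- which(norm_t == norm_h[i])
    if (length(hit)) {
      term <- schema$terms[[hit[1L]]]
      mappings[[length(mappings) + 1L]] <- field_mapping(term, column = i)
      if (!is.null(schema$id_term) &&
          identical(term$qualified_name, schema$id_term$qualified_name)) {
        id_column <- i
      }
    } else {
      unmapped <- c(unmapped, headers[i])
    }
  }
  mapping_set(schema, mappings, id_column = id_column, headers = headers,
              unmapped = unmapped)
}

#' Check a mapping set for problems
#'
#' Issues are returned as data, not raised: a term bound twice; a column
#' index outside the header range; no identifier column although the schema
#' designates an identifier term (an error for core data publication, a
#' warning for metadata-only publication); a constant binding whose constant
#' is empty.
#'
#' @param ms A [mapping_set()].
#' @param core_data Logical; `FALSE` relaxes the missing-identifier issue to
#'   a warning (metadata-only publication).
#' @return A data frame with columns `kind`, `severity`, `detail`; zero rows
#'   when the mapping is clean.
#' @export
validate_mapping <- function(ms, core_data = TRUE) {
  issues <- list()
  add <- function(kind, severity, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      kind = kind, severity = severity, detail = detail,
      stringsAsFactors = FALSE)
  }
  quals <- vapply(ms$mappings, function(m) m$term$qualified_name, character(1))
  for (q in unique(quals[duplicated(quals)])) {
    add("duplicate_term", "error", paste0("term bound more than once: ", q))
  }
  if (!is.null(ms$n_columns)) {
    for (m in ms$mappings) {
      if (!is.null(m$column) && m$column > ms$n_columns) {
        add("column_out_of_range", "error",
            paste0("column ", m$column, " for term ", m$term$simple_name,
                   " exceeds the ", ms$n_columns, " source columns"))
      }
    }
    if (!is.null(ms$id_column) && ms$id_column > ms$n_columns) {
      add("column_out_of_range", "error",
          paste0("id column ", ms$id_column, " exceeds the ",
                 ms$n_columns, " source columns"))
    }
  }
  schema_quals <- vapply(ms$schema$terms, function(t) t$qualified_name, character(1))
  bad <- setdiff(quals, schema_quals)
  for (q in bad) {
    add("foreign_term", "error",
        paste0("mapped term does not belong to the schema: ", q))
  }
  if (!is.null(ms$schema$id_term) && is.null(ms$id_column)) {
    add("missing_id_column", if (core_data) "error" else "warning",
        paste0("no record-identifier column designated although the schema's ",
               "identifier term is ", ms$schema$id_term$simple_name))
  }
  for (m in ms$mappings) {
    if (!is.null(m$constant) && !nzchar(m$constant)) {
      add("empty_constant", "error",
          paste0("constant mapping for ", m$term$simple_name, " is empty"))
    }
  }
  if (!length(issues)) {
    return(data.frame(kind = character(0), severity = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Project a source row into a standardized record
#'
#' Applies each mapping: column bindings take the row's field (or the
#' mapping's default when the field is empty), constant bindings take their
#' constant for every row.  The record identifier is taken verbatim (no
#' trimming) from the identifier column.
#'
#' @param row Character vector of source fields.
#' @param ms A [mapping_set()] with no error-severity issues.
#' @param row_number Row number used in error messages.
#' @return A list with `values` (named character vector keyed by qualified
#'   term name) and `id` (record identifier string, or `NA` when no
#'   identifier column is set).
#' @export
apply_mapping <- function(row, ms, row_number = NA) {
  needed <- c(vapply(ms$mappings, function(m) m$column %||% 0L, integer(1)),
              ms$id_column %||% 0L)
  if (length(row) < max(needed, 0L)) {
    arity_error(paste0("row", if (!is.na(row_number)) paste0(" ", row_number),
                       " has ", length(row), " fields but the mapping needs column ",
                       max(needed)))
  }
  values <- character(0)
  for (m in ms$mappings) {
    v <- if (!is.null(m$constant)) {
      m$constant
    } else {
      f <- row[[m$column]]
      if (!nzchar(f) && !is.null(m$default)) m$default else f
    }
    values[[m$term$qualified_name]] <- v
  }
  id <- if (!is.null(ms$id_column)) row[[ms$id_column]] else NA_character_
  list(values = values, id = id)
}
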