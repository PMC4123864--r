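# Publisher: orchestrates a publication event — read, map, validate,
# package, version — plus schedule arithmetic and the registry-registration
# document.  Published versions are immutable: a republication always
# creates version n+1, and a halted run never touches the version store.

SCHEDULE_INTERVALS <- c("annually", "biannually", "monthly", "weekly", "daily", "off")

#' Read and validate a resource configuration
#'
#' A resource configuration is a YAML document naming the source file(s),
#' the core type, the metadata, and optionally explicit mappings, a dialect
#' override, a publication schedule and a legacy registry identifier.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return The configuration list (class `dwca_resource_config`).
#' @export
read_resource_config <- function(config) {
  if (is_string(config)) {
    if (!file.exists(config)) io_error(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) usage_error("resource config must be a list or a YAML file path")
  if (is.null(config$name) || !nzchar(config$name)) {
    usage_error("resource config needs a 'name'")
  }
  if (grepl("[^A-Za-z0-9_-]", config$name)) {
    usage_error("resource name may contain only letters, digits, '-' and '_'")
  }
  config$core_type <- config$core_type %||% "occurrence"
  if (!config$core_type %in% c("occurrence", "taxon")) {
    usage_error("core_type must be 'occurrence' or 'taxon'")
  }
  if (is.null(config$core_source)) usage_error("resource config needs 'core_source'")
  if (is.null(config$metadata)) usage_error("resource config needs 'metadata'")
  structure(config, class = c("dwca_resource_config", "list"))
}

config_metadata <- function(config) {
  md <- config$metadata
  if (is_string(md)) return(parse_eml(md))
  creators <- md$creators
  if (is.null(creators) && !is.null(md$creator)) creators <- list(md$creator)
  eml_metadata(
    title = md$title, creators = creators, abstract = md$abstract,
    rights = md$rights, geographic_coverage = md$geographic_coverage,
    taxonomic_coverage = md$taxonomic_coverage,
    temporal_coverage = md$temporal_coverage, methods = md$methods,
    citation = md$citation, language = md$language,
    keywords = unlist(md$keywords) %||% NULL)
}

config_dialect <- function(dialect_cfg) {
  if (is.null(dialect_cfg)) return(NULL)
  text_dialect(
    field_delimiter = dialect_cfg$field_delimiter %||% "\t",
    quote_character = dialect_cfg$quote_character %||% "\"",
    line_terminator = dialect_cfg$line_terminator %||% "LF",
    encoding = dialect_cfg$encoding %||% "UTF-8",
    header_lines = dialect_cfg$header_lines %||% 1L)
}

# Build the mapping set for a source: explicit config mapping if present,
# otherwise automatic same-name matching.
config_mapping <- function(tab, schema, mapping_cfg = NULL) {
  if (is.null(mapping_cfg)) return(auto_map(tab$headers, schema))
  mappings <- lapply(mapping_cfg$fields %||% list(), function(f) {
    term <- lookup_term(f$term, schema)
    if (is.null(term)) usage_error(paste0("mapping names unknown term: ", f$term))
    if (!is.null(f$column)) {
      col <- if (is.character(f$column)) match(f$column, tab$headers) else f$column
      if (is.na(col)) usage_error(paste0("mapping names unknown column: ", f$column))
      field_mapping(term, column = col, default = f$default)
    } else {
      field_mapping(term, constant = f$constant)
    }
  })
  idc <- mapping_cfg$id_column
  if (is.character(idc)) idc <- match(idc, tab$headers)
  mapping_set(schema, mappings, id_column = idc, headers = tab$headers)
}

# Map every row of a source table, returning records and the ids stream.
map_source <- function(tab, ms) {
  rows <- read_rows(tab)
  records <- vector("list", length(rows))
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    rec <- apply_mapping(rows[[i]], ms, row_number = i)
    records[[i]] <- rec
    ids[i] <- rec$id %||% NA_character_
  }
  list(records = records, ids = ids, rows = rows)
}

history_path <- function(base_dir, name) file.path(base_dir, name, "history.json")

read_history <- function(base_dir, name) {
  hp <- history_path(base_dir, name)
  if (!file.exists(hp)) return(list())
  jsonlite::fromJSON(hp, simplifyVector = FALSE)
}

#' List the published versions of a resource
#'
#' @param name Resource name.
#' @param base_dir Version-store directory.
#' @return List of published-version records, oldest first.
#' @export
list_versions <- function(name, base_dir) {
  read_history(base_dir, name)
}

#' Publish a resource
#'
#' Runs the full publication pipeline: read the source(s), map columns to
#' Darwin Core terms, validate (record identifiers, row arity, extension
#' integrity), package the archive, and record a new immutable version.  On
#' any error-severity finding no archive is produced, the version store is
#' left untouched, and the validation report is returned instead — the
#' publication halts.
#'
#' @param config Resource configuration ([read_resource_config()] input).
#' @param base_dir Version-store directory; one subdirectory per resource,
#'   one numbered subdirectory per version.
#' @param pinned_timestamp Optional ISO 8601 instant recorded as the
#'   publication time (for reproducible builds); defaults to the current
#'   UTC time.
#' @return On success, a `dwca_published_version` (list with
#'   `version_number`, `timestamp`, `archive_path`, `record_count`,
#'   `metadata_only` and `validation_digest`).  On halt, the
#'   [validation_report()].
#' @export
publish <- function(config, base_dir, pinned_timestamp = NULL) {
  config <- read_resource_config(config)
  schemas <- builtin_schemas()
  core_schema <- schemas[[config$core_type]]
  metadata <- config_metadata(config)

  core_tab <- source_table(config$core_source,
                           dialect = config_dialect(config$dialect))
  ms <- config_mapping(core_tab, core_schema, config$mapping)
  mapping_issues <- validate_mapping(ms, core_data = TRUE)
  if (any(mapping_issues$severity == "error")) {
    usage_error(paste0("mapping is not publishable: ",
                       paste(mapping_issues$detail, collapse = "; ")))
  }
  core <- map_source(core_tab, ms)

  reports <- list(
    check_record_ids(core$ids, file = basename(config$core_source)),
    check_row_arity(core$rows, length(core_tab$headers),
                    file = basename(config$core_source)))

  ext_records <- list()
  for (ext_cfg in config$extensions %||% list()) {
    rt <- ext_cfg$row_type %||% schemas$multimedia$row_type
    ext_schema <- NULL
    for (s in schemas) if (identical(s$row_type, rt)) ext_schema <- s
    if (is.null(ext_schema) && !is.null(ext_cfg$definition)) {
      ext_schema <- parse_extension_definition(ext_cfg$definition)
    }
    if (is.null(ext_schema)) {
      usage_error(paste0("unknown extension rowType: ", rt))
    }
    ext_tab <- source_table(ext_cfg$source,
                            dialect = config_dialect(ext_cfg$dialect))
    ext_ms <- config_mapping(ext_tab, ext_schema, ext_cfg$mapping)
    coreid_col <- ext_cfg$coreid_column %||% {
      hit <- which(tolower(ext_tab$headers) == "coreid")
      if (length(hit)) hit[1] else usage_error(
        paste0("extension source ", ext_cfg$source, " has no coreid column"))
    }
    if (is.character(coreid_col)) coreid_col <- match(coreid_col, ext_tab$headers)
    rows <- read_rows(ext_tab)
    reports[[length(reports) + 1L]] <-
      check_row_arity(rows, length(ext_tab$headers), file = basename(ext_cfg$source))
    ext_rows <- vector("list", length(rows))
    issues <- list()
    for (i in seq_along(rows)) {
      rec <- apply_mapping(rows[[i]], ext_ms, row_number = i)
      cid <- if (coreid_col <= length(rows[[i]])) rows[[i]][[coreid_col]] else ""
      ext_rows[[i]] <- list(coreid = cid, values = rec$values)
      if (!nzchar(cid)) {
        issues[[length(issues) + 1L]] <- dwca_issue(
          "orphan_extension_row", "error",
          paste0("extension row has an empty coreid (", rt, ")"),
          file = basename(ext_cfg$source), row = i)
      } else if (!(cid %in% core$ids)) {
        issues[[length(issues) + 1L]] <- dwca_issue(
          "orphan_extension_row", "warning",
          paste0("coreid '", cid, "' matches no core record (", rt, ")"),
          file = basename(ext_cfg$source), row = i, value = cid)
      }
    }
    reports[[length(reports) + 1L]] <- validation_report(issues)
    ext_records[[rt]] <- ext_rows
  }

  report <- do.call(merge_reports, reports)
  if (report$verdict == "halt") {
    return(report)
  }

  history <- read_history(base_dir, config$name)
  version_number <- length(history) + 1L
  timestamp <- pinned_timestamp %||%
    format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  # Stage everything, then move into the store only on full success.
  staging <- tempfile("dwca_publish_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  archive_tmp <- file.path(staging, "archive.zip")
  records <- lapply(seq_along(core$records), function(i) {
    list(id = core$ids[i], values = core$records[[i]]$values)
  })
  package_archive(records, ext_records, metadata, archive_tmp,
                  core_row_type = core_schema$row_type,
                  core_schema = core_schema)

  version_dir <- file.path(base_dir, config$name, paste0("v", version_number))
  version <- structure(
    list(version_number = version_number, timestamp = timestamp,
         archive_path = file.path(version_dir, "archive.zip"),
         record_count = length(records), metadata_only = FALSE,
         validation_digest = list(verdict = report$verdict,
                                  counts = as.list(report$counts))),
    class = "dwca_published_version")

  versions_all <- c(history, list(unclass(version)))
  summary_html <- render_summary_page(metadata, NULL, versions_all)
  report_json <- jsonlite::toJSON(
    list(verdict = report$verdict, counts = as.list(report$counts),
         issues = report$issues),
    auto_unbox = TRUE, pretty = TRUE, na = "null")

  if (!dir.create(version_dir, recursive = TRUE)) {
    io_error(paste0("cannot create version directory: ", version_dir))
  }
  ok <- file.copy(archive_tmp, file.path(version_dir, "archive.zip"))
  if (!ok) io_error("failed to move the packaged archive into the version store")
  writeLines(report_json, file.path(version_dir, "report.json"))
  writeLines(summary_html, file.path(version_dir, "summary.html"))
  jsonlite::write_json(versions_all, history_path(base_dir, config$name),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  version
}

#' @export
print.dwca_published_version <- function(x, ...) {
  cat("<dwca_published_version> v", x$version_number, " (", x$timestamp, "), ",
      x$record_count, " records\n", sep = "")
  invisible(x)
}

# Add whole calendar months, clamping the day to the target month's length.
add_months_clamped <- function(date, n) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L
  m <- lt$mon + n          # 0-based month arithmetic
  y <- y + m %/% 12L
  m <- m %% 12L
  last_day <- c(31L, if ((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0) 29L else 28L,
                31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m + 1L]
  as.Date(sprintf("%04d-%02d-%02d", y, m + 1L, min(lt$mday, last_day)))
}

#' Compute the next scheduled publication date
#'
#' Advances the last publication date by the configured interval: daily one
#' day, weekly seven days, monthly one calendar month (day-of-month clamped
#' to the target month's length), biannually six calendar months, annually
#' twelve.  Returns `NULL` when the schedule is off or nothing has been
#' published yet.
#'
#' @param schedule List with `interval` (one of `r toString(SCHEDULE_INTERVALS)`)
#'   and `last_published` (a `Date` or ISO date string, possibly `NULL`).
#' @return A `Date`, or `NULL`.
#' @examples
#' next_publication_date(list(interval = "monthly", last_published = "2014-01-31"))
#' @export
next_publication_date <- function(schedule) {
  interval <- schedule$interval %||% "off"
  if (!interval %in% SCHEDULE_INTERVALS) {
    usage_error(paste0("unknown schedule interval: ", interval))
  }
  if (identical(interval, "off") || is.null(schedule$last_published)) {
    return(NULL)
  }
  last <- as.Date(schedule$last_published)
  switch(interval,
         daily = last + 1L,
         weekly = last + 7L,
         monthly = add_months_clamped(last, 1L),
         biannually = add_months_clamped(last, 6L),
         annually = add_months_clamped(last, 12L))
}

#' Is a scheduled resource due for publication?
#'
#' @param schedule As for [next_publication_date()].
#' @param today Reference date (defaults to the current date).
#' @return `TRUE` when a next date exists and is not in the future.
#' @export
schedule_due <- function(schedule, today = Sys.Date()) {
  nxt <- next_publication_date(schedule)
  !is.null(nxt) && nxt <= as.Date(today)
}

format_uuid_from_hex <- function(hex32) {
  paste(substring(hex32, c(1, 9, 13, 17, 21), c(8, 12, 16, 20, 32)),
        collapse = "-")
}

#' Build the registry-registration document for a resource
#'
#' Emits the structured document a dataset registry needs to make the
#' resource discoverable: a stable identifier, the title, the publishing
#' organization and the access endpoint of the latest archive.  When the
#' configuration carries a registry identifier from a legacy publishing
#' method, that identifier is reused and marked as migrated so the existing
#' registry entry is maintained rather than duplicated.  No network call is
#' made; the caller delivers the document.
#'
#' @param config Resource configuration.
#' @param history Non-empty list of published versions.
#' @return A list (class `dwca_registry_record`) with fields `identifier`,
#'   `title`, `organization`, `endpoint`, `migrated` and (when migrated)
#'   `legacy_identifier`.
#' @export
registry_record <- function(config, history) {
  config <- read_resource_config(config)
  if (!length(history)) {
    usage_error("cannot register a resource with no published versions")
  }
  metadata <- config_metadata(config)
  legacy <- config$legacy_registry_id
  identifier <- if (!is.null(legacy)) {
    legacy
  } else {
    paste0("urn:uuid:", format_uuid_from_hex(string_md5(paste0("dwca-resource:", config$name))))
  }
  latest <- history[[length(history)]]
  structure(
    list(identifier = identifier,
         title = metadata$title,
         organization = config$organization %||%
           (metadata$creators[[1]]$organization %||% metadata$creators[[1]]$name),
         endpoint = latest$archive_path,
         migrated = !is.null(legacy),
         legacy_identifier = legacy),
    class = "dwca_registry_record")
}
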