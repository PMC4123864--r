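# Fixture generator: seeded synthetic occurrence / checklist datasets with
# controlled error injection, so the mapping, packaging, validation and
# publishing pipeline is testable without any download.  Errors are injected
# after clean generation at seeded positions, and the injection log is the
# ground truth — counts are recorded by construction, never re-derived.

#' Specify a synthetic dataset fixture
#'
#' @param core_type `"occurrence"` or `"taxon"`.
#' @param n_records Number of core records.
#' @param extension Optional list with `row_type` (default the Simple
#'   Multimedia rowType) and `mean_rows` (mean extension rows per core
#'   record, Poisson).
#' @param errors Counts of injected problems: `duplicate_ids` (rows whose id
#'   is overwritten with another row's id), `missing_ids`,
#'   `orphan_extension_rows`, `ragged_rows`, `noncanonical_country_values`.
#' @param seed Integer; fully determines the output.
#' @param dialect Output [text_dialect()] (default comma-separated, quoted).
#' @return An object of class `dwca_fixture_spec`.
#' @export
fixture_spec <- function(core_type = c("occurrence", "taxon"), n_records = 100L,
                         extension = NULL,
                         errors = list(), seed = 1L,
                         dialect = text_dialect(",", "\"", "LF", "UTF-8", 1L)) {
  core_type <- match.arg(core_type)
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L) usage_error("n_records must be >= 1")
  defaults <- list(duplicate_ids = 0L, missing_ids = 0L,
                   orphan_extension_rows = 0L, ragged_rows = 0L,
                   noncanonical_country_values = 0L)
  unknown <- setdiff(names(errors), names(defaults))
  if (length(unknown)) {
    usage_error(paste0("unknown error kinds: ", paste(unknown, collapse = ", ")))
  }
  errors <- utils::modifyList(defaults, lapply(errors, as.integer))
  if (any(unlist(errors) < 0L)) usage_error("error counts must be >= 0")
  # duplicates consume a target row and a distinct source row each
  core_slots <- 2L * errors$duplicate_ids + errors$missing_ids +
    errors$ragged_rows + errors$noncanonical_country_values
  if (core_slots > n_records) {
    usage_error("error counts exceed the number of core records")
  }
  if (errors$orphan_extension_rows > 0L && is.null(extension)) {
    usage_error("orphan_extension_rows requires an extension")
  }
  if (!is.null(extension)) {
    extension <- list(
      row_type = extension$row_type %||% builtin_schemas()$multimedia$row_type,
      mean_rows = extension$mean_rows %||% 1)
  }
  structure(
    list(core_type = core_type, n_records = n_records, extension = extension,
         errors = errors, seed = as.integer(seed), dialect = dialect),
    class = "dwca_fixture_spec"
  )
}

fixture_names <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- readLines(system.file("extdata", "species_names.txt",
                                      package = "dwca", mustWork = TRUE),
                          warn = FALSE)
    }
    cache
  }
})

#' Generate a synthetic dataset
#'
#' Writes the core table (and optional extension table) under the spec's
#' dialect, injecting exactly the requested errors at seeded positions, and
#' returns the ground truth recorded during injection: expected validator
#' issue counts (one `duplicate_id` issue per involved row, so each injected
#' duplication contributes two), expected star-join cardinalities (for
#' fixtures whose identifiers remain clean) and the record count.  The same
#' spec always produces byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `core_path`, `extension_path` (or `NULL`), `truth`
#'   and `spec`.
#' @export
generate_fixture <- function(spec, dir) {
  if (!inherits(spec, "dwca_fixture_spec")) {
    usage_error("generate_fixture expects a fixture_spec")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_records
    names_pool <- fixture_names()
    sci <- sample(names_pool, n, replace = TRUE)
    if (spec$core_type == "occurrence") {
      ids <- sprintf("occ:%06d", seq_len(n))
      headers <- c("occurrenceID", "scientificName", "eventDate", "country",
                   "decimalLatitude", "decimalLongitude", "basisOfRecord")
      dates <- format(as.Date("2000-01-01") + sample.int(5000L, n, replace = TRUE),
                      "%Y-%m-%d")
      rows <- lapply(seq_len(n), function(i) {
        c(ids[i], sci[i], dates[i], "US",
          sprintf("%.4f", stats::runif(1, 25, 49)),
          sprintf("%.4f", stats::runif(1, -124, -67)),
          sample(c("PreservedSpecimen", "HumanObservation"), 1L))
      })
    } else {
      ids <- sprintf("tax:%06d", seq_len(n))
      headers <- c("taxonID", "scientificName", "taxonRank", "kingdom", "family")
      rows <- lapply(seq_len(n), function(i) {
        c(ids[i], sci[i], "species", "Animalia",
          paste0(sub(" .*", "", sci[i]), "idae"))
      })
    }

    # --- seeded error injection (the log below is the ground truth) ---
    e <- spec$errors
    pool <- sample.int(n)
    take <- function(k) {
      if (k == 0L) return(integer(0))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    dup_targets <- take(e$duplicate_ids)
    dup_sources <- take(e$duplicate_ids)
    missing_rows <- take(e$missing_ids)
    ragged_rows <- take(e$ragged_rows)
    noisy_rows <- take(e$noncanonical_country_values)

    for (k in seq_along(dup_targets)) {
      rows[[dup_targets[k]]][1] <- rows[[dup_sources[k]]][1]
      ids[dup_targets[k]] <- ids[dup_sources[k]]
    }
    for (r in missing_rows) {
      rows[[r]][1] <- ""
      ids[r] <- ""
    }
    for (r in ragged_rows) {
      rows[[r]] <- rows[[r]][-length(rows[[r]])]
    }
    variants <- c("USA", "United State", "U.S.A.",
                  "United States of America", "US.")
    if (spec$core_type == "occurrence") {
      for (k in seq_along(noisy_rows)) {
        rows[[noisy_rows[k]]][4] <- variants[((k - 1L) %% 5L) + 1L]
      }
    }

    # extension rows: many-to-one onto the surviving (valid) core ids, so
    # that only deliberately injected orphans are orphans
    ext_rows <- NULL
    ext_coreids <- character(0)
    if (!is.null(spec$extension)) {
      valid_ids <- unique(ids[nzchar(ids)])
      per_core <- stats::rpois(length(valid_ids), spec$extension$mean_rows)
      ext_coreids <- rep(valid_ids, per_core)
      ext_rows <- lapply(seq_along(ext_coreids), function(j) {
        c(ext_coreids[j], "StillImage", "image/jpeg",
          sprintf("http://example.org/media/%05d.jpg", j),
          paste0("Photo ", j))
      })
      ext_headers <- c("coreid", "type", "format", "identifier", "title")
    }

    orphan_rows <- integer(0)
    if (!is.null(ext_rows) && e$orphan_extension_rows > 0L) {
      if (e$orphan_extension_rows > length(ext_rows)) {
        usage_error("orphan_extension_rows exceeds the generated extension row count")
      }
      orphan_rows <- sample.int(length(ext_rows), e$orphan_extension_rows)
      for (k in seq_along(orphan_rows)) {
        orphan_id <- sprintf("orphan:%04d", k)
        ext_rows[[orphan_rows[k]]][1] <- orphan_id
        ext_coreids[orphan_rows[k]] <- orphan_id
      }
    }

    join_counts <- NULL
    if (e$duplicate_ids == 0L && e$missing_ids == 0L) {
      join_counts <- stats::setNames(integer(length(ids)), ids)
      if (length(ext_coreids)) {
        tab <- table(ext_coreids[ext_coreids %in% ids])
        join_counts[names(tab)] <- as.integer(tab)
      }
    }

    core_path <- file.path(dir, paste0(spec$core_type, ".csv"))
    write_delimited(rows, core_path, spec$dialect, headers = headers)
    extension_path <- NULL
    if (!is.null(ext_rows)) {
      extension_path <- file.path(dir, "multimedia.csv")
      write_delimited(ext_rows, extension_path, spec$dialect,
                      headers = ext_headers)
    }

    truth <- list(
      counts = list(
        missing_id = e$missing_ids,
        duplicate_id = 2L * e$duplicate_ids,
        orphan_extension_row = e$orphan_extension_rows,
        arity_mismatch = e$ragged_rows,
        vocabulary_flag = length(unique(
          variants[((seq_len(e$noncanonical_country_values) - 1L) %% 5L) + 1L]))),
      record_count = n,
      extension_row_count = length(ext_coreids),
      join_counts = join_counts,
      injected = list(duplicate_rows = sort(c(dup_targets, dup_sources)),
                      missing_rows = sort(missing_rows),
                      ragged_rows = sort(ragged_rows),
                      orphan_rows = sort(orphan_rows),
                      noisy_rows = sort(noisy_rows)))
    list(core_path = core_path, extension_path = extension_path,
         truth = truth, spec = spec)
  })
}

#' The country-field noise demonstration fixture
#'
#' Emits an occurrence table whose country column contains exactly five
#' distinct non-canonical spellings of the United States — USA, United
#' State, U.S.A., United States of America and US. — alongside rows using
#' the canonical code US, for demonstrating [check_vocabulary()].
#'
#' @param dir Output directory.
#' @return Path to the written table.
#' @export
country_noise_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  variants <- c("USA", "United State", "U.S.A.",
                "United States of America", "US.")
  countries <- c(rep("US", 5L), variants, variants[c(1L, 1L, 4L)])
  n <- length(countries)
  headers <- c("occurrenceID", "scientificName", "eventDate", "country")
  names_pool <- fixture_names()
  rows <- lapply(seq_len(n), function(i) {
    c(sprintf("occ:%06d", i), names_pool[((i - 1L) %% length(names_pool)) + 1L],
      "2013-03-01", countries[i])
  })
  path <- file.path(dir, "country_noise.csv")
  write_delimited(rows, path, text_dialect(",", "\"", "LF", "UTF-8", 1L),
                  headers = headers)
  path
}
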