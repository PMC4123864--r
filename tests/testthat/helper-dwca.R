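# Shared test helpers: random record/metadata generators and oracles.

# Characters deliberately including the delimiters and the quote character,
# to exercise quoting on write and unquoting on read.
nasty_chars <- c(letters, LETTERS, 0:9, " ", ",", ";", "|", "\"", "'",
                 "\t", ".", "-", "_", "(", ")", "/")

rand_string <- function(min = 0, max = 12) {
  n <- sample(min:max, 1)
  paste(sample(nasty_chars, n, replace = TRUE), collapse = "")
}

# Rectangular random records over a few occurrence terms; ids unique.
rand_records <- function(n, terms = c("scientificName", "locality", "recordedBy")) {
  occ <- builtin_schemas()$occurrence
  uris <- vapply(terms, function(t) lookup_term(t, occ)$qualified_name, character(1))
  lapply(seq_len(n), function(i) {
    vals <- vapply(uris, function(u) rand_string(), character(1))
    names(vals) <- unname(uris)
    list(id = sprintf("id%05d", i), values = vals)
  })
}

# Random extension rows pointing at the given core ids (plus optional
# orphan pointers).
rand_ext_rows <- function(m, core_ids, n_orphans = 0,
                          terms = c("identifier", "title")) {
  med <- builtin_schemas()$multimedia
  uris <- vapply(terms, function(t) lookup_term(t, med)$qualified_name, character(1))
  rows <- lapply(seq_len(m), function(j) {
    vals <- vapply(uris, function(u) rand_string(), character(1))
    names(vals) <- unname(uris)
    list(coreid = sample(core_ids, 1), values = vals)
  })
  if (n_orphans > 0 && m >= n_orphans) {
    at <- sample.int(m, n_orphans)
    for (k in seq_along(at)) rows[[at[k]]]$coreid <- sprintf("nope%04d", k)
  }
  rows
}

# Compare two term->value maps ignoring name order.
expect_same_values <- function(got, want) {
  expect_setequal(names(got), names(want))
  expect_identical(unname(got[names(want)]), unname(want))
}

minimal_metadata <- function(title = "Test dataset") {
  eml_metadata(title, list(list(name = "Tester", organization = NULL,
                                email = NULL)))
}

# Random metadata over the full modeled subset (fields dropped at random).
rand_metadata <- function() {
  maybe <- function(x) if (runif(1) < 0.5) x else NULL
  g <- if (runif(1) < 0.5) {
    w <- round(runif(1, -180, 170), 4)
    s <- round(runif(1, -90, 80), 4)
    list(description = "Sampled region",
         west = w, east = round(w + runif(1, 0, 9), 4),
         south = s, north = round(s + runif(1, 0, 9), 4))
  } else NULL
  creators <- lapply(seq_len(sample(1:3, 1)), function(i) {
    list(name = paste0("Creator", i),
         organization = maybe(paste0("Org", i)),
         email = maybe(paste0("c", i, "@example.org")))
  })
  eml_metadata(
    title = paste("Dataset", sample(1e6, 1)),
    creators = creators,
    abstract = maybe("Some records."),
    rights = maybe("CC0"),
    geographic_coverage = g,
    taxonomic_coverage = maybe(list(list(rank = "class", name = "Aves"),
                                    list(rank = "family", name = "Felidae"))),
    temporal_coverage = maybe(list(start = "2001-02-03", end = "2010-11-12")),
    methods = maybe("Standard survey."),
    citation = maybe("Someone (2014). Dataset."),
    language = maybe("en"),
    keywords = maybe(c("alpha", "beta")))
}

# Brute-force star-join oracle: for every core id, scan every extension row.
brute_force_join_counts <- function(core_ids, ext_coreids) {
  vapply(core_ids, function(id) sum(ext_coreids == id), integer(1),
         USE.NAMES = FALSE)
}

# Wrap a generated fixture as a directory-layout archive so validator
# checks can run on it end to end.
fixture_as_archive <- function(fx) {
  dir <- dirname(fx$core_path)
  schemas <- builtin_schemas()
  core_schema <- schemas[[fx$spec$core_type]]
  tab <- source_table(fx$core_path, dialect = fx$spec$dialect)
  ms <- auto_map(tab$headers, core_schema)
  bindings <- lapply(ms$mappings, function(m) {
    list(index = m$column - 1L, term = m$term)
  })
  core_fd <- file_descriptor(basename(fx$core_path), core_schema$row_type,
                             dialect = fx$spec$dialect, id_column = 0L,
                             bindings = bindings)
  exts <- list()
  if (!is.null(fx$extension_path)) {
    ext_tab <- source_table(fx$extension_path, dialect = fx$spec$dialect)
    med <- schemas$multimedia
    ext_ms <- auto_map(ext_tab$headers, med)
    ebind <- lapply(ext_ms$mappings, function(m) {
      list(index = m$column - 1L, term = m$term)
    })
    exts <- list(file_descriptor(basename(fx$extension_path), med$row_type,
                                 dialect = fx$spec$dialect, id_column = 0L,
                                 bindings = ebind))
  }
  d <- archive_descriptor(core_fd, exts)
  writeLines(write_meta_xml(d), file.path(dir, "meta.xml"))
  writeLines(write_eml(minimal_metadata()), file.path(dir, "eml.xml"))
  open_archive(dir)
}
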