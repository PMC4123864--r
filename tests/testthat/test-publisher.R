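make_config <- function(fx, name = "res1", extras = list()) {
  cfg <- list(
    name = name, core_type = fx$spec$core_type, core_source = fx$core_path,
    metadata = list(title = "Publisher test dataset",
                    creators = list(list(name = "Tester"))))
  if (!is.null(fx$extension_path)) {
    cfg$extensions <- list(list(source = fx$extension_path))
  }
  utils::modifyList(cfg, extras)
}

dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(tools::md5sum(files), basename(files))
}

test_that("publishing a clean resource creates immutable, gapless versions", {
  fx <- generate_fixture(fixture_spec("occurrence", n_records = 25,
                                      extension = list(mean_rows = 1),
                                      seed = 11), tempfile())
  cfg <- make_config(fx)
  base <- tempfile()
  v1 <- publish(cfg, base, pinned_timestamp = "2014-01-01T00:00:00Z")
  expect_s3_class(v1, "dwca_published_version")
  expect_identical(v1$version_number, 1L)
  expect_identical(v1$record_count, 25L)
  expect_true(file.exists(v1$archive_path))
  expect_true(file.exists(file.path(dirname(v1$archive_path), "summary.html")))

  v1_bytes <- dwca:::read_file_raw(v1$archive_path)
  v2 <- publish(cfg, base, pinned_timestamp = "2014-02-01T00:00:00Z")
  expect_identical(v2$version_number, 2L)
  # version 1's archive is byte-identical to before the republication
  expect_identical(dwca:::read_file_raw(v1$archive_path), v1_bytes)

  history <- list_versions("res1", base)
  expect_identical(vapply(history, `[[`, integer(1), "version_number"), 1:2)

  # pinned timestamps make republication byte-deterministic
  expect_identical(dwca:::read_file_raw(v1$archive_path),
                   dwca:::read_file_raw(v2$archive_path))
})

test_that("a duplicate or missing identifier halts publication without side effects", {
  base <- tempfile()
  clean <- generate_fixture(fixture_spec("occurrence", n_records = 30, seed = 4),
                            tempfile())
  publish(make_config(clean, "res2"), base,
          pinned_timestamp = "2014-01-01T00:00:00Z")
  before <- dir_digest(base)

  for (errs in list(list(duplicate_ids = 1L), list(missing_ids = 2L))) {
    bad <- generate_fixture(fixture_spec("occurrence", n_records = 30,
                                         errors = errs, seed = 4), tempfile())
    res <- publish(make_config(bad, "res2"), base,
                   pinned_timestamp = "2014-03-01T00:00:00Z")
    expect_s3_class(res, "dwca_validation_report")
    expect_identical(res$verdict, "halt")
    # version store untouched, byte for byte
    expect_identical(dir_digest(base), before)
  }

  # repairing the data publishes version n+1
  v2 <- publish(make_config(clean, "res2"), base,
                pinned_timestamp = "2014-04-01T00:00:00Z")
  expect_identical(v2$version_number, 2L)
})

test_that("orphan extension rows warn but do not block publication", {
  fx <- generate_fixture(fixture_spec("occurrence", n_records = 15,
                                      extension = list(mean_rows = 2),
                                      errors = list(orphan_extension_rows = 2),
                                      seed = 8), tempfile())
  v <- publish(make_config(fx, "res3"), tempfile(),
               pinned_timestamp = "2014-01-01T00:00:00Z")
  expect_s3_class(v, "dwca_published_version")
  expect_identical(v$validation_digest$counts$orphan_extension_row, 2L)
})

test_that("next publication dates follow the calendar, clamping month ends", {
  cases <- list(
    list("daily",      "2014-03-03", "2014-03-04"),
    list("weekly",     "2014-03-03", "2014-03-10"),
    list("monthly",    "2014-01-15", "2014-02-15"),
    list("monthly",    "2014-01-31", "2014-02-28"),
    list("monthly",    "2012-01-31", "2012-02-29"),  # leap year
    list("monthly",    "2014-12-10", "2015-01-10"),
    list("biannually", "2014-01-15", "2014-07-15"),
    list("biannually", "2013-08-31", "2014-02-28"),
    list("annually",   "2014-06-01", "2015-06-01"),
    list("annually",   "2012-02-29", "2013-02-28"))
  for (cs in cases) {
    expect_identical(
      next_publication_date(list(interval = cs[[1]], last_published = cs[[2]])),
      as.Date(cs[[3]]))
  }
  expect_null(next_publication_date(list(interval = "off",
                                         last_published = "2014-01-01")))
  expect_null(next_publication_date(list(interval = "monthly")))
  expect_error(next_publication_date(list(interval = "fortnightly")),
               class = "dwca_usage_error")
})

test_that("next publication dates are monotone in the last-published date", {
  set.seed(31)
  dates <- sort(as.Date("2010-01-01") + sample.int(3000, 40))
  for (interval in c("daily", "weekly", "monthly", "biannually", "annually")) {
    nxt <- vapply(dates, function(d) {
      as.numeric(next_publication_date(list(interval = interval,
                                            last_published = d)))
    }, numeric(1))
    expect_true(all(diff(nxt) >= 0))
  }
})

test_that("schedule due-ness compares the next date with today", {
  s <- list(interval = "weekly", last_published = "2014-01-01")
  expect_true(schedule_due(s, today = "2014-01-08"))
  expect_false(schedule_due(s, today = "2014-01-07"))
  expect_false(schedule_due(list(interval = "off"), today = "2014-01-08"))
})

test_that("registry records are deterministic and maintain legacy identifiers", {
  fx <- generate_fixture(fixture_spec("occurrence", n_records = 5, seed = 2),
                         tempfile())
  base <- tempfile()
  cfg <- make_config(fx, "res4")
  v <- publish(cfg, base, pinned_timestamp = "2014-01-01T00:00:00Z")
  history <- list_versions("res4", base)

  r1 <- registry_record(cfg, history)
  r2 <- registry_record(cfg, history)
  expect_identical(r1, r2)
  expect_false(r1$migrated)
  expect_match(r1$identifier, "^urn:uuid:[0-9a-f-]{36}$")

  legacy_cfg <- make_config(fx, "res4",
                            extras = list(legacy_registry_id = "digir-abc-123"))
  r3 <- registry_record(legacy_cfg, history)
  expect_true(r3$migrated)
  expect_identical(r3$identifier, "digir-abc-123")
  expect_identical(r3$legacy_identifier, "digir-abc-123")

  expect_error(registry_record(cfg, list()), class = "dwca_usage_error")
})
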