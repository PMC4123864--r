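test_that("record-id checking flags missing and duplicate identifiers per row", {
  r <- check_record_ids(c("a", "b", "b", ""))
  expect_identical(unname(r$counts["duplicate_id"]), 2L)
  expect_identical(unname(r$counts["missing_id"]), 1L)
  expect_identical(r$verdict, "halt")
  expect_true(all(r$issues$severity == "error"))
  expect_identical(sort(r$issues$row[r$issues$kind == "duplicate_id"]), c(2L, 3L))

  clean <- check_record_ids(c("a", "b", "c"))
  expect_identical(nrow(clean$issues), 0L)
  expect_identical(clean$verdict, "pass")

  # identifiers are opaque, case-sensitive strings
  expect_identical(check_record_ids(c("x", "X"))$verdict, "pass")
  # whitespace-only is missing; an id occurring thrice yields three issues
  r2 <- check_record_ids(c("  ", "q", "q", "q"))
  expect_identical(unname(r2$counts["missing_id"]), 1L)
  expect_identical(unname(r2$counts["duplicate_id"]), 3L)
})

test_that("record-id issue counts are invariant under row permutation", {
  set.seed(5)
  ids <- c(rep("dup", 3), "", "", letters[1:10])
  base <- check_record_ids(ids)$counts
  for (i in 1:5) {
    perm <- sample(ids)
    expect_identical(check_record_ids(perm)$counts, base)
  }
})

test_that("extension integrity separates orphans (warning) from empty coreids (error)", {
  med_rt <- builtin_schemas()$multimedia$row_type
  recs <- rand_records(2)
  recs[[1]]$id <- "1"; recs[[2]]$id <- "2"

  ext <- rand_ext_rows(2, core_ids = "1")
  ext[[2]]$coreid <- "4"
  zipf <- tempfile(fileext = ".zip")
  package_archive(recs, stats::setNames(list(ext), med_rt),
                  minimal_metadata(), zipf)
  r <- check_extension_integrity(open_archive(zipf))
  expect_identical(unname(r$counts["orphan_extension_row"]), 1L)
  expect_identical(r$issues$severity, "warning")
  expect_identical(r$issues$value, "4")
  expect_identical(r$verdict, "pass")

  # matching coreids produce no issues
  ext2 <- rand_ext_rows(3, core_ids = "1")
  ext2[[3]]$coreid <- "2"
  zipf2 <- tempfile(fileext = ".zip")
  package_archive(recs, stats::setNames(list(ext2), med_rt),
                  minimal_metadata(), zipf2)
  expect_identical(nrow(check_extension_integrity(open_archive(zipf2))$issues), 0L)

  # an empty coreid is written straight into a directory-layout archive
  dir <- tempfile(); dir.create(dir)
  utils::unzip(zipf2, exdir = dir)
  media <- readLines(file.path(dir, "multimedia.txt"))
  media[2] <- sub("^[^\t]*", "", media[2])  # blank the coreid field
  writeLines(media, file.path(dir, "multimedia.txt"))
  r3 <- check_extension_integrity(open_archive(dir))
  expect_identical(r3$verdict, "halt")
  expect_identical(sum(r3$issues$severity == "error"), 1L)
})

test_that("row arity checking flags exactly the deviating rows", {
  rows <- c(replicate(10, as.list(letters[1:5]), simplify = FALSE))
  rows <- lapply(rows, unlist)
  expect_identical(check_row_arity(rows, 5)$verdict, "pass")
  rows[[4]] <- rows[[4]][1:4]
  r <- check_row_arity(rows, 5)
  expect_identical(nrow(r$issues), 1L)
  expect_identical(r$issues$row, 4L)
  expect_identical(check_row_arity(list(), 3)$verdict, "pass")
  expect_error(check_row_arity(list(), 0), class = "dwca_usage_error")
})

test_that("vocabulary checking flags distinct non-canonical values with suggestions", {
  vocab <- load_vocabulary()
  values <- c("USA", "United State", "U.S.A.", "United States of America",
              "US.", "US", "US", "USA")
  res <- check_vocabulary(values, vocab)
  expect_identical(unname(res$report$counts["vocabulary_flag"]), 5L)
  expect_true(all(res$report$issues$severity == "warning"))
  expect_identical(res$report$verdict, "pass")
  expect_setequal(names(res$suggestions),
                  c("USA", "United State", "U.S.A.",
                    "United States of America", "US."))
  expect_true(all(res$suggestions == "US"))

  # canonical-only input passes with no suggestions
  res2 <- check_vocabulary(c("US", "CA", "MX"), vocab)
  expect_identical(nrow(res2$report$issues), 0L)
  expect_length(res2$suggestions, 0L)

  # an unknown value is flagged without a suggestion
  res3 <- check_vocabulary(c("Atlantis"), vocab)
  expect_identical(unname(res3$report$counts["vocabulary_flag"]), 1L)
  expect_false("Atlantis" %in% names(res3$suggestions))

  # flagging never rewrites the input
  v <- c("USA", "US")
  invisible(check_vocabulary(v, vocab))
  expect_identical(v, c("USA", "US"))
})

test_that("the verdict is halt exactly when an error-severity issue exists", {
  warn_only <- check_vocabulary(c("USA"), load_vocabulary())$report
  expect_identical(warn_only$verdict, "pass")
  with_error <- check_record_ids(c("", "a"))
  expect_identical(with_error$verdict, "halt")
  merged <- dwca:::merge_reports(warn_only, with_error)
  expect_identical(merged$verdict, "halt")
  expect_identical(dwca:::merge_reports(warn_only, warn_only)$verdict, "pass")
})
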