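occ <- builtin_schemas()$occurrence

test_that("auto-mapping follows the same-name rule and never guesses", {
  ms <- auto_map(c("scientificName", "eventDate", "my_notes"), occ)
  expect_length(ms$mappings, 2L)
  expect_identical(ms$unmapped, "my_notes")
  mapped <- vapply(ms$mappings, function(m) m$term$simple_name, character(1))
  expect_setequal(mapped, c("scientificName", "eventDate"))

  # normalization: case-fold + strip spaces/underscores
  ms2 <- auto_map(c("Scientific_Name"), occ)
  expect_identical(ms2$mappings[[1]]$term$simple_name, "scientificName")

  expect_length(auto_map(character(0), occ)$mappings, 0L)

  # identifier column is recorded when matched
  ms3 <- auto_map(c("country", "occurrenceID"), occ)
  expect_identical(ms3$id_column, 2L)
})

test_that("auto-mapping is idempotent and order-independent in its match set", {
  headers <- c("occurrenceID", "eventDate", "locality", "junkCol")
  for (perm in list(headers, rev(headers), headers[c(3, 1, 4, 2)])) {
    ms <- auto_map(perm, occ)
    mapped <- sort(vapply(ms$mappings, function(m) m$term$simple_name, character(1)))
    expect_identical(mapped, c("eventDate", "locality", "occurrenceID"))
    expect_identical(sort(ms$unmapped), "junkCol")
    expect_identical(perm[ms$id_column], "occurrenceID")
  }
})

test_that("mapping validation reports the stated issue kinds as data", {
  t_sci <- lookup_term("scientificName", occ)
  dup <- mapping_set(occ, list(field_mapping(t_sci, column = 1),
                               field_mapping(t_sci, column = 2)),
                     id_column = 1, n_columns = 2)
  issues <- validate_mapping(dup)
  expect_identical(sum(issues$kind == "duplicate_term"), 1L)

  no_id <- mapping_set(occ, list(field_mapping(t_sci, column = 1)), n_columns = 1)
  issues2 <- validate_mapping(no_id)
  expect_identical(issues2$kind, "missing_id_column")
  expect_identical(issues2$severity, "error")
  expect_identical(validate_mapping(no_id, core_data = FALSE)$severity, "warning")

  oob <- mapping_set(occ, list(field_mapping(t_sci, column = 5)),
                     id_column = 1, n_columns = 2)
  expect_identical(validate_mapping(oob)$kind, "column_out_of_range")

  empty_const <- mapping_set(
    occ, list(field_mapping(t_sci, column = 1),
              field_mapping(lookup_term("basisOfRecord", occ), constant = "")),
    id_column = 1, n_columns = 1)
  expect_true("empty_constant" %in% validate_mapping(empty_const)$kind)

  clean <- auto_map(c("occurrenceID", "scientificName"), occ)
  expect_identical(nrow(validate_mapping(clean)), 0L)
})

test_that("applying a mapping projects, defaults, and keeps ids verbatim", {
  ms <- auto_map(c("scientificName", "eventDate", "my_notes"), occ)
  rec <- apply_mapping(c("Puma concolor", "2012-03-01", "x"), ms)
  expect_same_values(rec$values, c(
    "http://rs.tdwg.org/dwc/terms/scientificName" = "Puma concolor",
    "http://rs.tdwg.org/dwc/terms/eventDate" = "2012-03-01"))

  # constant applies to every row; empty field takes the default
  t_basis <- lookup_term("basisOfRecord", occ)
  t_date <- lookup_term("eventDate", occ)
  ms2 <- mapping_set(occ, list(
    field_mapping(t_basis, constant = "PreservedSpecimen"),
    field_mapping(t_date, column = 2, default = "unknown")),
    id_column = 1, n_columns = 2)
  r1 <- apply_mapping(c("id1", "2010-01-02"), ms2)
  r2 <- apply_mapping(c(" id2 ", ""), ms2)
  expect_identical(unname(r1$values[t_basis$qualified_name]), "PreservedSpecimen")
  expect_identical(unname(r2$values[t_basis$qualified_name]), "PreservedSpecimen")
  expect_identical(unname(r2$values[t_date$qualified_name]), "unknown")
  expect_identical(r2$id, " id2 ")  # verbatim, no trimming

  expect_error(apply_mapping(c("only-one"), ms2, row_number = 9), "9",
               class = "dwca_arity_error")
})

test_that("mapped output keys never exceed the mapped terms", {
  headers <- c("occurrenceID", "scientificName", "country", "unmappable_x")
  ms <- auto_map(headers, occ)
  rec <- apply_mapping(c("a", "b", "c", "d"), ms)
  mapped_uris <- vapply(ms$mappings, function(m) m$term$qualified_name, character(1))
  expect_true(all(names(rec$values) %in% mapped_uris))
})

test_that("headers exactly matching the schema map completely with no issues", {
  headers <- vapply(occ$terms, `[[`, character(1), "simple_name")
  ms <- auto_map(headers, occ)
  expect_length(ms$mappings, length(headers))
  expect_length(ms$unmapped, 0L)
  expect_identical(nrow(validate_mapping(ms)), 0L)
})
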