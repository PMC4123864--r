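occ_rt <- builtin_schemas()$occurrence$row_type
med_rt <- builtin_schemas()$multimedia$row_type

simple_descriptor <- function(extensions = list()) {
  t_sci <- lookup_term("scientificName", builtin_schemas()$occurrence)
  core <- file_descriptor("occurrence.txt", occ_rt, id_column = 0L,
                          bindings = list(list(index = 1L, term = t_sci)))
  archive_descriptor(core, extensions)
}

test_that("meta.xml writing transcribes structure with escaped control characters", {
  d <- simple_descriptor()
  xml <- write_meta_xml(d)
  doc <- xml2::read_xml(xml)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='core']"), 1L)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='extension']"), 0L)
  core <- xml2::xml_find_first(doc, "//*[local-name()='core']")
  expect_identical(xml2::xml_attr(core, "fieldsTerminatedBy"), "\\t")
  expect_identical(xml2::xml_attr(core, "linesTerminatedBy"), "\\n")
  expect_false(grepl("\t", xml2::xml_attr(core, "fieldsTerminatedBy"), fixed = TRUE))
})

test_that("meta.xml parse is the inverse of write, with text-guide defaults", {
  t_id <- lookup_term("identifier", builtin_schemas()$multimedia)
  ext <- file_descriptor("media.txt", med_rt, id_column = 0L,
                         bindings = list(list(index = 1L, term = t_id,
                                              default = "none")))
  d <- simple_descriptor(list(ext))
  expect_identical(parse_meta_xml(write_meta_xml(d)), d)

  # omitted ignoreHeaderLines defaults to 0; omitted delimiter to comma
  minimal <- paste0(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    '<core rowType="', occ_rt, '"><files><location>x.txt</location></files>',
    '<id index="0"/></core></archive>')
  pd <- parse_meta_xml(minimal)
  expect_identical(pd$core$dialect$header_lines, 0L)
  expect_identical(pd$core$dialect$field_delimiter, ",")
  expect_length(pd$extensions, 0L)

  no_coreid <- paste0(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    '<core rowType="', occ_rt, '"><files><location>x.txt</location></files>',
    '<id index="0"/></core>',
    '<extension rowType="', med_rt, '"><files><location>m.txt</location></files>',
    '</extension></archive>')
  expect_error(parse_meta_xml(no_coreid), "Multimedia",
               class = "dwca_descriptor_error")
})

test_that("descriptor invariants are enforced before any output", {
  core <- file_descriptor("a.txt", occ_rt)
  expect_error(archive_descriptor(core, list(file_descriptor("a.txt", med_rt))),
               class = "dwca_descriptor_error")   # duplicate location
  expect_error(archive_descriptor(core, list(file_descriptor("b.txt", occ_rt))),
               class = "dwca_descriptor_error")   # extension rowType = core's
  expect_error(file_descriptor("dir/a.txt", occ_rt),
               class = "dwca_descriptor_error")
})

test_that("packaging writes the expected entries and line counts", {
  zipf <- tempfile(fileext = ".zip")
  recs <- rand_records(10)
  d <- package_archive(recs, metadata = minimal_metadata(), out_path = zipf)
  entries <- utils::unzip(zipf, list = TRUE)$Name
  expect_setequal(entries, c("occurrence.txt", "meta.xml", "eml.xml"))
  core_lines <- readLines(utils::unzip(zipf, "occurrence.txt", exdir = tempfile()))
  expect_length(core_lines, 11L)  # 1 header + 10 records

  zipf2 <- tempfile(fileext = ".zip")
  ext <- list(rand_ext_rows(2, core_ids = vapply(recs[1], `[[`, "", "id")))
  names(ext) <- med_rt
  package_archive(recs[1], ext, minimal_metadata(), zipf2)
  expect_length(utils::unzip(zipf2, list = TRUE)$Name, 4L)

  # metadata-only package: eml.xml alone
  zipf3 <- tempfile(fileext = ".zip")
  package_archive(list(), metadata = minimal_metadata(), out_path = zipf3,
                  metadata_only = TRUE)
  expect_identical(utils::unzip(zipf3, list = TRUE)$Name, "eml.xml")

  bad <- list(list(list(coreid = "", values = c())))
  names(bad) <- med_rt
  expect_error(package_archive(recs, bad[1], minimal_metadata(), tempfile()),
               class = "dwca_packaging_error")
})

test_that("opening an archive checks meta.xml and referenced files", {
  zipf <- tempfile(fileext = ".zip")
  d <- package_archive(rand_records(3), metadata = minimal_metadata(),
                       out_path = zipf)
  a <- open_archive(zipf)
  expect_identical(a$descriptor, d)

  # same archive as an unzipped directory behaves identically
  dir <- tempfile(); dir.create(dir)
  utils::unzip(zipf, exdir = dir)
  a2 <- open_archive(dir)
  expect_identical(a2$descriptor, d)
  expect_identical(lapply(read_star_records(a2), `[[`, "core_id"),
                   lapply(read_star_records(a), `[[`, "core_id"))

  # a descriptor referencing an absent file names it
  unlink(file.path(dir, "occurrence.txt"))
  expect_error(open_archive(dir), "occurrence.txt", class = "dwca_archive_error")

  nometa <- tempfile(); dir.create(nometa)
  writeLines("x", file.path(nometa, "whatever.txt"))
  expect_error(open_archive(nometa), class = "dwca_archive_error")
})

test_that("star reading groups extension rows per core record exactly", {
  # core ids 1,2,3; multimedia coreids 1,1,2 -> counts 2,1,0
  recs <- rand_records(3)
  recs[[1]]$id <- "1"; recs[[2]]$id <- "2"; recs[[3]]$id <- "3"
  ext_rows <- rand_ext_rows(3, core_ids = "1")
  ext_rows[[3]]$coreid <- "2"
  exts <- stats::setNames(list(ext_rows), med_rt)
  zipf <- tempfile(fileext = ".zip")
  package_archive(recs, exts, minimal_metadata(), zipf)
  stars <- read_star_records(open_archive(zipf))
  counts <- vapply(stars, function(s) length(s$extension_rows[[med_rt]]), integer(1))
  expect_identical(counts, c(2L, 1L, 0L))
  expect_identical(vapply(stars, `[[`, "", "core_id"), c("1", "2", "3"))
  # extension row content survives the round trip
  expect_same_values(stars[[1]]$extension_rows[[med_rt]][[1]],
                     ext_rows[[1]]$values)

  # an orphan coreid is attached to no record (validator's business)
  ext_rows2 <- rand_ext_rows(2, core_ids = "1")
  ext_rows2[[2]]$coreid <- "4"
  zipf2 <- tempfile(fileext = ".zip")
  package_archive(recs, stats::setNames(list(ext_rows2), med_rt),
                  minimal_metadata(), zipf2)
  stars2 <- read_star_records(open_archive(zipf2))
  expect_identical(sum(vapply(stars2, function(s)
    length(s$extension_rows[[med_rt]]), integer(1))), 1L)
})

test_that("a duplicate core id makes the star join fail loudly", {
  recs <- rand_records(2)
  recs[[2]]$id <- recs[[1]]$id
  zipf <- tempfile(fileext = ".zip")
  package_archive(recs, metadata = minimal_metadata(), out_path = zipf)
  expect_error(read_star_records(open_archive(zipf)), recs[[1]]$id,
               class = "dwca_join_error")
})

test_that("package -> open -> star-read reproduces randomized records exactly", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(1:40, 1)
    recs <- rand_records(n)
    ids <- vapply(recs, `[[`, "", "id")
    m <- sample(0:60, 1)
    exts <- stats::setNames(list(rand_ext_rows(m, core_ids = ids)), med_rt)
    zipf <- tempfile(fileext = ".zip")
    package_archive(recs, exts, minimal_metadata(), zipf)
    stars <- read_star_records(open_archive(zipf))
    expect_length(stars, n)
    for (i in seq_len(n)) {
      expect_identical(stars[[i]]$core_id, recs[[i]]$id)
      expect_same_values(stars[[i]]$core_values, recs[[i]]$values)
    }
    # conservation: grouped rows = extension rows - orphans (none here)
    expect_identical(
      sum(vapply(stars, function(s) length(s$extension_rows[[med_rt]]), integer(1))),
      m)
  }
})
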