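# Archive codec: the meta.xml descriptor model, its XML writer/parser, the
# zip packager and the star-join reader.  An archive is a star schema: one
# core table of records plus extension tables whose rows point at core
# records through a coreid column.

DWC_TEXT_NS <- "http://rs.tdwg.org/dwc/text/"

# Writer dialect: every data file this package writes is tab-delimited,
# double-quote quoted, UTF-8, LF-terminated, with one header line, and all
# dialect attributes are stated explicitly in meta.xml.
writer_dialect <- function() {
  text_dialect(field_delimiter = "\t", quote_character = "\"",
               line_terminator = "LF", encoding = "UTF-8", header_lines = 1L)
}

#' Construct an archive file descriptor
#'
#' Describes one data file inside an archive: its location (entry name), its
#' rowType, its dialect, which column holds the record id (core) or the
#' coreid pointer (extension), and the term-to-column bindings.
#'
#' @param location File name inside the archive (no directories).
#' @param row_type RowType URI of the file's records.
#' @param dialect A [text_dialect()].
#' @param id_column 0-based index of the id (core) / coreid (extension)
#'   column.
#' @param bindings List of bindings, each a list with `index` (0-based
#'   column index, or `NULL` for a constant field), `term` (a [dwc_term()])
#'   and optional `default`.
#' @return An object of class `dwca_file_descriptor`.
#' @export
file_descriptor <- function(location, row_type, dialect = writer_dialect(),
                            id_column = 0L, bindings = list()) {
  if (!is_string(location) || !nzchar(location) || grepl("/", location)) {
    descriptor_error("location must be a bare file name (no directories)")
  }
  if (!is_string(row_type) || !nzchar(row_type)) {
    descriptor_error(paste0("file descriptor for '", location, "' lacks a rowType"))
  }
  id_column <- as.integer(id_column)
  if (is.na(id_column) || id_column < 0L) {
    descriptor_error("id column index must be >= 0")
  }
  bindings <- lapply(bindings, function(b) {
    idx <- if (is.null(b$index)) NULL else as.integer(b$index)
    if (!is.null(idx) && (is.na(idx) || idx < 0L)) {
      descriptor_error("binding column indices must be >= 0")
    }
    list(index = idx, term = b$term, default = b$default %||% NULL)
  })
  structure(
    list(location = location, row_type = row_type, dialect = dialect,
         id_column = id_column, bindings = bindings),
    class = "dwca_file_descriptor"
  )
}

#' Construct an archive descriptor
#'
#' The meta.xml model: exactly one core file plus any number of extension
#' files, and the name of the metadata document.
#'
#' @param core Core [file_descriptor()].
#' @param extensions List of extension [file_descriptor()]s; each rowType
#'   must differ from the core's.
#' @param metadata_location Entry name of the EML document.
#' @return An object of class `dwca_archive_descriptor`.
#' @export
archive_descriptor <- function(core, extensions = list(),
                               metadata_location = "eml.xml") {
  locs <- c(core$location, vapply(extensions, `[[`, character(1), "location"))
  if (anyDuplicated(locs)) {
    descriptor_error(paste0("duplicate file locations in archive: ",
                            paste(unique(locs[duplicated(locs)]), collapse = ", ")))
  }
  ext_types <- vapply(extensions, `[[`, character(1), "row_type")
  if (any(ext_types == core$row_type)) {
    descriptor_error("an extension rowType equals the core rowType")
  }
  if (anyDuplicated(ext_types)) {
    descriptor_error("duplicate extension rowTypes")
  }
  if (!is_string(metadata_location) || !nzchar(metadata_location)) {
    descriptor_error("metadata_location must be a non-empty file name")
  }
  structure(
    list(core = core, extensions = extensions,
         metadata_location = metadata_location),
    class = "dwca_archive_descriptor"
  )
}

# meta.xml attribute escaping: control characters are written in their
# backslash-escaped form, never literally.
meta_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

meta_unescape <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\\", "\\", x, fixed = TRUE)
  x
}

dialect_attrs <- function(d) {
  eol <- if (d$line_terminator == "CRLF") "\r\n" else "\n"
  c(fieldsTerminatedBy = meta_escape(d$field_delimiter),
    linesTerminatedBy = meta_escape(eol),
    fieldsEnclosedBy = if (is.null(d$quote_character)) "" else d$quote_character,
    encoding = d$encoding,
    ignoreHeaderLines = as.character(d$header_lines))
}

add_file_element <- function(parent, fd, element, id_element) {
  attrs <- c(rowType = fd$row_type, dialect_attrs(fd$dialect))
  node <- xml2::xml_add_child(parent, element)
  for (nm in names(attrs)) xml2::xml_set_attr(node, nm, attrs[[nm]])
  files <- xml2::xml_add_child(node, "files")
  loc <- xml2::xml_add_child(files, "location")
  xml2::xml_set_text(loc, fd$location)
  idn <- xml2::xml_add_child(node, id_element)
  xml2::xml_set_attr(idn, "index", as.character(fd$id_column))
  for (b in fd$bindings) {
    f <- xml2::xml_add_child(node, "field")
    if (!is.null(b$index)) xml2::xml_set_attr(f, "index", as.character(b$index))
    xml2::xml_set_attr(f, "term", b$term$qualified_name)
    if (!is.null(b$default)) xml2::xml_set_attr(f, "default", b$default)
  }
  node
}

#' Serialize an archive descriptor to meta.xml
#'
#' Emits the descriptor in the Darwin Core text namespace: an `archive` root
#' with a `metadata` attribute, one `core` element and one `extension`
#' element per extension, each carrying explicit dialect attributes, a
#' `files/location` child, an `id` (core) or `coreid` (extension) element
#' and one `field` element per binding.  Tab and newline delimiters appear
#' in their backslash-escaped forms.
#'
#' @param d A valid [archive_descriptor()].
#' @return meta.xml document text (single string).
#' @export
write_meta_xml <- function(d) {
  if (!inherits(d, "dwca_archive_descriptor")) {
    descriptor_error("write_meta_xml expects an archive descriptor")
  }
  doc <- xml2::xml_new_root("archive", xmlns = DWC_TEXT_NS,
                            metadata = d$metadata_location)
  add_file_element(doc, d$core, "core", "id")
  for (ext in d$extensions) {
    add_file_element(doc, ext, "extension", "coreid")
  }
  as.character(doc)
}

parse_dialect_attrs <- function(node) {
  attr_or <- function(name, default) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  # Text-guide defaults apply when attributes are absent.
  delim <- meta_unescape(attr_or("fieldsTerminatedBy", ","))
  eol <- meta_unescape(attr_or("linesTerminatedBy", "\n"))
  quote <- attr_or("fieldsEnclosedBy", "\"")
  text_dialect(
    field_delimiter = delim,
    quote_character = if (nzchar(quote)) quote else NULL,
    line_terminator = if (identical(eol, "\r\n")) "CRLF" else "LF",
    encoding = attr_or("encoding", "UTF-8"),
    header_lines = as.integer(attr_or("ignoreHeaderLines", "0"))
  )
}

parse_file_element <- function(node, id_element) {
  row_type <- xml2::xml_attr(node, "rowType")
  if (is.na(row_type) || !nzchar(row_type)) {
    descriptor_error(paste0("<", xml2::xml_name(node), "> element lacks rowType"))
  }
  loc_node <- xml2::xml_find_first(node, "./*[local-name()='files']/*[local-name()='location']")
  if (inherits(loc_node, "xml_missing")) {
    descriptor_error(paste0("file descriptor for rowType ", row_type,
                            " lacks files/location"))
  }
  known <- c("rowType", "fieldsTerminatedBy", "linesTerminatedBy",
             "fieldsEnclosedBy", "encoding", "ignoreHeaderLines", "dateFormat")
  extra <- setdiff(names(xml2::xml_attrs(node)), known)
  if (length(extra)) {
    dwca_log("ignoring unknown descriptor attributes: ", paste(extra, collapse = ", "))
  }
  id_node <- xml2::xml_find_first(node, paste0("./*[local-name()='", id_element, "']"))
  if (inherits(id_node, "xml_missing")) {
    if (id_element == "coreid") {
      descriptor_error(paste0("extension with rowType ", row_type,
                              " lacks a coreid element"))
    }
    id_idx <- 0L
  } else {
    id_idx <- as.integer(xml2::xml_attr(id_node, "index") %||% "0")
    if (is.na(id_idx)) id_idx <- 0L
  }
  fields <- xml2::xml_find_all(node, "./*[local-name()='field']")
  bindings <- lapply(fields, function(f) {
    idx <- xml2::xml_attr(f, "index")
    dft <- xml2::xml_attr(f, "default")
    list(index = if (is.na(idx)) NULL else as.integer(idx),
         term = dwc_term(xml2::xml_attr(f, "term")),
         default = if (is.na(dft)) NULL else dft)
  })
  file_descriptor(location = xml2::xml_text(loc_node), row_type = row_type,
                  dialect = parse_dialect_attrs(node), id_column = id_idx,
                  bindings = bindings)
}

#' Parse a meta.xml document
#'
#' Inverse of [write_meta_xml()] on its output.  Absent optional attributes
#' take the text-guide defaults (comma delimiter, LF line ends, double-quote
#' quoting, UTF-8, zero header lines).  Unknown attributes are ignored with
#' a log line.
#'
#' @param xml meta.xml text, or a path to the file.
#' @return An [archive_descriptor()].
#' @export
parse_meta_xml <- function(xml) {
  doc <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) parse_error(paste0("malformed meta.xml: ",
                                           conditionMessage(e)))
  )
  root <- xml2::xml_root(doc)
  core_node <- xml2::xml_find_first(root, "./*[local-name()='core']")
  if (inherits(core_node, "xml_missing")) {
    descriptor_error("meta.xml has no core element")
  }
  core <- parse_file_element(core_node, "id")
  ext_nodes <- xml2::xml_find_all(root, "./*[local-name()='extension']")
  extensions <- lapply(ext_nodes, parse_file_element, id_element = "coreid")
  md <- xml2::xml_attr(root, "metadata")
  archive_descriptor(core, extensions,
                     metadata_location = if (is.na(md)) "eml.xml" else md)
}

# --- packaging ---------------------------------------------------------------

records_to_table <- function(records, id_header, schema = NULL) {
  term_uris <- character(0)
  if (!is.null(schema)) {
    used <- unique(unlist(lapply(records, function(r) names(r$values))))
    term_uris <- vapply(schema$terms, `[[`, character(1), "qualified_name")
    term_uris <- term_uris[term_uris %in% used]
    used <- setdiff(used, term_uris)
    term_uris <- c(term_uris, used)
  } else {
    for (r in records) {
      term_uris <- union(term_uris, names(r$values))
    }
  }
  terms <- lapply(term_uris, dwc_term)
  headers <- c(id_header, vapply(terms, `[[`, character(1), "simple_name"))
  rows <- lapply(records, function(r) {
    vals <- vapply(term_uris, function(u) r$values[[u]] %||% "", character(1),
                   USE.NAMES = FALSE)
    c(r$id, vals)
  })
  bindings <- lapply(seq_along(terms), function(i) {
    list(index = i, term = terms[[i]], default = NULL)  # 0-based; id is column 0
  })
  list(headers = headers, rows = rows, bindings = bindings)
}

location_for_rowtype <- function(row_type) {
  paste0(tolower(sub("^.*[/#]", "", row_type)), ".txt")
}

#' Package records into a Darwin Core Archive
#'
#' Writes a zip containing one tab-delimited UTF-8 data file per record
#' stream (a header line plus data rows), `meta.xml` at the zip root and
#' the EML metadata document.  The record identifier is always written as
#' physical column 0 of each data file.  A metadata-only package (no core
#' records, `metadata_only = TRUE`) contains just the metadata document.
#'
#' @param core_records List of records, each a list with `id` (string) and
#'   `values` (named character vector keyed by qualified term name).
#' @param extension_records Named list mapping extension rowType URI to a
#'   list of rows, each a list with `coreid` and `values`.
#' @param metadata An `eml_metadata` object, EML text, or a path to an EML
#'   file.
#' @param out_path Output zip path.
#' @param core_row_type RowType URI of the core (default Occurrence).
#' @param core_schema Optional [dwc_schema()] used to order core columns;
#'   defaults to the built-in schema matching `core_row_type` when there is
#'   one.
#' @param metadata_only Logical; package only the metadata document.
#' @return The [archive_descriptor()] used, or invisibly `NULL` for a
#'   metadata-only package.
#' @export
package_archive <- function(core_records, extension_records = list(),
                            metadata, out_path,
                            core_row_type = builtin_schemas()$occurrence$row_type,
                            core_schema = NULL, metadata_only = FALSE) {
  if (!length(core_records) && !isTRUE(metadata_only)) {
    packaging_error("no core records; pass metadata_only = TRUE for a metadata-only package")
  }
  eml_text <- if (inherits(metadata, "dwca_eml_metadata")) {
    write_eml(metadata)
  } else if (is_string(metadata) && file.exists(metadata)) {
    rawToChar(read_file_raw(metadata))
  } else if (is_string(metadata)) {
    metadata
  } else {
    metadata_error("metadata must be an eml_metadata object, EML text or a file path")
  }
  entries <- list()
  if (isTRUE(metadata_only)) {
    entries[["eml.xml"]] <- charToRaw(enc2utf8(eml_text))
    zip_write(out_path, entries)
    return(invisible(NULL))
  }

  if (is.null(core_schema)) {
    builtin <- builtin_schemas()
    for (s in builtin) {
      if (identical(s$row_type, core_row_type)) core_schema <- s
    }
  }
  d <- writer_dialect()
  core_tab <- records_to_table(core_records, id_header = "id", schema = core_schema)
  core_fd <- file_descriptor(location_for_rowtype(core_row_type),
                             core_row_type, dialect = d, id_column = 0L,
                             bindings = core_tab$bindings)
  entries[[core_fd$location]] <-
    charToRaw(enc2utf8(format_delimited(core_tab$rows, d, core_tab$headers)))

  ext_fds <- list()
  builtin <- builtin_schemas()
  for (rt in names(extension_records)) {
    rows_in <- extension_records[[rt]]
    coreids <- vapply(rows_in, function(r) r$coreid %||% "", character(1))
    if (any(!nzchar(coreids))) {
      packaging_error(paste0("extension ", rt, " has rows with an empty coreid"))
    }
    ext_schema <- NULL
    for (s in builtin) if (identical(s$row_type, rt)) ext_schema <- s
    recs <- lapply(rows_in, function(r) list(id = r$coreid, values = r$values))
    tab <- records_to_table(recs, id_header = "coreid", schema = ext_schema)
    loc <- location_for_rowtype(rt)
    if (loc %in% c(core_fd$location, vapply(ext_fds, `[[`, character(1), "location"))) {
      loc <- paste0("ext", length(ext_fds) + 1L, "_", loc)
    }
    fd <- file_descriptor(loc, rt, dialect = d, id_column = 0L,
                          bindings = tab$bindings)
    ext_fds[[length(ext_fds) + 1L]] <- fd
    entries[[loc]] <- charToRaw(enc2utf8(format_delimited(tab$rows, d, tab$headers)))
  }

  descriptor <- archive_descriptor(core_fd, ext_fds, metadata_location = "eml.xml")
  entries[["meta.xml"]] <- charToRaw(enc2utf8(write_meta_xml(descriptor)))
  entries[["eml.xml"]] <- charToRaw(enc2utf8(eml_text))
  zip_write(out_path, entries)
  descriptor
}

# --- reading -----------------------------------------------------------------

#' Open a Darwin Core Archive
#'
#' Accepts either a zip file or a directory laid out like an unzipped
#' archive.  The descriptor is parsed eagerly and every location it
#' references is checked for existence; data files are read lazily by
#' [read_star_records()].
#'
#' @param path Zip file or directory containing `meta.xml`.
#' @return An archive handle of class `dwca_archive` with fields
#'   `descriptor`, `dir` and `path`.
#' @export
open_archive <- function(path) {
  if (!file.exists(path)) archive_error(paste0("no such archive: ", path))
  if (dir.exists(path)) {
    dir <- path
  } else {
    dir <- tempfile("dwca_open_")
    dir.create(dir)
    tryCatch(utils::unzip(path, exdir = dir),
             error = function(e) archive_error(paste0("cannot unzip ", path, ": ",
                                                      conditionMessage(e))),
             warning = function(w) archive_error(paste0("cannot unzip ", path, ": ",
                                                        conditionMessage(w))))
  }
  meta_path <- file.path(dir, "meta.xml")
  if (!file.exists(meta_path)) {
    archive_error(paste0("archive has no meta.xml: ", path))
  }
  descriptor <- parse_meta_xml(meta_path)
  for (fd in c(list(descriptor$core), descriptor$extensions)) {
    if (!file.exists(file.path(dir, fd$location))) {
      archive_error(paste0("descriptor references a missing file: ", fd$location))
    }
  }
  structure(list(descriptor = descriptor, dir = dir, path = path),
            class = "dwca_archive")
}

# Read one archive data file into (ids, values) using its descriptor.
read_descriptor_file <- function(a, fd) {
  tab <- structure(
    list(path = file.path(a$dir, fd$location), dialect = fd$dialect,
         headers = character(0), row_count = NA_integer_),
    class = "dwca_source_table"
  )
  rows <- read_rows(tab)
  terms <- vapply(fd$bindings, function(b) b$term$qualified_name, character(1))
  lens <- lengths(rows)
  if (length(rows) && length(unique(lens)) == 1L) {
    # uniform arity: column-wise vectorized extraction
    mat <- matrix(unlist(rows, use.names = FALSE), nrow = length(rows),
                  byrow = TRUE)
    get_col <- function(idx0) {
      if (idx0 + 1L <= ncol(mat)) mat[, idx0 + 1L] else rep("", nrow(mat))
    }
    ids <- get_col(fd$id_column)
    cols <- lapply(fd$bindings, function(b) {
      v <- if (is.null(b$index)) rep("", nrow(mat)) else get_col(b$index)
      if (!is.null(b$default)) v[!nzchar(v)] <- b$default
      v
    })
    values <- lapply(seq_len(nrow(mat)), function(i) {
      stats::setNames(vapply(cols, `[[`, character(1), i), terms)
    })
  } else {
    get_field <- function(row, idx0) {
      if (idx0 + 1L <= length(row)) row[[idx0 + 1L]] else ""
    }
    ids <- vapply(rows, get_field, character(1), idx0 = fd$id_column)
    values <- lapply(rows, function(row) {
      out <- vapply(fd$bindings, function(b) {
        v <- if (is.null(b$index)) "" else get_field(row, b$index)
        if (!nzchar(v) && !is.null(b$default)) v <- b$default
        v
      }, character(1))
      stats::setNames(out, terms)
    })
  }
  list(ids = ids, values = values)
}

#' Read an archive as star records
#'
#' Joins extension rows to core records on exact string equality of the
#' extension's coreid and the core's id, yielding one star record per core
#' row in core file order.  Extension rows whose coreid matches no core id
#' are dropped here (they are validator findings, see
#' [check_extension_integrity()]).  The join builds one in-memory index of
#' core ids, so memory grows with the core row count, not total data size.
#'
#' @param a An open [open_archive()] handle.
#' @return A list of star records, each a list with `core_id`,
#'   `core_values` (named character) and `extension_rows` (named list
#'   mapping extension rowType to a list of named character vectors, in
#'   extension file order).
#' @export
read_star_records <- function(a) {
  core <- read_descriptor_file(a, a$descriptor$core)
  if (anyDuplicated(core$ids)) {
    dup <- core$ids[duplicated(core$ids)][1]
    join_error(paste0("duplicate core record id during star join: '", dup, "'"))
  }
  ext_types <- vapply(a$descriptor$extensions, `[[`, character(1), "row_type")
  ext_by_core <- lapply(seq_along(core$ids), function(i) {
    out <- vector("list", length(ext_types))
    names(out) <- ext_types
    for (j in seq_along(out)) out[[j]] <- list()
    out
  })
  for (k in seq_along(a$descriptor$extensions)) {
    fd <- a$descriptor$extensions[[k]]
    ext <- read_descriptor_file(a, fd)
    pos <- match(ext$ids, core$ids)
    for (r in seq_along(ext$ids)) {
      p <- pos[r]
      if (is.na(p) || !nzchar(ext$ids[r])) next  # orphan: validator territory
      grp <- ext_by_core[[p]][[fd$row_type]]
      grp[[length(grp) + 1L]] <- ext$values[[r]]
      ext_by_core[[p]][[fd$row_type]] <- grp
    }
  }
  lapply(seq_along(core$ids), function(i) {
    structure(
      list(core_id = core$ids[i], core_values = core$values[[i]],
           extension_rows = ext_by_core[[i]]),
      class = "dwca_star_record"
    )
  })
}
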