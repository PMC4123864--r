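# Dataset metadata: an EML dataset-level subset (the fields a publishing
# tool populates), its XML writer/parser, a data-paper manuscript exporter
# and a static HTML summary page renderer.  Dublin Core input is accepted on
# read but metadata is always written as EML, the richer of the two.

EML_NS <- "eml://ecoinformatics.org/eml-2.1.1"

DATA_PAPER_SECTIONS <- c("Title", "Authors", "Abstract", "Keywords",
                         "Taxonomic Coverage", "Geographic Coverage",
                         "Temporal Coverage", "Methods",
                         "Dataset Description", "Rights", "References")

#' Construct dataset metadata
#'
#' The modeled subset covers what a dataset landing page and a data paper
#' need: title, creators, abstract, rights, geographic / taxonomic /
#' temporal coverage, methods, citation and language.
#'
#' @param title Dataset title (non-empty).
#' @param creators List of creators, each a list with `name` and optional
#'   `organization` and `email`; at least one is required.
#' @param abstract,rights,methods,citation,language Optional strings.
#' @param geographic_coverage Optional list with `description` and optional
#'   `west`, `east`, `south`, `north` decimal-degree bounds
#'   (-180 <= west <= east <= 180, -90 <= south <= north <= 90).
#' @param taxonomic_coverage Optional list of lists with `rank` and `name`.
#' @param temporal_coverage Optional list with `start` and `end` ISO dates.
#' @param keywords Optional character vector.
#' @return An object of class `dwca_eml_metadata`.
#' @export
eml_metadata <- function(title, creators, abstract = NULL, rights = NULL,
                         geographic_coverage = NULL, taxonomic_coverage = NULL,
                         temporal_coverage = NULL, methods = NULL,
                         citation = NULL, language = NULL,
                         keywords = NULL) {
  if (!is_string(title) || !nzchar(trimws(title))) {
    metadata_error("metadata field 'title' must be a non-empty string")
  }
  if (!is.list(creators) || !length(creators)) {
    metadata_error("metadata field 'creators' must list at least one creator")
  }
  creators <- lapply(creators, function(cr) {
    if (is_string(cr)) cr <- list(name = cr)
    if (!is_string(cr$name) || !nzchar(cr$name)) {
      metadata_error("each creator needs a non-empty 'name'")
    }
    list(name = cr$name, organization = cr$organization %||% NULL,
         email = cr$email %||% NULL)
  })
  if (!is.null(geographic_coverage)) {
    g <- geographic_coverage
    bbox <- c(g$west, g$east, g$south, g$north)
    if (length(bbox) && length(bbox) != 4L) {
      metadata_error("geographic_coverage bounding box needs all of west/east/south/north")
    }
    if (length(bbox) == 4L) {
      if (g$west > g$east || g$west < -180 || g$east > 180) {
        metadata_error("geographic_coverage: need -180 <= west <= east <= 180")
      }
      if (g$south > g$north || g$south < -90 || g$north > 90) {
        metadata_error("geographic_coverage: need -90 <= south <= north <= 90")
      }
    }
  }
  structure(
    list(title = title, creators = creators, abstract = abstract,
         rights = rights, geographic_coverage = geographic_coverage,
         taxonomic_coverage = taxonomic_coverage,
         temporal_coverage = temporal_coverage, methods = methods,
         citation = citation, language = language, keywords = keywords,
         extra_xml = character(0)),
    class = "dwca_eml_metadata"
  )
}

add_text_child <- function(parent, name, text) {
  node <- xml2::xml_add_child(parent, name)
  xml2::xml_set_text(node, as.character(text))
  node
}

num_chr <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

#' Serialize dataset metadata as EML
#'
#' Absent optional fields are omitted, never written as empty elements.
#' Foreign elements captured by [parse_eml()] are re-emitted unchanged.
#'
#' @param m An [eml_metadata()] object.
#' @return EML document text (single string).
#' @export
write_eml <- function(m) {
  if (!inherits(m, "dwca_eml_metadata")) {
    metadata_error("write_eml expects an eml_metadata object")
  }
  doc <- xml2::xml_new_root("eml:eml", "xmlns:eml" = EML_NS,
                            packageId = paste0("dwca-", string_md5(m$title)),
                            system = "dwca")
  ds <- xml2::xml_add_child(doc, "dataset")
  add_text_child(ds, "title", m$title)
  for (cr in m$creators) {
    node <- xml2::xml_add_child(ds, "creator")
    ind <- xml2::xml_add_child(node, "individualName")
    add_text_child(ind, "surName", cr$name)
    if (!is.null(cr$organization)) add_text_child(node, "organizationName", cr$organization)
    if (!is.null(cr$email)) add_text_child(node, "electronicMailAddress", cr$email)
  }
  if (!is.null(m$language)) add_text_child(ds, "language", m$language)
  if (!is.null(m$abstract)) {
    add_text_child(xml2::xml_add_child(ds, "abstract"), "para", m$abstract)
  }
  if (!is.null(m$keywords) && length(m$keywords)) {
    ks <- xml2::xml_add_child(ds, "keywordSet")
    for (k in m$keywords) add_text_child(ks, "keyword", k)
  }
  if (!is.null(m$rights)) {
    add_text_child(xml2::xml_add_child(ds, "intellectualRights"), "para", m$rights)
  }
  has_cov <- !is.null(m$geographic_coverage) || !is.null(m$taxonomic_coverage) ||
    !is.null(m$temporal_coverage)
  if (has_cov) {
    cov <- xml2::xml_add_child(ds, "coverage")
    if (!is.null(m$geographic_coverage)) {
      g <- m$geographic_coverage
      gc <- xml2::xml_add_child(cov, "geographicCoverage")
      if (!is.null(g$description)) add_text_child(gc, "geographicDescription", g$description)
      if (!is.null(g$west)) {
        bc <- xml2::xml_add_child(gc, "boundingCoordinates")
        add_text_child(bc, "westBoundingCoordinate", num_chr(g$west))
        add_text_child(bc, "eastBoundingCoordinate", num_chr(g$east))
        add_text_child(bc, "northBoundingCoordinate", num_chr(g$north))
        add_text_child(bc, "southBoundingCoordinate", num_chr(g$south))
      }
    }
    if (!is.null(m$temporal_coverage)) {
      tc <- xml2::xml_add_child(cov, "temporalCoverage")
      rd <- xml2::xml_add_child(tc, "rangeOfDates")
      add_text_child(xml2::xml_add_child(rd, "beginDate"), "calendarDate",
                     m$temporal_coverage$start)
      add_text_child(xml2::xml_add_child(rd, "endDate"), "calendarDate",
                     m$temporal_coverage$end)
    }
    if (!is.null(m$taxonomic_coverage)) {
      tx <- xml2::xml_add_child(cov, "taxonomicCoverage")
      for (t in m$taxonomic_coverage) {
        cl <- xml2::xml_add_child(tx, "taxonomicClassification")
        add_text_child(cl, "taxonRankName", t$rank)
        add_text_child(cl, "taxonRankValue", t$name)
      }
    }
  }
  if (!is.null(m$methods)) {
    ms <- xml2::xml_add_child(ds, "methods")
    step <- xml2::xml_add_child(ms, "methodStep")
    add_text_child(xml2::xml_add_child(step, "description"), "para", m$methods)
  }
  if (!is.null(m$citation)) {
    am <- xml2::xml_add_child(doc, "additionalMetadata")
    md <- xml2::xml_add_child(am, "metadata")
    add_text_child(md, "citation", m$citation)
  }
  for (x in m$extra_xml) {
    frag <- xml2::xml_root(xml2::read_xml(x))
    xml2::xml_add_child(ds, frag)
  }
  as.character(doc)
}

xml_text_or_null <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NULL else xml2::xml_text(hit)
}

#' Parse an EML (or Dublin Core) metadata document
#'
#' Inverse of [write_eml()] on its outputs.  Elements of the dataset section
#' outside the modeled subset are preserved opaquely and re-emitted by
#' [write_eml()], so read-modify-write does not lose foreign content.  A
#' Dublin Core record (elements in the `dc:` namespace such as
#' `dc:title`/`dc:creator`) is mapped into the same metadata type.
#'
#' @param xml EML text or a path to an EML file.
#' @return An [eml_metadata()] object.
#' @export
parse_eml <- function(xml) {
  doc <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) parse_error(paste0("malformed metadata document: ",
                                           conditionMessage(e)))
  )
  root <- xml2::xml_root(doc)
  # Dublin Core record: map dc:title/dc:creator/... into the same type.
  dc_titles <- xml2::xml_find_all(
    root, ".//*[local-name()='title' and namespace-uri()='http://purl.org/dc/elements/1.1/']")
  if (length(dc_titles)) {
    dc <- function(nm) xml2::xml_find_all(
      root, paste0(".//*[local-name()='", nm,
                   "' and namespace-uri()='http://purl.org/dc/elements/1.1/']"))
    creators <- lapply(xml2::xml_text(dc("creator")), function(n) list(name = n))
    if (!length(creators)) creators <- list(list(name = "Unknown"))
    desc <- xml2::xml_text(dc("description"))
    rights <- xml2::xml_text(dc("rights"))
    return(eml_metadata(
      title = xml2::xml_text(dc_titles[[1]]),
      creators = creators,
      abstract = if (length(desc)) desc[[1]] else NULL,
      rights = if (length(rights)) rights[[1]] else NULL))
  }
  ds <- xml2::xml_find_first(root, ".//*[local-name()='dataset']")
  if (inherits(ds, "xml_missing")) {
    metadata_error("metadata document has no dataset section")
  }
  title <- xml_text_or_null(ds, "./*[local-name()='title']")
  if (is.null(title) || !nzchar(title)) {
    metadata_error("metadata document has no title")
  }
  creators <- lapply(
    xml2::xml_find_all(ds, "./*[local-name()='creator']"),
    function(node) {
      list(
        name = xml_text_or_null(
          node, "./*[local-name()='individualName']/*[local-name()='surName']") %||%
          xml_text_or_null(node, "./*[local-name()='organizationName']") %||% "Unknown",
        organization = xml_text_or_null(node, "./*[local-name()='organizationName']"),
        email = xml_text_or_null(node, "./*[local-name()='electronicMailAddress']"))
    })
  if (!length(creators)) metadata_error("metadata document lists no creator")

  g <- NULL
  gc_node <- xml2::xml_find_first(
    ds, "./*[local-name()='coverage']/*[local-name()='geographicCoverage']")
  if (!inherits(gc_node, "xml_missing")) {
    num <- function(nm) {
      v <- xml_text_or_null(gc_node, paste0(
        "./*[local-name()='boundingCoordinates']/*[local-name()='", nm, "']"))
      if (is.null(v)) NULL else as.numeric(v)
    }
    g <- list(description = xml_text_or_null(gc_node, "./*[local-name()='geographicDescription']"),
              west = num("westBoundingCoordinate"), east = num("eastBoundingCoordinate"),
              south = num("southBoundingCoordinate"), north = num("northBoundingCoordinate"))
    g <- g[!vapply(g, is.null, logical(1))]
  }
  tx <- NULL
  tx_nodes <- xml2::xml_find_all(
    ds, paste0("./*[local-name()='coverage']/*[local-name()='taxonomicCoverage']",
               "/*[local-name()='taxonomicClassification']"))
  if (length(tx_nodes)) {
    tx <- lapply(tx_nodes, function(node) {
      list(rank = xml_text_or_null(node, "./*[local-name()='taxonRankName']"),
           name = xml_text_or_null(node, "./*[local-name()='taxonRankValue']"))
    })
  }
  tc <- NULL
  tc_node <- xml2::xml_find_first(
    ds, paste0("./*[local-name()='coverage']/*[local-name()='temporalCoverage']",
               "/*[local-name()='rangeOfDates']"))
  if (!inherits(tc_node, "xml_missing")) {
    tc <- list(
      start = xml_text_or_null(tc_node, "./*[local-name()='beginDate']/*[local-name()='calendarDate']"),
      end = xml_text_or_null(tc_node, "./*[local-name()='endDate']/*[local-name()='calendarDate']"))
  }
  keywords <- xml2::xml_text(xml2::xml_find_all(
    ds, "./*[local-name()='keywordSet']/*[local-name()='keyword']"))
  if (!length(keywords)) keywords <- NULL

  m <- eml_metadata(
    title = title, creators = creators,
    abstract = xml_text_or_null(ds, "./*[local-name()='abstract']/*[local-name()='para']") %||%
      xml_text_or_null(ds, "./*[local-name()='abstract']"),
    rights = xml_text_or_null(ds, "./*[local-name()='intellectualRights']/*[local-name()='para']") %||%
      xml_text_or_null(ds, "./*[local-name()='intellectualRights']"),
    geographic_coverage = g, taxonomic_coverage = tx, temporal_coverage = tc,
    methods = xml_text_or_null(
      ds, paste0("./*[local-name()='methods']/*[local-name()='methodStep']",
                 "/*[local-name()='description']/*[local-name()='para']")),
    citation = xml_text_or_null(
      root, paste0("./*[local-name()='additionalMetadata']/*[local-name()='metadata']",
                   "/*[local-name()='citation']")),
    language = xml_text_or_null(ds, "./*[local-name()='language']"),
    keywords = keywords)

  known <- c("title", "creator", "language", "abstract", "keywordSet",
             "intellectualRights", "coverage", "methods")
  foreign <- Filter(function(node) !(xml2::xml_name(node) %in% known),
                    xml2::xml_children(ds))
  m$extra_xml <- vapply(foreign, as.character, character(1))
  m
}

placeholder_or <- function(x) {
  if (is.null(x) || !length(x) || !nzchar(paste(x, collapse = ""))) {
    "[To be completed]"
  } else {
    x
  }
}

#' Export metadata as a data-paper manuscript draft
#'
#' Produces a structured-text (Markdown) manuscript skeleton with eleven
#' titled sections in fixed order: Title, Authors, Abstract, Keywords,
#' Taxonomic Coverage, Geographic Coverage, Temporal Coverage, Methods,
#' Dataset Description, Rights, References.  Sections with no content are
#' emitted with a placeholder marker rather than dropped, so the skeleton is
#' always complete.
#'
#' @param m An [eml_metadata()] object.
#' @param stats Optional dataset statistics: a list with `record_count`,
#'   `core_type` (rowType URI or label) and `extensions` (character vector
#'   of extension rowTypes).
#' @return Manuscript text (single Markdown string).
#' @export
export_data_paper <- function(m, stats = NULL) {
  if (!inherits(m, "dwca_eml_metadata")) {
    metadata_error("export_data_paper expects an eml_metadata object")
  }
  authors <- vapply(m$creators, function(cr) {
    paste0(cr$name,
           if (!is.null(cr$organization)) paste0(" (", cr$organization, ")") else "")
  }, character(1))
  tax <- if (!is.null(m$taxonomic_coverage)) {
    vapply(m$taxonomic_coverage, function(t) paste0(t$rank, ": ", t$name), character(1))
  } else NULL
  geo <- if (!is.null(m$geographic_coverage)) {
    g <- m$geographic_coverage
    paste0(g$description %||% "",
           if (!is.null(g$west)) paste0(
             if (!is.null(g$description)) " " else "",
             "Bounding box: ", num_chr(g$west), " W to ", num_chr(g$east),
             " E, ", num_chr(g$south), " S to ", num_chr(g$north), " N."))
  } else NULL
  temp <- if (!is.null(m$temporal_coverage)) {
    paste0(m$temporal_coverage$start, " to ", m$temporal_coverage$end)
  } else NULL
  dataset_desc <- if (!is.null(stats)) {
    paste0("The dataset comprises ", stats$record_count %||% "?",
           " records with core type ", stats$core_type %||% "?",
           if (length(stats$extensions))
             paste0(", with extensions: ", paste(stats$extensions, collapse = ", "))
           else ", with no extensions", ".")
  } else NULL
  content <- list(
    "Title" = m$title,
    "Authors" = paste(authors, collapse = "; "),
    "Abstract" = m$abstract,
    "Keywords" = if (!is.null(m$keywords)) paste(m$keywords, collapse = ", ") else NULL,
    "Taxonomic Coverage" = if (!is.null(tax)) paste(tax, collapse = "\n") else NULL,
    "Geographic Coverage" = geo,
    "Temporal Coverage" = temp,
    "Methods" = m$methods,
    "Dataset Description" = dataset_desc,
    "Rights" = m$rights,
    "References" = m$citation
  )
  sections <- vapply(DATA_PAPER_SECTIONS, function(s) {
    paste0("## ", s, "\n\n", placeholder_or(content[[s]]), "\n")
  }, character(1))
  paste(sections, collapse = "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

default_citation <- function(m, versions) {
  latest <- versions[[1]]
  year <- substr(latest$timestamp %||% "", 1, 4)
  paste0(paste(vapply(m$creators, `[[`, character(1), "name"), collapse = ", "),
         " (", year, "). ", m$title, ". Version ", latest$version_number, ".")
}

#' Render a static dataset summary page
#'
#' A self-contained HTML page showing the dataset metadata, a download link
#' for the latest archive, the version history (newest first) and the
#' citation string (auto-composed as "creators (year). title. version." when
#' the metadata carries none).
#'
#' @param m An [eml_metadata()] object.
#' @param d The latest [archive_descriptor()] (may be `NULL` for a
#'   metadata-only dataset).
#' @param versions List of published versions (as returned by [publish()]),
#'   any order; rendered newest first.
#' @return HTML text (single string).
#' @export
render_summary_page <- function(m, d = NULL, versions) {
  if (!length(versions)) {
    usage_error("cannot render a summary page with no published versions")
  }
  ord <- order(vapply(versions, function(v) v$version_number, numeric(1)),
               decreasing = TRUE)
  versions <- versions[ord]
  latest <- versions[[1]]
  citation <- m$citation %||% default_citation(m, versions)
  rows <- vapply(versions, function(v) {
    paste0("<tr><td>", v$version_number, "</td><td>",
           html_escape(v$timestamp %||% ""), "</td><td>",
           v$record_count %||% 0, "</td><td><a href=\"",
           html_escape(v$archive_path %||% ""), "\">archive</a></td></tr>")
  }, character(1))
  creators <- paste(vapply(m$creators, function(cr) {
    html_escape(paste0(cr$name,
                       if (!is.null(cr$organization)) paste0(" (", cr$organization, ")") else ""))
  }, character(1)), collapse = "; ")
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n<title>",
    html_escape(m$title), "</title>\n<style>body{font-family:sans-serif;max-width:50em;margin:2em auto}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;padding:0.3em}</style>\n",
    "</head>\n<body>\n",
    "<h1>", html_escape(m$title), "</h1>\n",
    "<p class=\"creators\">", creators, "</p>\n",
    if (!is.null(m$abstract)) paste0("<h2>Abstract</h2>\n<p>", html_escape(m$abstract), "</p>\n") else "",
    if (!is.null(m$rights)) paste0("<h2>Rights</h2>\n<p>", html_escape(m$rights), "</p>\n") else "",
    "<h2>Download</h2>\n<p><a href=\"", html_escape(latest$archive_path %||% ""),
    "\">Darwin Core Archive (version ", latest$version_number, ")</a></p>\n",
    "<h2>Citation</h2>\n<p>", html_escape(citation), "</p>\n",
    "<h2>Versions</h2>\n<table>\n<tr><th>Version</th><th>Published</th>",
    "<th>Records</th><th>Archive</th></tr>\n",
    paste(rows, collapse = "\n"), "\n</table>\n",
    "</body>\n</html>\n")
}
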