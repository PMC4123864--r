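# Term registry: Darwin Core terms, the two built-in cores (Occurrence,
# Taxon) and the Simple Multimedia extension, plus a parser for
# extension-definition XML documents in the resource-registry style.

#' Construct a Darwin Core term
#'
#' A term is a vocabulary entry identified by its qualified URI; the simple
#' name is the last path component.  Two terms are equal if and only if their
#' qualified names are equal.
#'
#' @param qualified_name Full term URI, e.g.
#'   `"http://rs.tdwg.org/dwc/terms/scientificName"`.
#' @param simple_name Short token; derived from the URI when omitted.
#' @return An object of class `dwca_term` with fields `qualified_name`,
#'   `simple_name` and `namespace`.
#' @examples
#' dwc_term("http://rs.tdwg.org/dwc/terms/scientificName")
#' @export
dwc_term <- function(qualified_name, simple_name = NULL) {
  if (!is_string(qualified_name) || !nzchar(qualified_name)) {
    usage_error("qualified_name must be a non-empty string")
  }
  split_at <- max(gregexpr("[/#]", qualified_name)[[1]])
  if (is.null(simple_name)) {
    simple_name <- if (split_at > 0) substring(qualified_name, split_at + 1L) else qualified_name
  }
  if (grepl("\\s", simple_name)) {
    usage_error(paste0("term simple name contains whitespace: '", simple_name, "'"))
  }
  namespace <- if (split_at > 0) substring(qualified_name, 1L, split_at) else ""
  structure(
    list(qualified_name = qualified_name, simple_name = simple_name,
         namespace = namespace),
    class = "dwca_term"
  )
}

#' @export
print.dwca_term <- function(x, ...) {
  cat("<dwca_term> ", x$simple_name, " (", x$qualified_name, ")\n", sep = "")
  invisible(x)
}

#' @export
`==.dwca_term` <- function(e1, e2) {
  identical(e1$qualified_name, e2$qualified_name)
}

#' Construct a row-type schema
#'
#' A schema is an ordered set of terms for one rowType (a core or an
#' extension), optionally designating one term as the record identifier
#' (occurrenceID for the Occurrence Core, taxonID for the Taxon Core).
#'
#' @param row_type URI identifying the schema's rowType.
#' @param terms List of [dwc_term()] objects, unique by qualified name.
#' @param id_term Optional identifier term; must be a member of `terms`.
#' @param is_core Logical; `TRUE` only for the built-in cores.
#' @param title Optional human-readable label.
#' @return An object of class `dwca_schema`.
#' @export
dwc_schema <- function(row_type, terms, id_term = NULL, is_core = FALSE,
                       title = NULL) {
  if (!is_string(row_type) || !nzchar(row_type)) {
    schema_error("schema rowType must be a non-empty string")
  }
  quals <- vapply(terms, function(t) t$qualified_name, character(1))
  dup <- quals[duplicated(quals)]
  if (length(dup)) {
    schema_error(paste0("duplicate term in schema: ", paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(id_term) && !(id_term$qualified_name %in% quals)) {
    schema_error(paste0("id term ", id_term$qualified_name,
                        " is not a member of the schema"))
  }
  structure(
    list(row_type = row_type, terms = terms, id_term = id_term,
         is_core = isTRUE(is_core), title = title),
    class = "dwca_schema"
  )
}

#' @export
print.dwca_schema <- function(x, ...) {
  cat("<dwca_schema> ", x$row_type,
      if (x$is_core) " [core]" else "",
      "\n  terms: ", length(x$terms),
      if (!is.null(x$id_term)) paste0("\n  id term: ", x$id_term$simple_name) else "",
      "\n", sep = "")
  invisible(x)
}

.schema_cache <- new.env(parent = emptyenv())

schema_file <- function(name) {
  system.file("extdata", "schemas", name, package = "dwca", mustWork = TRUE)
}

#' Built-in schemas
#'
#' Returns the bundled schema definitions: the Occurrence Core, the Taxon
#' Core and the Simple Multimedia extension.  The two cores carry their
#' identifier terms (occurrenceID and taxonID).  The result is identical
#' across calls.
#'
#' @return A named list of [dwc_schema()] objects
#'   (`occurrence`, `taxon`, `multimedia`).
#' @examples
#' names(builtin_schemas())
#' builtin_schemas()$occurrence$id_term$simple_name
#' @export
builtin_schemas <- function() {
  if (!is.null(.schema_cache$builtin)) {
    return(.schema_cache$builtin)
  }
  occ <- parse_extension_definition(schema_file("dwc_occurrence.xml"))
  tax <- parse_extension_definition(schema_file("dwc_taxon.xml"))
  med <- parse_extension_definition(schema_file("multimedia.xml"))
  occ$is_core <- TRUE
  tax$is_core <- TRUE
  occ$id_term <- lookup_term("occurrenceID", occ)
  tax$id_term <- lookup_term("taxonID", tax)
  out <- list(occurrence = occ, taxon = tax, multimedia = med)
  .schema_cache$builtin <- out
  out
}

#' Resolve a term name within a schema
#'
#' Resolution is by exact qualified name first, then by case-insensitive
#' simple name.  A name matching several terms' simple names resolves to the
#' first in schema order with a warning.  A miss returns `NULL` rather than
#' raising an error.
#'
#' @param name Term name: a qualified URI or a simple name.
#' @param schema A [dwc_schema()].
#' @return The matching `dwca_term`, or `NULL` when not found.
#' @examples
#' lookup_term("scientificName", builtin_schemas()$occurrence)
#' @export
lookup_term <- function(name, schema) {
  if (!is_string(name) || !nzchar(name)) {
    usage_error("term name must be a non-empty string")
  }
  quals <- vapply(schema$terms, function(t) t$qualified_name, character(1))
  hit <- which(quals == name)
  if (!length(hit)) {
    simples <- vapply(schema$terms, function(t) tolower(t$simple_name), character(1))
    hit <- which(simples == tolower(name))
    if (length(hit) > 1L) {
      warning("term name '", name, "' is ambiguous in ", schema$row_type,
              "; using the first match in schema order", call. = FALSE)
      hit <- hit[1L]
    }
  }
  if (!length(hit)) return(NULL)
  schema$terms[[hit[1L]]]
}

#' Parse an extension-definition XML document
#'
#' Reads a schema definition in the resource-registry style: a root element
#' carrying a `rowType` attribute and repeated `property` children each
#' carrying a `qualName` term URI.  Properties are kept in document order.
#' Unknown attributes are ignored (logged when `options(dwca.verbose=TRUE)`).
#'
#' @param xml Path to an XML file, or a string of XML text.
#' @return A non-core [dwc_schema()].  If the root carries a `subject`
#'   attribute naming one of its terms (e.g. `"dwc:occurrenceID"`), that term
#'   is recorded as the schema's identifier term.
#' @export
parse_extension_definition <- function(xml) {
  doc <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) parse_error(paste0("malformed extension definition: ",
                                           conditionMessage(e)))
  )
  root <- xml2::xml_root(doc)
  row_type <- xml2::xml_attr(root, "rowType")
  if (is.na(row_type) || !nzchar(row_type)) {
    schema_error("extension definition lacks a rowType attribute on its root element")
  }
  known_root <- c("rowType", "title", "subject")
  extra <- setdiff(names(xml2::xml_attrs(root)), known_root)
  if (length(extra)) {
    dwca_log("ignoring unknown root attributes: ", paste(extra, collapse = ", "))
  }
  props <- xml2::xml_find_all(root, ".//*[local-name()='property']")
  terms <- lapply(props, function(p) {
    qual <- xml2::xml_attr(p, "qualName")
    if (is.na(qual) || !nzchar(qual)) {
      schema_error("property element lacks a qualName attribute")
    }
    extra <- setdiff(names(xml2::xml_attrs(p)), c("qualName", "name"))
    if (length(extra)) {
      dwca_log("ignoring unknown property attributes: ", paste(extra, collapse = ", "))
    }
    dwc_term(qual)
  })
  quals <- vapply(terms, function(t) t$qualified_name, character(1))
  dup <- unique(quals[duplicated(quals)])
  if (length(dup)) {
    schema_error(paste0("term listed twice in extension definition: ",
                        paste(dup, collapse = ", ")))
  }
  sch <- dwc_schema(row_type, terms, is_core = FALSE,
                    title = xml2::xml_attr(root, "title"))
  subject <- xml2::xml_attr(root, "subject")
  if (!is.na(subject) && nzchar(subject)) {
    simple <- sub("^.*:", "", subject)
    sch$id_term <- lookup_term(simple, sch)
  }
  sch
}
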