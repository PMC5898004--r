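# Reading SBML / CellML documents into the canonical tree.

VERBATIM_CONTAINERS <- c("notes", "annotation", "documentation")

#' Parse an SBML or CellML document
#'
#' Reads well-formed XML and returns a canonicalized model document. The
#' canonical form sorts attributes by name, rewrites namespace prefixes to a
#' stable table, drops inter-element whitespace, and trims/collapses text
#' everywhere except inside `notes`, `annotation` and `documentation`
#' subtrees, whose text is kept verbatim (human-readable descriptions are
#' semantically meaningful; indentation is not). Schema validation is not
#' performed: well-formedness plus root-element detection only.
#'
#' @param x XML as a raw vector, a single string, or a file path.
#' @param model_id Repository identifier of the model.
#' @param version_id Version label of this document.
#' @param timestamp Release instant (POSIXct, or an ISO-8601 string; UTC).
#' @param source_uri Optional origin of the bytes.
#' @return A `model_document`: list with `format` ("SBML" or "CellML"),
#'   `model_id`, `version_id`, `timestamp`, `root` (canonical tree) and
#'   `source_uri`.
#' @examples
#' sbml <- '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
#'            <model id="m"/></sbml>'
#' doc <- parse_model(sbml, "M0001", "1", "2005-04-11")
#' doc$format
#' @export
parse_model <- function(x, model_id = "", version_id = "",
                        timestamp = as.POSIXct(NA), source_uri = "") {
  xdoc <- tryCatch(
    {
      if (is.raw(x)) xml2::read_xml(x)
      else if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x))
        xml2::read_xml(x)
      else xml2::read_xml(paste(x, collapse = "\n"))
    },
    error = function(e) stop("XML parse error: ", conditionMessage(e), call. = FALSE)
  )
  root_el <- xml2::xml_root(xdoc)
  local <- xml2::xml_name(root_el)
  root_ns <- xml2::xml_find_chr(root_el, "string(namespace-uri(.))")
  format <- if (identical(local, "sbml")) {
    "SBML"
  } else if (identical(local, "model") && grepl("cellml", root_ns, fixed = TRUE)) {
    "CellML"
  } else {
    stop("unsupported format: root element <", local, "> is neither SBML nor CellML",
         call. = FALSE)
  }
  ns_map <- tryCatch(xml2::xml_ns(xdoc), error = function(e) character())
  root <- build_tree(root_el, ns_map, verbatim = FALSE)
  new_model_document(format, model_id, version_id, timestamp, root, source_uri)
}

new_model_document <- function(format, model_id, version_id, timestamp, root,
                               source_uri = "") {
  if (inherits(timestamp, "Date")) timestamp <- as.POSIXct(timestamp, tz = "UTC")
  if (is.character(timestamp))
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  structure(list(format = format, model_id = model_id, version_id = version_id,
                 timestamp = timestamp, root = root, source_uri = source_uri),
            class = "model_document")
}

#' @export
print.model_document <- function(x, ...) {
  cat(sprintf("<model_document> %s  model=%s version=%s  (%d element nodes)\n",
              x$format, x$model_id, x$version_id, count_element_nodes(x$root)))
  invisible(x)
}

is_model_document <- function(x) inherits(x, "model_document")

# xml2 element -> canonical tree node
build_tree <- function(el, ns_map, verbatim) {
  local <- xml2::xml_name(el)
  nsuri <- xml2::xml_find_chr(el, "string(namespace-uri(.))")
  raw_attrs <- xml2::xml_attrs(el, ns_map)
  if (length(raw_attrs))
    raw_attrs <- raw_attrs[names(raw_attrs) != "xmlns" &
                             !startsWith(names(raw_attrs), "xmlns:")]
  attrs <- character(0)
  if (length(raw_attrs)) {
    canon_names <- vapply(names(raw_attrs), function(nm) {
      if (grepl(":", nm, fixed = TRUE)) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        uri <- unname(ns_map[parts[1]])
        if (is.na(uri) || !length(uri)) nm else paste0("{", uri, "}", parts[2])
      } else nm
    }, character(1))
    attrs <- setNames(unname(raw_attrs), canon_names)
  }
  verbatim_here <- verbatim || local %in% VERBATIM_CONTAINERS
  children <- list()
  for (k in xml2::xml_contents(el)) {
    tp <- xml2::xml_type(k)
    if (tp == "element") {
      children[[length(children) + 1L]] <- build_tree(k, ns_map, verbatim_here)
    } else if (tp %in% c("text", "cdata")) {
      txt <- xml2::xml_text(k)
      if (verbatim_here) {
        if (nzchar(trimws(txt)))
          children[[length(children) + 1L]] <- xml_textnode(txt)
      } else {
        norm <- gsub("\\s+", " ", trimws(txt))
        if (nzchar(norm))
          children[[length(children) + 1L]] <- xml_textnode(norm)
      }
    } # comments / PIs dropped: not part of the model
  }
  xml_element(local, nsuri, attrs, children)
}
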