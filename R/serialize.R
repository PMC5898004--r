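# Canonical serialization: deterministic, byte-identical for semantically
# identical trees. Attribute order, namespace prefixes, and whitespace are
# all normalized, so cosmetic edits vanish under diff.

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  gsub("\"", "&quot;", xml_escape_text(x), fixed = TRUE)
}

# Collect namespace URIs: element URIs and attribute URIs, in preorder
# first-appearance order.
collect_ns <- function(root) {
  elem_uris <- character(0)
  attr_uris <- character(0)
  rec <- function(node) {
    if (!is_element(node)) return(invisible(NULL))
    if (nzchar(node$ns) && !(node$ns %in% elem_uris))
      elem_uris[[length(elem_uris) + 1L]] <<- node$ns
    for (nm in names(node$attrs)) {
      if (startsWith(nm, "{")) {
        uri <- sub("^\\{([^}]*)\\}.*$", "\\1", nm)
        if (!(uri %in% attr_uris)) attr_uris[[length(attr_uris) + 1L]] <<- uri
      }
    }
    for (k in node$children) rec(k)
  }
  rec(root)
  list(elem = elem_uris, attr = attr_uris)
}

#' Canonical XML serialization
#'
#' Produces the deterministic text form that both the line diff and
#' document-equality checks operate on. Two documents that differ only in
#' attribute order, namespace prefixes, or inter-element whitespace
#' serialize to identical bytes.
#'
#' @param x A `model_document` or a tree node.
#' @return A single string (UTF-8, trailing newline).
#' @export
canonical_serialize <- function(x) {
  root <- if (is_model_document(x)) x$root else x
  stopifnot(is_element(root))
  nss <- collect_ns(root)
  default_uri <- if (nzchar(root$ns)) root$ns else ""
  # prefix table: default for the root's namespace; ns2, ns3, ... for the rest
  other <- setdiff(unique(c(nss$elem, nss$attr)), default_uri)
  prefixes <- if (length(other)) setNames(paste0("ns", seq_along(other) + 1L), other)
              else character(0)
  # attributes in the default namespace still need an explicit prefix
  if (nzchar(default_uri) && default_uri %in% nss$attr)
    prefixes[default_uri] <- "ns1"

  decls <- character(0)
  if (nzchar(default_uri)) decls <- paste0(" xmlns=\"", xml_escape_attr(default_uri), "\"")
  if (length(prefixes)) {
    ord <- order(unname(prefixes), method = "radix")
    decls <- c(decls, paste0(" xmlns:", unname(prefixes)[ord], "=\"",
                             xml_escape_attr(names(prefixes)[ord]), "\""))
  }

  attr_str <- function(attrs) {
    if (!length(attrs)) return("")
    nm <- vapply(names(attrs), function(n) {
      if (startsWith(n, "{")) {
        uri <- sub("^\\{([^}]*)\\}.*$", "\\1", n)
        loc <- sub("^\\{[^}]*\\}", "", n)
        paste0(prefixes[[uri]], ":", loc)
      } else n
    }, character(1))
    ord <- order(nm, method = "radix")
    paste0(" ", nm[ord], "=\"", xml_escape_attr(unname(attrs))[ord], "\"",
           collapse = "")
  }
  tagname <- function(node) {
    if (!nzchar(node$ns) || identical(node$ns, default_uri)) node$label
    else paste0(prefixes[[node$ns]], ":", node$label)
  }
  open_tag <- function(node, extra = "") {
    xmlns_reset <- if (!nzchar(node$ns) && nzchar(default_uri)) " xmlns=\"\"" else ""
    paste0("<", tagname(node), extra, xmlns_reset, attr_str(node$attrs))
  }

  inline <- function(node) {
    if (!is_element(node)) return(xml_escape_text(node$value))
    if (!length(node$children)) return(paste0(open_tag(node), "/>"))
    paste0(open_tag(node), ">",
           paste(vapply(node$children, inline, character(1)), collapse = ""),
           "</", tagname(node), ">")
  }
  lines <- vector("list", 2L * count_all_nodes(root))
  li <- 0L
  emit <- function(x) { li <<- li + 1L; lines[[li]] <<- x }
  block <- function(node, depth, extra = "") {
    ind <- strrep("  ", depth)
    has_text <- any(!vapply(node$children, is_element, logical(1)))
    if (!length(node$children)) {
      emit(paste0(ind, open_tag(node, extra), "/>"))
    } else if (has_text) {
      emit(paste0(ind, open_tag(node, extra), ">",
                  paste(vapply(node$children, inline, character(1)),
                        collapse = ""),
                  "</", tagname(node), ">"))
    } else {
      emit(paste0(ind, open_tag(node, extra), ">"))
      for (k in node$children) block(k, depth + 1L)
      emit(paste0(ind, "</", tagname(node), ">"))
    }
  }
  block(root, 0L, extra = paste(decls, collapse = ""))
  paste0(paste(unlist(lines[seq_len(li)]), collapse = "\n"), "\n")
}

canonical_equal <- function(a, b) {
  identical(canonical_serialize(a), canonical_serialize(b))
}
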