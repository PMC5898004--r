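# In-memory XML tree used by the whole package.
#
# An element node is a list with fields
#   kind     "element"
#   label    local name
#   ns       namespace URI ("" when none)
#   attrs    named character vector, names are canonical attribute names
#            ("local" or "{uri}local"), always sorted by name
#   children list of element/text nodes, document order
#   uid      integer, unique within a tree (assigned by index_tree / tag_uids)
# A text node is list(kind = "text", value = <string>, uid = <int>).
#
# Paths are XPath-like: "/sbml[1]/model[1]/listOfSpecies[1]/species[2]" for
# elements (1-based rank among same-label siblings), plus "/@id" for an
# attribute of the addressed element and "/text()[2]" for its 2nd text child.

xml_element <- function(label, ns = "", attrs = character(), children = list()) {
  if (length(attrs)) {
    attrs <- attrs[order(names(attrs), method = "radix")]
    if (anyDuplicated(names(attrs)))
      stop("duplicate attribute names under one element: ",
           paste(names(attrs)[duplicated(names(attrs))], collapse = ", "))
  }
  structure(list(kind = "element", label = label, ns = ns,
                 attrs = attrs, children = children, uid = NA_integer_),
            class = "xml_tree_node")
}

xml_textnode <- function(value) {
  structure(list(kind = "text", value = as.character(value), uid = NA_integer_),
            class = "xml_tree_node")
}

is_element <- function(x) identical(x$kind, "element")

# safe attribute lookup on the named character vector (NULL when absent)
aget <- function(attrs, name) {
  if (length(attrs) && name %in% names(attrs)) unname(attrs[[name]]) else NULL
}

#' @export
print.xml_tree_node <- function(x, ...) {
  if (is_element(x)) {
    cat("<", x$label, "> element, ", length(x$attrs), " attrs, ",
        length(x$children), " children\n", sep = "")
  } else {
    cat("text node: ", substr(x$value, 1, 60), "\n", sep = "")
  }
  invisible(x)
}

# Assign fresh uids over the whole tree (preorder). Returns the tree.
tag_uids <- function(root) {
  counter <- 0L
  walk <- function(node) {
    counter <<- counter + 1L
    node$uid <- counter
    if (is_element(node) && length(node$children))
      node$children <- lapply(node$children, walk)
    node
  }
  walk(root)
}

count_all_nodes <- function(node) {
  if (!is_element(node)) return(1L)
  1L + sum(vapply(node$children, count_all_nodes, integer(1)))
}

# Flatten a tree into parallel per-node vectors (elements and text nodes).
# Used by the matcher, entity counting oracle checks, and path lookup.
# retag = FALSE keeps existing uids (they must then be unique already).
index_tree <- function(root, retag = TRUE) {
  if (retag) root <- tag_uids(root)
  n <- count_all_nodes(root)
  uid <- integer(n); parent <- integer(n); kind <- character(n)
  label <- character(n); ns <- character(n); value <- rep(NA_character_, n)
  path <- character(n)
  nodes <- vector("list", n)
  i <- 0L

  rec <- function(node, parent_uid, base_path, pos) {
    p <- paste0(base_path, "/", node$label, "[", pos, "]")
    i <<- i + 1L
    uid[i] <<- node$uid; parent[i] <<- parent_uid; kind[i] <<- "element"
    label[i] <<- node$label; ns[i] <<- node$ns; path[i] <<- p
    nodes[[i]] <<- node
    kids <- node$children
    if (length(kids)) {
      lab_seen <- new.env(parent = emptyenv())
      txt_seen <- 0L
      for (k in kids) {
        if (is_element(k)) {
          key <- k$label
          r <- if (is.null(lab_seen[[key]])) 1L else lab_seen[[key]] + 1L
          lab_seen[[key]] <- r
          rec(k, node$uid, p, r)
        } else {
          txt_seen <- txt_seen + 1L
          i <<- i + 1L
          uid[i] <<- k$uid; parent[i] <<- node$uid; kind[i] <<- "text"
          label[i] <<- "text()"; ns[i] <<- ""; value[i] <<- k$value
          path[i] <<- paste0(p, "/text()[", txt_seen, "]")
          nodes[[i]] <<- k
        }
      }
    }
    invisible(NULL)
  }
  rec(root, 0L, "", 1L)
  list(root = root,
       tab = data.frame(uid = uid, parent = parent, kind = kind, label = label,
                        ns = ns, value = value, path = path,
                        order = seq_len(n), stringsAsFactors = FALSE),
       nodes = setNames(nodes, as.character(uid)))
}

# --- path utilities -------------------------------------------------------

parse_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, nzchar(path))
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  steps <- lapply(parts, function(p) {
    if (startsWith(p, "@")) return(list(type = "attr", name = substring(p, 2L)))
    if (grepl("^text\\(\\)\\[\\d+\\]$", p))
      return(list(type = "text", rank = as.integer(sub("^text\\(\\)\\[(\\d+)\\]$", "\\1", p)))) # nolint
    m <- regmatches(p, regexec("^(.*)\\[(\\d+)\\]$", p))[[1]]
    if (length(m) != 3L) stop("malformed path step: ", p)
    list(type = "element", label = m[2], rank = as.integer(m[3]))
  })
  steps
}

# Resolve a path to a child-index chain (positions in $children lists).
# Returns integer vector, or NULL if unresolvable. The first step must
# address the root element itself.
resolve_path <- function(root, path) {
  steps <- parse_path(path)
  s1 <- steps[[1]]
  if (s1$type != "element" || s1$label != root$label || s1$rank != 1L) return(NULL)
  idx <- integer(0)
  node <- root
  for (s in steps[-1]) {
    if (s$type == "attr") return(list(idx = idx, attr = s$name))
    if (s$type == "text") {
      seen <- 0L
      hit <- NA_integer_
      for (i in seq_along(node$children)) {
        if (!is_element(node$children[[i]])) {
          seen <- seen + 1L
          if (seen == s$rank) { hit <- i; break }
        }
      }
      if (is.na(hit)) return(NULL)
      return(list(idx = c(idx, hit), text = TRUE))
    }
    seen <- 0L
    hit <- NA_integer_
    for (i in seq_along(node$children)) {
      k <- node$children[[i]]
      if (is_element(k) && k$label == s$label) {
        seen <- seen + 1L
        if (seen == s$rank) { hit <- i; break }
      }
    }
    if (is.na(hit)) return(NULL)
    idx <- c(idx, hit)
    node <- node$children[[hit]]
  }
  list(idx = idx)
}

tree_get <- function(root, idx) {
  node <- root
  for (i in idx) node <- node$children[[i]]
  node
}

# Functional update: replace/modify the node at child-index chain `idx`.
# fun(node) returning NULL deletes the node.
tree_modify <- function(root, idx, fun) {
  if (!length(idx)) {
    out <- fun(root)
    if (is.null(out)) stop("cannot delete the document root")
    return(out)
  }
  i <- idx[[1]]
  child <- tree_modify(root$children[[i]], idx[-1], fun)
  if (is.null(child)) root$children[[i]] <- NULL else root$children[[i]] <- child
  root
}

# Insert `node` into parent's children at global position `at` (clamped).
tree_insert_child <- function(root, parent_idx, node, at) {
  tree_modify(root, parent_idx, function(p) {
    kids <- p$children
    at <- max(1L, min(as.integer(at), length(kids) + 1L))
    p$children <- append(kids, list(node), after = at - 1L)
    p
  })
}

# Modify the node with the given uid anywhere in the tree; fun returning
# NULL removes it. Returns list(root=, found=).
mutate_uid <- function(root, uid, fun) {
  found <- FALSE
  rec <- function(node) {
    if (identical(node$uid, uid)) {
      found <<- TRUE
      return(fun(node))
    }
    if (is_element(node) && length(node$children) && !found) {
      kids <- list()
      for (k in node$children) {
        nk <- if (found) k else rec(k)
        if (!is.null(nk)) kids[[length(kids) + 1L]] <- nk
      }
      node$children <- kids
    }
    node
  }
  list(root = rec(root), found = found)
}

get_node_by_uid <- function(root, uid) {
  out <- NULL
  rec <- function(node) {
    if (!is.null(out)) return(invisible(NULL))
    if (identical(node$uid, uid)) { out <<- node; return(invisible(NULL)) }
    if (is_element(node)) for (k in node$children) rec(k)
  }
  rec(root)
  out
}

# uid -> path map (elements and text nodes), without reassigning uids
uid_paths <- function(root) {
  env <- new.env(parent = emptyenv())
  rec <- function(node, path) {
    env[[as.character(node$uid)]] <- path
    if (!is_element(node)) return(invisible(NULL))
    lab_seen <- new.env(parent = emptyenv())
    txt_seen <- 0L
    for (k in node$children) {
      if (is_element(k)) {
        r <- if (is.null(lab_seen[[k$label]])) 1L else lab_seen[[k$label]] + 1L
        lab_seen[[k$label]] <- r
        rec(k, paste0(path, "/", k$label, "[", r, "]"))
      } else {
        txt_seen <- txt_seen + 1L
        env[[as.character(k$uid)]] <- paste0(path, "/text()[", txt_seen, "]")
      }
    }
  }
  rec(root, paste0("/", root$label, "[1]"))
  env
}

subtree_uids <- function(node) {
  out <- integer(0)
  rec <- function(n) {
    out[[length(out) + 1L]] <<- n$uid
    if (is_element(n)) for (k in n$children) rec(k)
  }
  rec(node)
  out
}

count_element_nodes <- function(root) {
  if (!is_element(root)) return(0L)
  1L + sum(vapply(root$children, count_element_nodes, integer(1)))
}

# All descendant node records of a subtree in preorder, used when expanding
# triggered operations: elements, then per element its attributes and text kids.
subtree_records <- function(node, base_path) {
  out <- list()
  rec <- function(node, path) {
    if (!is_element(node)) return(invisible(NULL))
    out[[length(out) + 1L]] <<- list(kind = "element", path = path,
                                     label = node$label, ns = node$ns)
    for (a in names(node$attrs))
      out[[length(out) + 1L]] <<- list(kind = "attribute",
                                       path = paste0(path, "/@", a),
                                       value = unname(node$attrs[[a]]))
    lab_seen <- new.env(parent = emptyenv())
    txt_seen <- 0L
    for (k in node$children) {
      if (is_element(k)) {
        r <- if (is.null(lab_seen[[k$label]])) 1L else lab_seen[[k$label]] + 1L
        lab_seen[[k$label]] <- r
        rec(k, paste0(path, "/", k$label, "[", r, "]"))
      } else {
        txt_seen <- txt_seen + 1L
        out[[length(out) + 1L]] <<- list(kind = "text",
                                         path = paste0(path, "/text()[", txt_seen, "]"),
                                         value = k$value)
      }
    }
  }
  rec(node, base_path)
  out
}
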