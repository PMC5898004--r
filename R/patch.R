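# Replaying a delta: the correctness oracle for the diff.
# apply_delta(a, diff_models(a, b)) must canonical-equal b.

inconsistent_delta <- function(msg) {
  stop(structure(class = c("modevol_inconsistent_delta", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Apply a delta to a document
#'
#' Replays an edit script produced by [diff_models()] onto its base
#' document. Triggered operations are informational (the non-triggered
#' subtree operations carry the payload) and are skipped during replay.
#' Applying a delta to a document that is not its base raises an
#' `modevol_inconsistent_delta` error.
#'
#' @param a The base `model_document` (the `diff_models` first argument).
#' @param d A `delta`.
#' @return A `model_document` canonical-equal to the diff's second argument.
#' @export
apply_delta <- function(a, d) {
  stopifnot(is_model_document(a), inherits(d, "delta"))
  idx <- index_tree(a$root)
  root <- idx$root
  path2uid <- setNames(idx$tab$uid, idx$tab$path)

  res_uid <- function(path, what) {
    p <- strip_attr(path)
    if (!(p %in% names(path2uid)))
      inconsistent_delta(paste0(what, " path not found in base: ", path))
    path2uid[[p]]
  }
  strip_attr <- function(p) sub("/@[^/]+$", "", p)
  is_attr_path <- function(p) grepl("/@[^/]+$", p)
  attr_name <- function(p) sub("^.*/@", "", p)

  attr_sets <- list()    # uid -> named list(name = value or NULL-marker)
  text_updates <- list() # uid(text node) -> value
  del_uids <- integer(0)
  move_uids <- integer(0)
  placements <- list()

  for (op in d$ops) {
    if (op$triggered) next
    switch(paste(op$op_type, op$entity_kind),
      "delete element" = {
        del_uids <- c(del_uids, res_uid(op$old_path, "delete"))
      },
      "delete attribute" = {
        u <- res_uid(op$old_path, "delete-attr")
        an <- attr_name(op$old_path)
        node <- idx$nodes[[as.character(u)]]
        if (is.null(aget(node$attrs, an)))
          inconsistent_delta(paste0("attribute absent in base: ", op$old_path))
        attr_sets[[as.character(u)]] <- c(attr_sets[[as.character(u)]],
                                          setNames(list(NULL), an))
      },
      "delete text" = {
        del_uids <- c(del_uids, res_uid(op$old_path, "delete-text"))
      },
      "update attribute" = {
        u <- res_uid(op$old_path, "update-attr")
        an <- attr_name(op$old_path)
        node <- idx$nodes[[as.character(u)]]
        if (!identical(aget(node$attrs, an), op$old_value))
          inconsistent_delta(paste0("attribute value mismatch at ", op$old_path))
        attr_sets[[as.character(u)]] <- c(attr_sets[[as.character(u)]],
                                          setNames(list(op$new_value), an))
      },
      "update text" = {
        u <- res_uid(op$old_path, "update-text")
        nd <- idx$nodes[[as.character(u)]]
        if (is_element(nd) || !identical(nd$value, op$old_value))
          inconsistent_delta(paste0("text value mismatch at ", op$old_path))
        text_updates[[as.character(u)]] <- op$new_value
      },
      "move element" = {
        u <- res_uid(op$old_path, "move")
        move_uids <- c(move_uids, u)
        placements[[length(placements) + 1L]] <-
          list(kind = "move", uid = u, new_path = op$new_path,
               new_index = op$new_index)
      },
      "insert element" = {
        if (is.null(op$payload))
          inconsistent_delta("element insert without payload cannot be replayed")
        placements[[length(placements) + 1L]] <-
          list(kind = "insert", node = op$payload, new_path = op$new_path,
               new_index = op$new_index)
      },
      "insert attribute" = {
        placements[[length(placements) + 1L]] <-
          list(kind = "attr", new_path = op$new_path, value = op$new_value)
      },
      "insert text" = {
        placements[[length(placements) + 1L]] <-
          list(kind = "text", new_path = op$new_path, value = op$new_value,
               new_index = op$new_index)
      },
      inconsistent_delta(paste("unsupported op:", op$op_type, op$entity_kind))
    )
  }

  # phase 1+2: value updates, then detach moves / apply deletes, in one walk
  detached <- new.env(parent = emptyenv())
  rebuild <- function(node) {
    key <- as.character(node$uid)
    if (!is_element(node)) {
      if (!is.null(text_updates[[key]])) node$value <- text_updates[[key]]
      if (node$uid %in% del_uids) return(NULL)
      return(node)
    }
    as_ <- attr_sets[[key]]
    if (!is.null(as_)) {
      attrs <- as.list(node$attrs)
      for (an in names(as_)) attrs[[an]] <- as_[[an]]
      node$attrs <- if (length(attrs)) {
        v <- unlist(attrs); v[order(names(v), method = "radix")]
      } else character(0)
    }
    kids <- list()
    for (k in node$children) {
      nk <- rebuild(k)
      if (!is.null(nk)) kids[[length(kids) + 1L]] <- nk
    }
    node$children <- kids
    if (node$uid %in% move_uids) { detached[[key]] <- node; return(NULL) }
    if (node$uid %in% del_uids) return(NULL)
    node
  }
  root <- rebuild(root)
  if (is.null(root)) inconsistent_delta("delta deletes the document root")

  # phase 3: placements, parents shallow-first, then ascending child index
  parent_path <- function(p) sub("/[^/]+$", "", p)
  depth_of <- function(p) lengths(regmatches(p, gregexpr("/", p, fixed = TRUE)))
  if (length(placements)) {
    pp <- vapply(placements, function(x) parent_path(x$new_path), character(1))
    dp <- depth_of(pp)
    ni <- vapply(placements, function(x)
      if (is.null(x$new_index) || is.na(x$new_index)) .Machine$integer.max
      else as.integer(x$new_index), integer(1))
    ord <- order(dp, pp, ni, method = "radix")
    for (i in ord) {
      pl <- placements[[i]]
      if (pl$kind == "attr") next  # handled after structure settles
      loc <- resolve_path(root, parent_path(pl$new_path))
      if (is.null(loc))
        inconsistent_delta(paste0("cannot resolve insertion parent for ",
                                  pl$new_path))
      node <- switch(pl$kind,
        move = {
          n <- detached[[as.character(pl$uid)]]
          if (is.null(n)) inconsistent_delta("moved node lost during replay")
          n
        },
        insert = pl$node,
        text = xml_textnode(pl$value))
      at <- pl$new_index
      if (is.null(at) || is.na(at)) at <- target_rank_position(root, loc$idx, pl$new_path)
      root <- tree_insert_child(root, loc$idx, node, at)
    }
    for (i in ord) {
      pl <- placements[[i]]
      if (pl$kind != "attr") next
      loc <- resolve_path(root, pl$new_path)
      if (is.null(loc) || is.null(loc$attr))
        inconsistent_delta(paste0("cannot resolve attribute insert ", pl$new_path))
      root <- tree_modify(root, loc$idx, function(n) {
        a <- c(n$attrs, setNames(pl$value, loc$attr))
        n$attrs <- a[order(names(a), method = "radix")]
        n
      })
    }
  }
  new_model_document(a$format, a$model_id, d$version_to, a$timestamp,
                     tag_uids(root), a$source_uri)
}

# fallback placement when a hand-written delta lacks new_index: insert so the
# node obtains the requested rank among same-label siblings
target_rank_position <- function(root, parent_idx, new_path) {
  steps <- parse_path(new_path)
  last <- steps[[length(steps)]]
  parent <- tree_get(root, parent_idx)
  want_rank <- last$rank
  seen <- 0L
  for (i in seq_along(parent$children)) {
    k <- parent$children[[i]]
    hit <- if (last$type == "text") !is_element(k)
           else is_element(k) && k$label == last$label
    if (hit) {
      seen <- seen + 1L
      if (seen == want_rank) return(i)
    }
  }
  length(parent$children) + 1L
}
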