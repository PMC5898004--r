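# Typed edit scripts between two versions of a model.

OP_TYPES <- c("insert", "delete", "update", "move")
ENTITY_KINDS <- c("element", "attribute", "text")

new_op <- function(op_type, entity_kind, old_path = NA_character_,
                   new_path = NA_character_, old_value = NA_character_,
                   new_value = NA_character_, triggered = FALSE,
                   label = NA_character_, ns = NA_character_,
                   new_index = NA_integer_, payload = NULL) {
  structure(list(op_type = op_type, entity_kind = entity_kind,
                 old_path = old_path, new_path = new_path,
                 old_value = old_value, new_value = new_value,
                 triggered = isTRUE(triggered), label = label, ns = ns,
                 new_index = new_index, payload = payload),
            class = "diff_op")
}

#' @export
format.diff_op <- function(x, ...) {
  loc <- if (!is.na(x$old_path) && !is.na(x$new_path) &&
             !identical(x$old_path, x$new_path))
    paste(x$old_path, "->", x$new_path)
  else if (!is.na(x$old_path)) x$old_path else x$new_path
  val <- if (!is.na(x$old_value) && !is.na(x$new_value))
    sprintf(" [%s -> %s]", x$old_value, x$new_value)
  else if (!is.na(x$new_value)) sprintf(" [%s]", x$new_value)
  else if (!is.na(x$old_value)) sprintf(" [%s]", x$old_value)
  else ""
  sprintf("%s%-7s %-9s %s%s", if (x$triggered) "~" else " ",
          x$op_type, x$entity_kind, loc, val)
}

#' @export
print.diff_op <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

op_core <- function(op) {
  c(op_type = op$op_type, entity_kind = op$entity_kind,
    old_path = op$old_path, new_path = op$new_path)
}

#' Summarize an op list into (op_type x entity_kind) counts
#' @keywords internal
#' @export
summarize_ops <- function(ops) {
  tab <- matrix(0L, nrow = length(OP_TYPES), ncol = length(ENTITY_KINDS),
                dimnames = list(OP_TYPES, ENTITY_KINDS))
  trig <- 0L
  for (op in ops) {
    tab[op$op_type, op$entity_kind] <- tab[op$op_type, op$entity_kind] + 1L
    if (op$triggered) trig <- trig + 1L
  }
  list(by_type_kind = tab, triggered = trig, total = length(ops))
}

new_delta <- function(model_id, version_from, version_to, ops,
                      line_inserts = NA_integer_, line_deletes = NA_integer_) {
  structure(list(model_id = model_id, version_from = version_from,
                 version_to = version_to, ops = ops,
                 summary = summarize_ops(ops),
                 line_inserts = as.integer(line_inserts),
                 line_deletes = as.integer(line_deletes)),
            class = "delta")
}

#' @export
print.delta <- function(x, ...) {
  cat(sprintf("<delta> %s: %s -> %s | %d ops (%d triggered), lines +%d/-%d\n",
              x$model_id, x$version_from, x$version_to, x$summary$total,
              x$summary$triggered, x$line_inserts, x$line_deletes))
  s <- x$summary$by_type_kind
  for (t in rownames(s)) if (sum(s[t, ]) > 0)
    cat(sprintf("  %-7s %s\n", t,
                paste(colnames(s)[s[t, ] > 0], s[t, s[t, ] > 0],
                      sep = "=", collapse = " ")))
  invisible(x)
}

# longest increasing subsequence -> indices kept (stable, prefers earlier
# elements on ties via strict patience sorting)
lis_indices <- function(x) {
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  tails <- integer(0)    # index into x of smallest tail of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails)
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid - 1L
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    if (lo > length(tails)) tails[lo] <- i else tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- k; k <- prev[k] }
  out
}

#' Structural diff between two versions of a model
#'
#' Computes the typed edit script transforming `a` into `b`: inserts,
#' deletes, updates and moves over element, attribute and text nodes.
#' Operations on strict descendants of an inserted or deleted subtree are
#' flagged `triggered` (they are implied by the subtree operation) and are
#' included in the summary counts. The delta also carries plain line-diff
#' counts computed on the canonical serializations.
#'
#' A move is a matched element whose parent changed, or — within a matched
#' parent — an element off the longest increasing subsequence of its label
#' group's target-side order (so a single relocation reports a single move,
#' not a cascade of rank shifts).
#'
#' @param a,b `model_document`s with the same `model_id`.
#' @param sim_threshold Passed to [match_trees()].
#' @return A `delta` object.
#' @export
diff_models <- function(a, b, sim_threshold = 0.7) {
  stopifnot(is_model_document(a), is_model_document(b))
  if (!identical(a$model_id, b$model_id))
    stop("model_id mismatch: distinct models are not comparable histories (",
         a$model_id, " vs ", b$model_id, ")", call. = FALSE)
  m <- match_trees(index_tree(a$root), index_tree(b$root), sim_threshold)
  ops <- derive_ops(m)
  ld <- line_diff(canonical_serialize(a), canonical_serialize(b))
  new_delta(a$model_id, a$version_id, b$version_id, ops,
            line_inserts = ld[["line_inserts"]],
            line_deletes = ld[["line_deletes"]])
}

derive_ops <- function(m) {
  ia <- m$a; ib <- m$b; map <- m$map; rmap <- m$rmap
  ta <- ia$tab; tb <- ib$tab
  ops <- list()
  push <- function(op) ops[[length(ops) + 1L]] <<- op

  ea <- ta[ta$kind == "element", , drop = FALSE]
  eb <- tb[tb$kind == "element", , drop = FALSE]
  unm_a <- ea$uid[is.na(map[ea$uid])]
  unm_b <- eb$uid[is.na(rmap[eb$uid])]
  # flat lookups keyed by uid (data.frame row access is too slow in the loops)
  pa_path <- setNames(ta$path, ta$uid); pb_path <- setNames(tb$path, tb$uid)
  pa_parent <- setNames(ta$parent, ta$uid); pb_parent <- setNames(tb$parent, tb$uid)
  pa_label <- setNames(ta$label, ta$uid); pb_label <- setNames(tb$label, tb$uid)
  pa_ns <- setNames(ta$ns, ta$uid); pb_ns <- setNames(tb$ns, tb$uid)
  in_unm_a <- logical(max(ta$uid)); in_unm_a[unm_a] <- TRUE
  in_unm_b <- logical(max(tb$uid)); in_unm_b[unm_b] <- TRUE

  # deletes: every unmatched a element; triggered iff its parent is also
  # unmatched. Attribute/text nodes of unmatched elements are triggered ops.
  for (ua in unm_a) {
    key <- as.character(ua)
    pa <- pa_parent[[key]]
    trig <- pa > 0L && in_unm_a[pa]
    p <- pa_path[[key]]
    push(new_op("delete", "element", old_path = p, triggered = trig,
                label = pa_label[[key]], ns = pa_ns[[key]]))
    node <- ia$nodes[[key]]
    for (an in names(node$attrs))
      push(new_op("delete", "attribute", old_path = paste0(p, "/@", an),
                  old_value = unname(node$attrs[[an]]), triggered = TRUE))
  }
  txt_a <- ta[ta$kind == "text", , drop = FALSE]
  for (i in which(txt_a$parent %in% unm_a)) {
    push(new_op("delete", "text", old_path = txt_a$path[i],
                old_value = txt_a$value[i], triggered = TRUE))
  }

  # inserts, mirrored; non-triggered element inserts carry their subtree
  # payload and global child index so the delta can be replayed.
  for (ub in unm_b) {
    key <- as.character(ub)
    pb <- pb_parent[[key]]
    trig <- pb > 0L && in_unm_b[pb]
    idx <- NA_integer_
    payload <- NULL
    node <- ib$nodes[[key]]
    if (!trig) {
      payload <- node
      idx <- child_global_index(ib, pb, ub)
    }
    p <- pb_path[[key]]
    push(new_op("insert", "element", new_path = p, triggered = trig,
                label = pb_label[[key]], ns = pb_ns[[key]],
                new_index = idx, payload = payload))
    for (an in names(node$attrs))
      push(new_op("insert", "attribute", new_path = paste0(p, "/@", an),
                  new_value = unname(node$attrs[[an]]), triggered = TRUE))
  }
  txt_b <- tb[tb$kind == "text", , drop = FALSE]
  for (i in which(txt_b$parent %in% unm_b)) {
    push(new_op("insert", "text", new_path = txt_b$path[i],
                new_value = txt_b$value[i], triggered = TRUE))
  }

  # matched element pairs: attributes, text children, moves
  txt_by_parent_a <- split(txt_a, as.character(txt_a$parent))
  txt_by_parent_b <- split(txt_b, as.character(txt_b$parent))
  empty_txt <- txt_a[0, , drop = FALSE]

  mt_a <- ea$uid[!is.na(map[ea$uid])]
  for (ua in mt_a) {
    ub <- map[ua]
    ka <- as.character(ua); kb <- as.character(ub)
    ra <- list(path = pa_path[[ka]], parent = pa_parent[[ka]],
               label = pa_label[[ka]], ns = pa_ns[[ka]])
    rb <- list(path = pb_path[[kb]], parent = pb_parent[[kb]])
    na_ <- ia$nodes[[ka]]; nb_ <- ib$nodes[[kb]]
    # attributes
    a_at <- na_$attrs; b_at <- nb_$attrs
    for (an in union(names(a_at), names(b_at))) {
      av <- aget(a_at, an); bv <- aget(b_at, an)
      if (is.null(av)) {
        push(new_op("insert", "attribute", new_path = paste0(rb$path, "/@", an),
                    new_value = unname(bv)))
      } else if (is.null(bv)) {
        push(new_op("delete", "attribute", old_path = paste0(ra$path, "/@", an),
                    old_value = unname(av)))
      } else if (!identical(av, bv)) {
        push(new_op("update", "attribute",
                    old_path = paste0(ra$path, "/@", an),
                    new_path = paste0(rb$path, "/@", an),
                    old_value = unname(av), new_value = unname(bv)))
      }
    }
    # text children: LCS-align equal values, pair leftovers positionally
    ta_txt <- txt_by_parent_a[[ka]] %||% empty_txt
    tb_txt <- txt_by_parent_b[[kb]] %||% empty_txt
    if (nrow(ta_txt) || nrow(tb_txt)) {
      al <- align_values(ta_txt$value, tb_txt$value)
      for (k in seq_len(nrow(al$pairs))) {
        i <- al$pairs[k, 1]; j <- al$pairs[k, 2]
        if (!identical(ta_txt$value[i], tb_txt$value[j]))
          push(new_op("update", "text", old_path = ta_txt$path[i],
                      new_path = tb_txt$path[j],
                      old_value = ta_txt$value[i], new_value = tb_txt$value[j]))
      }
      for (i in al$only_a)
        push(new_op("delete", "text", old_path = ta_txt$path[i],
                    old_value = ta_txt$value[i]))
      for (j in al$only_b)
        push(new_op("insert", "text", new_path = tb_txt$path[j],
                    new_value = tb_txt$value[j],
                    new_index = child_global_index(ib, ub, tb_txt$uid[j])))
    }
    # cross-parent move
    pa <- ra$parent; pb <- rb$parent
    if (pa > 0L && pb > 0L) {
      if (is.na(map[pa]) || map[pa] != pb) {
        push(new_op("move", "element", old_path = ra$path, new_path = rb$path,
                    label = ra$label, ns = ra$ns,
                    new_index = child_global_index(ib, pb, ub)))
      }
    }
  }

  # within-parent moves: per matched parent pair, per label group, mapped
  # children off the LIS of their target-side order
  ech_a <- split(ea$uid[ea$parent > 0L], as.character(ea$parent[ea$parent > 0L]))
  ech_b <- split(eb$uid[eb$parent > 0L], as.character(eb$parent[eb$parent > 0L]))
  for (ua in mt_a) {
    ub <- map[ua]
    ca <- ech_a[[as.character(ua)]]
    if (length(ca) < 2L) next
    ca <- ca[!is.na(map[ca])]
    ca <- ca[pb_parent[as.character(map[ca])] == ub]  # same-parent pairs only
    if (length(ca) < 2L) next
    cb_order <- ech_b[[as.character(ub)]]
    labs <- pa_label[as.character(ca)]
    for (lab in unique(labs)) {
      grp <- ca[labs == lab]
      if (length(grp) < 2L) next
      pos_b <- match(map[grp], cb_order)
      keep <- lis_indices(pos_b)
      moved <- setdiff(seq_along(grp), keep)
      for (i in moved) {
        ua2 <- grp[i]; ub2 <- map[ua2]
        push(new_op("move", "element",
                    old_path = pa_path[[as.character(ua2)]],
                    new_path = pb_path[[as.character(ub2)]],
                    label = lab, ns = pa_ns[[as.character(ua2)]],
                    new_index = child_global_index(ib, ub, ub2)))
      }
    }
  }

  sort_ops(ops)
}

child_global_index <- function(idx, parent_uid, child_uid) {
  node <- idx$nodes[[as.character(parent_uid)]]
  for (i in seq_along(node$children)) {
    if (identical(node$children[[i]]$uid, child_uid)) return(i)
  }
  NA_integer_
}

align_values <- function(va, vb) {
  n <- length(va); m <- length(vb)
  if (!n || !m) {
    return(list(pairs = matrix(integer(0), ncol = 2),
                only_a = seq_len(n), only_b = seq_len(m)))
  }
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m))
    L[i + 1L, j + 1L] <- if (identical(va[i], vb[j])) L[i, j] + 1L
                         else max(L[i, j + 1L], L[i + 1L, j])
  pairs <- matrix(integer(0), ncol = 2)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (identical(va[i], vb[j]) && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  free_a <- setdiff(seq_len(n), pairs[, 1])
  free_b <- setdiff(seq_len(m), pairs[, 2])
  k <- min(length(free_a), length(free_b))
  if (k > 0L)
    pairs <- rbind(pairs, cbind(free_a[seq_len(k)], free_b[seq_len(k)]))
  list(pairs = pairs,
       only_a = if (length(free_a) > k) free_a[(k + 1L):length(free_a)] else integer(0),
       only_b = if (length(free_b) > k) free_b[(k + 1L):length(free_b)] else integer(0))
}

sort_ops <- function(ops) {
  if (!length(ops)) return(ops)
  key1 <- vapply(ops, function(o)
    if (!is.na(o$old_path)) o$old_path else o$new_path, character(1))
  key2 <- vapply(ops, `[[`, character(1), "op_type")
  key3 <- vapply(ops, function(o)
    if (is.na(o$new_path)) "" else o$new_path, character(1))
  ops[order(key1, key2, key3, method = "radix")]
}
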