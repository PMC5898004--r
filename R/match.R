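# Node correspondence between two canonical trees.
#
# Three passes, deterministic, no randomness:
#   1. exact match on identity attributes (id / metaid / name) where the
#      (label, id) key is unique in both trees;
#   2. fixpoint propagation: matched parents match children that are unique
#      by label or by (label, id) within the pair; matched children match
#      their parents when labels agree;
#   3. greedy similarity matching of residual same-label elements by
#      subtree-token Jaccard similarity >= 0.7, ties broken by document
#      order.
# Passes 2 and 3 alternate until no new pairs appear. Roots are always
# mapped. Attribute and text nodes are aligned per matched element later,
# in the diff stage.

ID_ATTRS <- c("id", "metaid", "name")

node_idval <- function(node) {
  for (a in ID_ATTRS) {
    v <- aget(node$attrs, a)
    if (!is.null(v)) return(v)
  }
  NA_character_
}

subtree_tokens <- function(node) {
  toks <- character(0)
  rec <- function(n) {
    if (!is_element(n)) {
      toks <<- c(toks, strsplit(trimws(n$value), "\\s+")[[1]])
      return(invisible(NULL))
    }
    toks <<- c(toks, n$label, names(n$attrs), unname(n$attrs))
    for (k in n$children) rec(k)
  }
  rec(node)
  unique(toks)
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Match the element nodes of two canonical trees
#'
#' @param ia,ib Tree indices from `index_tree()` (internal), or raw tree
#'   roots, or `model_document`s.
#' @param sim_threshold Minimum Jaccard similarity of subtree tokens for the
#'   structural (pass 3) matching of elements without a shared identity.
#' @return List with the two indices (`a`, `b`) and the partial one-to-one
#'   mapping `map` / `rmap` (named integer vectors, uid -> uid).
#' @keywords internal
#' @export
match_trees <- function(ia, ib, sim_threshold = 0.7) {
  if (is_model_document(ia)) ia <- index_tree(ia$root)
  else if (inherits(ia, "xml_tree_node")) ia <- index_tree(ia)
  if (is_model_document(ib)) ib <- index_tree(ib$root)
  else if (inherits(ib, "xml_tree_node")) ib <- index_tree(ib)

  ta <- ia$tab; tb <- ib$tab
  ea <- ta[ta$kind == "element", , drop = FALSE]
  eb <- tb[tb$kind == "element", , drop = FALSE]
  na_max <- max(ta$uid); nb_max <- max(tb$uid)
  map <- rep(NA_integer_, na_max)   # uid_a -> uid_b
  rmap <- rep(NA_integer_, nb_max)  # uid_b -> uid_a
  parent_a <- integer(na_max); parent_a[ta$uid] <- ta$parent
  parent_b <- integer(nb_max); parent_b[tb$uid] <- tb$parent
  label_a <- character(na_max); label_a[ta$uid] <- ta$label
  label_b <- character(nb_max); label_b[tb$uid] <- tb$label

  add_pair <- function(ua, ub) {
    if (!is.na(map[ua]) || !is.na(rmap[ub])) return(FALSE)
    map[ua] <<- ub; rmap[ub] <<- ua
    TRUE
  }

  id_a <- vapply(ia$nodes[as.character(ea$uid)], node_idval, character(1))
  id_b <- vapply(ib$nodes[as.character(eb$uid)], node_idval, character(1))
  key_a <- ifelse(is.na(id_a), NA, paste0(ea$label, "\r", id_a))
  key_b <- ifelse(is.na(id_b), NA, paste0(eb$label, "\r", id_b))

  # roots first
  add_pair(ea$uid[1], eb$uid[1])

  # pass 1: globally unique identity keys
  ka <- table(key_a); kb <- table(key_b)
  shared <- intersect(names(ka)[ka == 1L], names(kb)[kb == 1L])
  for (k in shared) add_pair(ea$uid[which(key_a == k)], eb$uid[which(key_b == k)])

  ch_map_a <- split(ea$uid[ea$parent > 0L], ea$parent[ea$parent > 0L])
  ch_map_b <- split(eb$uid[eb$parent > 0L], eb$parent[eb$parent > 0L])
  children_of_a <- function(uid) ch_map_a[[as.character(uid)]]
  children_of_b <- function(uid) ch_map_b[[as.character(uid)]]
  idkey_of <- function(keys, euids, uid) keys[match(uid, euids)]

  propagate <- function() {
    grew <- TRUE
    any_new <- FALSE
    while (grew) {
      grew <- FALSE
      pairs_a <- which(!is.na(map))
      for (ua in pairs_a) {
        ub <- map[ua]
        # parents
        pa <- parent_a[ua]; pb <- parent_b[ub]
        if (pa > 0L && pb > 0L && is.na(map[pa]) && is.na(rmap[pb]) &&
            identical(label_a[pa], label_b[pb])) {
          if (add_pair(pa, pb)) { grew <- TRUE; any_new <- TRUE }
        }
        # children unique by label, then by (label, id)
        ca <- children_of_a(ua); ca <- ca[is.na(map[ca])]
        cb <- children_of_b(ub); cb <- cb[is.na(rmap[cb])]
        if (!length(ca) || !length(cb)) next
        la <- label_a[ca]; lb <- label_b[cb]
        for (lab in intersect(la, lb)) {
          sa <- ca[la == lab]; sb <- cb[lb == lab]
          if (length(sa) == 1L && length(sb) == 1L) {
            if (add_pair(sa, sb)) { grew <- TRUE; any_new <- TRUE }
          } else {
            ida <- idkey_of(key_a, ea$uid, sa); idb <- idkey_of(key_b, eb$uid, sb)
            common <- intersect(ida[!is.na(ida) & !duplicated(ida)],
                                idb[!is.na(idb) & !duplicated(idb)])
            common <- setdiff(common, c(ida[duplicated(ida)], idb[duplicated(idb)]))
            for (k in common) {
              if (add_pair(sa[which(ida == k)[1]], sb[which(idb == k)[1]])) {
                grew <- TRUE; any_new <- TRUE
              }
            }
          }
        }
      }
    }
    any_new
  }

  # rank among same-label siblings, straight from the canonical path
  rank_of <- function(tab, uid) {
    p <- tab$path[match(uid, tab$uid)]
    as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", p))
  }

  # pass 4 (run before similarity): residual same-label children of matched
  # parents whose sibling ranks coincide exactly are aligned by rank. This
  # pins elements whose content changed beyond recognition (e.g. a notes
  # paragraph whose text was replaced or removed) without risking a match
  # between a deleted and an unrelated inserted sibling, whose ranks differ.
  rank_pass <- function() {
    any_new <- FALSE
    for (ua in ea$uid[!is.na(map[ea$uid])]) {
      ub <- map[ua]
      ca <- children_of_a(ua); ca <- ca[is.na(map[ca])]
      cb <- children_of_b(ub); cb <- cb[is.na(rmap[cb])]
      if (!length(ca) || !length(cb)) next
      for (lab in intersect(label_a[ca], label_b[cb])) {
        sa <- ca[label_a[ca] == lab]; sb <- cb[label_b[cb] == lab]
        if (length(sa) != length(sb)) next
        rka <- rank_of(ta, sa); rkb <- rank_of(tb, sb)
        if (!identical(sort(rka), sort(rkb))) next
        sa <- sa[order(rka)]; sb <- sb[order(rkb)]
        for (i in seq_along(sa))
          if (add_pair(sa[i], sb[i])) any_new <- TRUE
      }
    }
    any_new
  }

  tok_cache_a <- new.env(parent = emptyenv())
  tok_cache_b <- new.env(parent = emptyenv())
  toks <- function(idx, uid, cache) {
    key <- as.character(uid)
    if (is.null(cache[[key]])) cache[[key]] <- subtree_tokens(idx$nodes[[key]])
    cache[[key]]
  }

  depth_a <- integer(na_max)
  depth_a[ta$uid] <- lengths(regmatches(ta$path, gregexpr("/", ta$path, fixed = TRUE)))

  # Containers before contents: only the shallowest residual depth is matched
  # per round, then propagation pins unique children under the new pairs.
  # Otherwise content-identical leaves (two equal map_components, two equal
  # math terms) can cross-match between unrelated parents and manufacture
  # spurious moves out of deleted subtrees.
  similarity_pass <- function() {
    ra <- ea$uid[is.na(map[ea$uid])]
    rb <- eb$uid[is.na(rmap[eb$uid])]
    if (!length(ra) || !length(rb)) return(FALSE)
    any_new <- FALSE
    cand <- list()
    parents_paired <- function(ua, ub) {
      pa <- parent_a[ua]; pb <- parent_b[ub]
      pa > 0L && pb > 0L && !is.na(map[pa]) && map[pa] == pb
    }
    for (lab in intersect(label_a[ra], label_b[rb])) {
      sa <- ra[label_a[ra] == lab]; sb <- rb[label_b[rb] == lab]
      for (ua in sa) for (ub in sb) {
        # conflicting identity attributes mark different entities: allow a
        # similarity match only in place (a rename under the same parent),
        # never across parents — otherwise a deletion and an unrelated
        # insertion with coincidentally similar content read as a move
        ida <- id_a[match(ua, ea$uid)]; idb <- id_b[match(ub, eb$uid)]
        if (!is.na(ida) && !is.na(idb) && ida != idb &&
            !parents_paired(ua, ub)) next
        s <- jaccard(toks(ia, ua, tok_cache_a), toks(ib, ub, tok_cache_b))
        if (s >= sim_threshold)
          cand[[length(cand) + 1L]] <- c(ua, ub, s)
      }
    }
    if (!length(cand)) return(FALSE)
    cm <- do.call(rbind, cand)
    dmin <- min(depth_a[cm[, 1]])
    cm <- cm[depth_a[cm[, 1]] == dmin, , drop = FALSE]
    # among ties, prefer pairs whose parents are already matched to each other
    pagree <- vapply(seq_len(nrow(cm)), function(i) {
      pa <- parent_a[cm[i, 1]]; pb <- parent_b[cm[i, 2]]
      as.integer(!(pa > 0L && pb > 0L && !is.na(map[pa]) && map[pa] == pb))
    }, integer(1))
    ord <- order(-cm[, 3], pagree, cm[, 1], cm[, 2], method = "radix")
    for (i in ord) {
      if (add_pair(cm[i, 1], cm[i, 2])) any_new <- TRUE
    }
    any_new
  }

  propagate()
  repeat {
    grew4 <- rank_pass()
    if (grew4) propagate()
    grew3 <- similarity_pass()
    if (grew3) propagate()
    if (!grew3 && !grew4) break
  }

  list(a = ia, b = ib, map = map, rmap = rmap)
}
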