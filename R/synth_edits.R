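# Planting edits into a document and recording the ground-truth ledger.
#
# Planted edits never overlap: each edit claims the A-subtree it touches and
# conflicting claims are resampled. Within-container moves are planted with
# displacement >= 2 and an exclusive lock on their (container, label) group —
# a displacement-1 move is a swap, for which "which element moved" is
# genuinely ambiguous, so exact recovery would be ill-posed.

sbml_cfg <- list(
  insert_parents = c(species = "listOfSpecies", parameter = "listOfParameters",
                     compartment = "listOfCompartments"),
  deletable = c("species", "parameter", "reaction", "unitDefinition"),
  numeric_attrs = list(species = "initialConcentration", parameter = "value",
                       compartment = "size"),
  optional_attrs = list(species = "sboTerm", parameter = "name",
                        compartment = "name", reaction = "name"),
  removable_attrs = list(species = "name", parameter = "name"),
  id_attr = "id",
  move_containers = c("listOfSpecies", "listOfParameters", "listOfReactions"),
  text_parent = "p")

cellml_cfg <- list(
  insert_parents = c(variable = "component", units = "model"),
  deletable = c("variable", "connection", "units"),
  numeric_attrs = list(variable = "initial_value"),
  optional_attrs = list(variable = "public_interface", component = "cmeta_id"),
  removable_attrs = list(variable = "initial_value"),
  id_attr = "name",
  move_containers = c("component"),
  text_parent = "documentation")

fresh_id_val <- function() paste0("x", paste(sample(c(letters, 0:9), 8,
                                                    replace = TRUE), collapse = ""))

build_insert_node <- function(format, child_label, id_stable, counter_env) {
  nxt <- function() { counter_env$n <- counter_env$n + 1L; counter_env$n }
  withuid <- function(node) { node$uid <- nxt(); node }
  if (format == "SBML") {
    attrs <- switch(child_label,
      species = c(compartment = "c1", initialConcentration = rnum()),
      parameter = c(value = rnum()),
      compartment = c(size = rnum()))
    if (id_stable) attrs <- c(attrs, setNames(fresh_id_val(), "id"))
    withuid(xml_element(child_label, SBML_NS, attrs))
  } else {
    if (child_label == "variable") {
      attrs <- c(units = "u1", initial_value = rnum())
      if (id_stable) attrs <- c(attrs, setNames(fresh_id_val(), "name"))
      withuid(xml_element("variable", CELLML_NS, attrs))
    } else {
      attrs <- c(if (id_stable) setNames(fresh_id_val(), "name"))
      node <- xml_element("units", CELLML_NS, attrs,
                          list(xml_element("unit", CELLML_NS,
                                           c(units = "second"))))
      node <- withuid(node)
      node$children[[1]] <- withuid(node$children[[1]])
      node
    }
  }
}

# Plant up to the requested number of edits into doc; returns the new tree,
# the ledger ops, and the per-entity count delta.
plant_edits <- function(doc, spec) {
  fmt <- doc$format
  cfg <- if (fmt == "SBML") sbml_cfg else cellml_cfg
  A <- tag_uids(doc$root)
  ia <- index_tree(A, retag = FALSE)
  ta <- ia$tab
  paths_a <- uid_paths(A)
  counter_env <- new.env(parent = emptyenv())
  counter_env$n <- max(ta$uid)
  B <- A
  claimed <- integer(0)
  move_groups <- character(0)   # groups locked by a move (fully exclusive)
  ins_groups <- character(0)    # groups that received an insert
  del_groups <- character(0)    # groups that received a delete
  records <- list()

  elements <- ta[ta$kind == "element", , drop = FALSE]
  texts <- ta[ta$kind == "text", , drop = FALSE]
  label_of <- setNames(ta$label, ta$uid)
  parent_of <- setNames(ta$parent, ta$uid)
  # zero-length-safe: paste0(integer(0), "|", x) recycles to length 1,
  # and empty_vec[TRUE] is NA — so guard explicitly
  grp_key <- function(parent_uid, label) {
    if (!length(parent_uid)) return(character(0))
    paste0(parent_uid, "|", label)
  }
  free_elems <- function(labels) {
    u <- elements$uid[elements$label %in% labels]
    u[!(u %in% claimed)]
  }
  node_a <- function(uid) ia$nodes[[as.character(uid)]]

  pick <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[[sample.int(length(x), 1L)]] else NULL
  }

  n_edits <- spec$n_edits
  if (!is.null(names(n_edits))) {
    plan <- rep(names(n_edits), times = n_edits)
    plan <- sample(plan)
  } else {
    plan <- sample(OP_TYPES, n_edits, replace = TRUE, prob = spec$op_mix)
  }

  choose_entity <- function(op_type) {
    mix <- spec$entity_mix
    allowed <- switch(op_type, move = "element",
                      update = c("attribute", "text"), ENTITY_KINDS)
    mix <- mix[allowed]
    if (!is.null(spec$target_bias) && op_type %in% c("insert", "update") &&
        stats::runif(1) < spec$target_bias) return("text")
    sample(names(mix), 1L, prob = mix / sum(mix))
  }

  try_plant <- function(op_type) {
    kind <- choose_entity(op_type)
    key <- paste(op_type, kind)
    switch(key,
      "insert element" = {
        child_label <- pick(names(cfg$insert_parents))
        parent_label <- cfg$insert_parents[[child_label]]
        parents <- free_elems(parent_label)
        parents <- parents[!(grp_key(parents, child_label) %in%
                               c(move_groups, del_groups))]
        pu <- pick(parents)
        if (is.null(pu)) return(FALSE)
        node <- build_insert_node(fmt, child_label, spec$id_stability, counter_env)
        pb <- get_node_by_uid(B, pu)
        at <- sample.int(length(pb$children) + 1L, 1L)
        B <<- mutate_uid(B, pu, function(p) {
          p$children <- append(p$children, list(node), after = at - 1L); p
        })$root
        ins_groups <<- c(ins_groups, grp_key(pu, child_label))
        records[[length(records) + 1L]] <<- list(kind = "insert_element",
                                                 uid = node$uid, parent = pu)
        TRUE
      },
      "insert attribute" = {
        cand <- integer(0)
        for (lab in names(cfg$optional_attrs)) {
          us <- free_elems(lab)
          us <- us[vapply(us, function(u)
            is.null(aget(node_a(u)$attrs, cfg$optional_attrs[[lab]])), logical(1))]
          cand <- c(cand, us)
        }
        u <- pick(cand)
        if (is.null(u)) return(FALSE)
        an <- cfg$optional_attrs[[label_of[[as.character(u)]]]]
        val <- rword(1)
        B <<- mutate_uid(B, u, function(n) {
          a <- c(n$attrs, setNames(val, an))
          n$attrs <- a[order(names(a), method = "radix")]; n
        })$root
        claimed <<- c(claimed, u)
        records[[length(records) + 1L]] <<- list(kind = "insert_attr", uid = u,
                                                 name = an, value = val)
        TRUE
      },
      "insert text" = {
        # only into empty text-capable elements: adjacent text siblings would
        # merge on reparse and break canonical round trips
        cand <- elements$uid[elements$label == cfg$text_parent]
        cand <- cand[!(cand %in% claimed)]
        cand <- cand[vapply(cand, function(u)
          length(node_a(u)$children) == 0L, logical(1))]
        u <- pick(cand)
        if (is.null(u)) return(FALSE)
        val <- rsentence(5)
        tn <- xml_textnode(val)
        counter_env$n <- counter_env$n + 1L
        tn$uid <- counter_env$n
        B <<- mutate_uid(B, u, function(n) {
          n$children <- list(tn); n
        })$root
        claimed <<- c(claimed, u)
        records[[length(records) + 1L]] <<- list(kind = "insert_text",
                                                 uid = tn$uid, parent = u,
                                                 value = val)
        TRUE
      },
      "delete element" = {
        cand <- free_elems(cfg$deletable)
        cand <- cand[!(grp_key(parent_of[as.character(cand)],
                               label_of[as.character(cand)]) %in%
                         c(move_groups, ins_groups))]
        u <- pick(cand)
        if (is.null(u)) return(FALSE)
        sub <- subtree_uids(node_a(u))
        if (any(sub %in% claimed)) return(FALSE)
        B <<- mutate_uid(B, u, function(n) NULL)$root
        claimed <<- c(claimed, sub)
        del_groups <<- c(del_groups,
                         grp_key(parent_of[[as.character(u)]],
                                 label_of[[as.character(u)]]))
        records[[length(records) + 1L]] <<- list(kind = "delete_element", uid = u)
        TRUE
      },
      "delete attribute" = {
        cand <- integer(0)
        for (lab in names(cfg$removable_attrs)) {
          us <- free_elems(lab)
          us <- us[vapply(us, function(u)
            !is.null(aget(node_a(u)$attrs, cfg$removable_attrs[[lab]])), logical(1))]
          cand <- c(cand, us)
        }
        u <- pick(cand)
        if (is.null(u)) return(FALSE)
        an <- cfg$removable_attrs[[label_of[[as.character(u)]]]]
        old <- node_a(u)$attrs[[an]]
        B <<- mutate_uid(B, u, function(n) {
          n$attrs <- n$attrs[setdiff(names(n$attrs), an)]; n
        })$root
        claimed <<- c(claimed, u)
        records[[length(records) + 1L]] <<- list(kind = "delete_attr", uid = u,
                                                 name = an, value = old)
        TRUE
      },
      "delete text" = {
        cand <- texts[!(texts$parent %in% claimed) & !(texts$uid %in% claimed), ,
                      drop = FALSE]
        cand <- cand[label_of[as.character(cand$parent)] == cfg$text_parent, ,
                     drop = FALSE]
        if (!nrow(cand)) return(FALSE)
        i <- sample.int(nrow(cand), 1L)
        u <- cand$uid[i]
        B <<- mutate_uid(B, u, function(n) NULL)$root
        claimed <<- c(claimed, u, cand$parent[i])
        records[[length(records) + 1L]] <<- list(kind = "delete_text", uid = u,
                                                 value = cand$value[i])
        TRUE
      },
      "update attribute" = {
        rename_id <- !spec$id_stability && stats::runif(1) < 0.6
        if (rename_id) {
          labs <- names(cfg$numeric_attrs)
          cand <- free_elems(labs)
          cand <- cand[vapply(cand, function(u)
            !is.null(aget(node_a(u)$attrs, cfg$id_attr)), logical(1))]
          u <- pick(cand)
          if (is.null(u)) return(FALSE)
          an <- cfg$id_attr
          new <- fresh_id_val()
        } else {
          cand <- integer(0)
          for (lab in names(cfg$numeric_attrs)) {
            us <- free_elems(lab)
            us <- us[vapply(us, function(u)
              !is.null(aget(node_a(u)$attrs, cfg$numeric_attrs[[lab]])), logical(1))]
            cand <- c(cand, us)
          }
          u <- pick(cand)
          if (is.null(u)) return(FALSE)
          an <- cfg$numeric_attrs[[label_of[[as.character(u)]]]]
          repeat { new <- rnum(); if (!identical(new, node_a(u)$attrs[[an]])) break }
        }
        old <- node_a(u)$attrs[[an]]
        B <<- mutate_uid(B, u, function(n) { n$attrs[[an]] <- new; n })$root
        claimed <<- c(claimed, u)
        records[[length(records) + 1L]] <<- list(kind = "update_attr", uid = u,
                                                 name = an, old = old, new = new)
        TRUE
      },
      "update text" = {
        cand <- texts[!(texts$parent %in% claimed) & !(texts$uid %in% claimed), ,
                      drop = FALSE]
        if (!nrow(cand)) return(FALSE)
        i <- sample.int(nrow(cand), 1L)
        u <- cand$uid[i]
        repeat { new <- rsentence(6); if (!identical(new, cand$value[i])) break }
        B <<- mutate_uid(B, u, function(n) { n$value <- new; n })$root
        claimed <<- c(claimed, u, cand$parent[i])
        records[[length(records) + 1L]] <<- list(kind = "update_text", uid = u,
                                                 old = cand$value[i], new = new)
        TRUE
      },
      "move element" = {
        plant_move(fmt)
      },
      FALSE)
  }

  plant_move <- function(fmt) {
    cross <- fmt == "CellML" && stats::runif(1) < 0.7
    if (cross) {
      comps <- free_elems("component")
      if (length(comps) < 2L) return(FALSE)
      vars <- elements$uid[elements$label == "variable"]
      vars <- vars[!(vars %in% claimed) & parent_of[as.character(vars)] %in% comps]
      vars <- vars[!(grp_key(parent_of[as.character(vars)], "variable") %in%
                       c(move_groups, ins_groups, del_groups))]
      u <- pick(vars)
      if (is.null(u)) return(FALSE)
      src <- parent_of[[as.character(u)]]
      dst <- pick(setdiff(comps, src))
      dkey <- grp_key(dst, "variable")
      skey <- grp_key(src, "variable")
      if (any(c(dkey, skey) %in% c(move_groups, ins_groups, del_groups)))
        return(FALSE)
      node <- NULL
      res <- mutate_uid(B, u, function(n) { node <<- n; NULL })
      B <<- res$root
      db <- get_node_by_uid(B, dst)
      at <- sample.int(length(db$children) + 1L, 1L)
      B <<- mutate_uid(B, dst, function(p) {
        p$children <- append(p$children, list(node), after = at - 1L); p
      })$root
      claimed <<- c(claimed, subtree_uids(node))
      move_groups <<- c(move_groups, dkey, skey)
      records[[length(records) + 1L]] <<- list(kind = "move", uid = u)
      return(TRUE)
    }
    conts <- free_elems(cfg$move_containers)
    conts <- conts[sample.int(length(conts))]
    for (cu in conts) {
      pb <- get_node_by_uid(B, cu)
      kids <- pb$children
      n <- length(kids)
      if (n < 3L) next
      kid_uids <- vapply(kids, `[[`, integer(1), "uid")
      lab <- kids[[1]]$label
      key <- grp_key(cu, lab)
      if (key %in% c(move_groups, ins_groups, del_groups)) next
      if (any(kid_uids %in% claimed)) next
      i <- sample.int(n, 1L)
      far <- which(abs(seq_len(n) - i) >= 2L)
      if (!length(far)) next
      j <- far[[sample.int(length(far), 1L)]]
      node <- kids[[i]]
      kids[[i]] <- NULL
      kids <- append(kids, list(node), after = j - 1L)
      B <<- mutate_uid(B, cu, function(p) { p$children <- kids; p })$root
      claimed <<- c(claimed, subtree_uids(node))
      move_groups <<- c(move_groups, key)
      records[[length(records) + 1L]] <<- list(kind = "move", uid = node$uid)
      return(TRUE)
    }
    FALSE
  }

  for (want in plan) {
    ok <- FALSE
    tries <- 0L
    op <- want
    while (!ok && tries < 40L) {
      ok <- isTRUE(try_plant(op))
      tries <- tries + 1L
      if (!ok) op <- sample(OP_TYPES, 1L, prob = spec$op_mix)
    }
  }

  paths_b <- uid_paths(B)
  ops <- ledger_ops(records, ia, paths_a, paths_b, B)
  list(root = B, ops = ops)
}

ledger_ops <- function(records, ia, paths_a, paths_b, B) {
  ops <- list()
  push <- function(op) ops[[length(ops) + 1L]] <<- op
  pa <- function(uid) paths_a[[as.character(uid)]]
  pb <- function(uid) paths_b[[as.character(uid)]]
  for (r in records) {
    switch(r$kind,
      insert_element = {
        node <- get_node_by_uid(B, r$uid)
        base <- pb(r$uid)
        recs <- subtree_records(node, base)
        parent <- get_node_by_uid(B, r$parent)
        idx <- which(vapply(parent$children, `[[`, integer(1), "uid") == r$uid)
        push(new_op("insert", "element", new_path = base, label = node$label,
                    ns = node$ns, new_index = idx, payload = node))
        for (rec in recs[-1]) {
          if (rec$kind == "element")
            push(new_op("insert", "element", new_path = rec$path,
                        label = rec$label, ns = rec$ns, triggered = TRUE))
          else if (rec$kind == "attribute")
            push(new_op("insert", "attribute", new_path = rec$path,
                        new_value = rec$value, triggered = TRUE))
          else
            push(new_op("insert", "text", new_path = rec$path,
                        new_value = rec$value, triggered = TRUE))
        }
      },
      delete_element = {
        node <- ia$nodes[[as.character(r$uid)]]
        base <- pa(r$uid)
        recs <- subtree_records(node, base)
        push(new_op("delete", "element", old_path = base, label = node$label,
                    ns = node$ns))
        for (rec in recs[-1]) {
          if (rec$kind == "element")
            push(new_op("delete", "element", old_path = rec$path,
                        label = rec$label, ns = rec$ns, triggered = TRUE))
          else if (rec$kind == "attribute")
            push(new_op("delete", "attribute", old_path = rec$path,
                        old_value = rec$value, triggered = TRUE))
          else
            push(new_op("delete", "text", old_path = rec$path,
                        old_value = rec$value, triggered = TRUE))
        }
      },
      insert_attr = push(new_op("insert", "attribute",
                                new_path = paste0(pb(r$uid), "/@", r$name),
                                new_value = r$value)),
      delete_attr = push(new_op("delete", "attribute",
                                old_path = paste0(pa(r$uid), "/@", r$name),
                                old_value = r$value)),
      insert_text = {
        parent <- get_node_by_uid(B, r$parent)
        idx <- which(vapply(parent$children, `[[`, integer(1), "uid") == r$uid)
        push(new_op("insert", "text", new_path = pb(r$uid),
                    new_value = r$value, new_index = idx))
      },
      delete_text = push(new_op("delete", "text", old_path = pa(r$uid),
                                old_value = r$value)),
      update_attr = push(new_op("update", "attribute",
                                old_path = paste0(pa(r$uid), "/@", r$name),
                                new_path = paste0(pb(r$uid), "/@", r$name),
                                old_value = r$old, new_value = r$new)),
      update_text = push(new_op("update", "text", old_path = pa(r$uid),
                                new_path = pb(r$uid),
                                old_value = r$old, new_value = r$new)),
      move = {
        node <- get_node_by_uid(B, r$uid)
        bpath <- pb(r$uid)
        ppath <- sub("/[^/]+$", "", bpath)
        loc <- resolve_path(B, ppath)
        parent <- tree_get(B, loc$idx)
        idx <- which(vapply(parent$children, `[[`, integer(1), "uid") == r$uid)
        push(new_op("move", "element", old_path = pa(r$uid), new_path = bpath,
                    label = node$label, ns = node$ns, new_index = idx))
      })
  }
  sort_ops(ops)
}
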