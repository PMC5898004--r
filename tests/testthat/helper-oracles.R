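# Independent test oracles. Nothing in here calls the code paths it checks.

# --- quadratic LCS line-diff oracle --------------------------------------

oracle_line_counts <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(sub("\n$", "", a), "\n", fixed = TRUE)[[1]]
  if (length(b) == 1L) b <- strsplit(sub("\n$", "", b), "\n", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m))
    L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L
                         else max(L[i, j + 1L], L[i + 1L, j])
  lcs <- L[n + 1L, m + 1L]
  c(line_inserts = m - lcs, line_deletes = n - lcs)
}

# --- independent element-node counter via xml2 XPath ---------------------

oracle_element_count <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  length(xml2::xml_find_all(doc, "//*"))
}

oracle_label_count <- function(xml_text, local_names) {
  doc <- xml2::read_xml(xml_text)
  xp <- paste(sprintf("//*[local-name()='%s']", local_names), collapse = " | ")
  length(xml2::xml_find_all(doc, xp))
}

# --- Zhang–Shasha tree edit distance (unit costs) ------------------------
# Operates on simple list trees: list(label = chr, children = list(...)).
# Used only on small trees (<= ~60 nodes including attribute/text leaves).

zs_flatten <- function(tree) {
  labels <- character(0); lml <- integer(0)
  rec <- function(node) {
    ids <- integer(0)
    for (k in node$children) ids <- c(ids, rec(k))
    labels[[length(labels) + 1L]] <<- node$label
    me <- length(labels)
    lml[[me]] <<- if (length(ids)) lml[[ids[1]]] else me
    c(ids, me)
  }
  rec(tree)
  list(labels = labels, lml = lml, n = length(labels))
}

zs_keyroots <- function(lml) {
  n <- length(lml)
  seen <- logical(n)
  kr <- integer(0)
  for (i in rev(seq_len(n))) {
    if (!seen[lml[i]]) { kr <- c(i, kr); seen[lml[i]] <- TRUE }
  }
  sort(kr)
}

oracle_zhang_shasha <- function(t1, t2) {
  f1 <- zs_flatten(t1); f2 <- zs_flatten(t2)
  n <- f1$n; m <- f2$n
  td <- matrix(0L, n, m)
  for (i in zs_keyroots(f1$lml)) {
    for (j in zs_keyroots(f2$lml)) {
      li <- f1$lml[i]; lj <- f2$lml[j]
      fd <- matrix(0L, i - li + 2L, j - lj + 2L)
      for (x in seq_len(i - li + 1L)) fd[x + 1L, 1L] <- fd[x, 1L] + 1L
      for (y in seq_len(j - lj + 1L)) fd[1L, y + 1L] <- fd[1L, y] + 1L
      for (x in seq_len(i - li + 1L)) {
        for (y in seq_len(j - lj + 1L)) {
          i1 <- li + x - 1L; j1 <- lj + y - 1L
          if (f1$lml[i1] == li && f2$lml[j1] == lj) {
            cost <- if (f1$labels[i1] == f2$labels[j1]) 0L else 1L
            fd[x + 1L, y + 1L] <- min(fd[x, y + 1L] + 1L, fd[x + 1L, y] + 1L,
                                      fd[x, y] + cost)
            td[i1, j1] <- fd[x + 1L, y + 1L]
          } else {
            fd[x + 1L, y + 1L] <- min(fd[x, y + 1L] + 1L, fd[x + 1L, y] + 1L,
                                      fd[f1$lml[i1] - li + 1L,
                                         f2$lml[j1] - lj + 1L] + td[i1, j1])
          }
        }
      }
    }
  }
  td[n, m]
}

# convert a model document tree into the ZS representation: element nodes
# keep their label; attributes become "@name=value" leaves (sorted, first),
# text children become "#value" leaves in place
zs_from_doc <- function(doc) {
  conv <- function(node) {
    if (!identical(node$kind, "element"))
      return(list(label = paste0("#", node$value), children = list()))
    kids <- list()
    for (a in names(node$attrs))
      kids[[length(kids) + 1L]] <- list(label = paste0("@", a, "=", node$attrs[[a]]),
                                        children = list())
    for (k in node$children) kids[[length(kids) + 1L]] <- conv(k)
    list(label = node$label, children = kids)
  }
  conv(doc$root)
}

# --- random generic trees + mutations for the oracle-equivalence check ----

rnd_tree_doc <- function(n_species, seed) {
  generate_seed_model("SBML",
                      size = list(species = n_species, reactions = 1L,
                                  compartments = 1L, parameters = 1L),
                      rng_seed = seed, model_id = "ORC")
}
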