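# Version histories: the unit the statistics tables aggregate over.

new_model_history <- function(model_id, repository, versions) {
  stopifnot(length(versions) >= 1L)
  structure(list(model_id = model_id, repository = repository,
                 versions = versions),
            class = "model_history")
}

#' @export
print.model_history <- function(x, ...) {
  cat(sprintf("<model_history> %s (%s): %d versions\n", x$model_id,
              x$repository, length(x$versions)))
  invisible(x)
}

version_record <- function(doc, curation_status = "unknown", file = NA_character_) {
  list(version_id = doc$version_id, timestamp = doc$timestamp,
       curation_status = curation_status, file = file, doc = doc)
}

#' Grow a synthetic version history from a seed document
#'
#' Each version is derived from the previous one by applying exactly the
#' planted edits; the returned ledger records them as fully-specified diff
#' operations (paths in before/after coordinates, triggered descendants of
#' subtree operations expanded), plus the expected per-entity count deltas.
#' Timestamps increase strictly on a synthetic release calendar (uniform
#' 30–365 day gaps, echoing repository release cadence).
#'
#' @param seed_doc A `model_document`, typically from [generate_seed_model()].
#' @param n_versions Total number of versions including the seed (>= 1).
#' @param spec An [edit_spec()].
#' @return List with `history` (a `model_history` whose version records hold
#'   the documents in memory) and `ledger` (one entry per transition:
#'   `version_from`, `version_to`, `ops`, `entity_delta`).
#' @export
generate_history <- function(seed_doc, n_versions, spec = edit_spec()) {
  stopifnot(is_model_document(seed_doc), n_versions >= 1L)
  local_seed(spec$rng_seed, {
    versions <- list(version_record(seed_doc))
    ledger <- list()
    cur <- seed_doc
    ts <- cur$timestamp
    for (i in seq_len(n_versions - 1L)) {
      planted <- plant_edits(cur, spec)
      ts <- ts + round(stats::runif(1, 30, 365)) * 86400
      nxt <- new_model_document(cur$format, cur$model_id,
                                as.character(i + 1L), ts,
                                tag_uids(planted$root),
                                source_uri = paste0("synthetic://",
                                                    cur$model_id, "/", i + 1L))
      before <- count_entities(cur)
      after <- count_entities(nxt)
      ledger[[i]] <- list(version_from = cur$version_id,
                          version_to = nxt$version_id,
                          ops = planted$ops,
                          entity_delta = unlist(after[ENTITY_COLS]) -
                            unlist(before[ENTITY_COLS]))
      versions[[i + 1L]] <- version_record(nxt)
      cur <- nxt
    }
    hist <- new_model_history(seed_doc$model_id,
                              if (seed_doc$format == "SBML") "biomodels-like"
                              else "pmr-like",
                              versions)
    list(history = hist, ledger = ledger)
  })
}

#' Generate a whole synthetic corpus
#'
#' @param n_models Number of models.
#' @param rng_seed Master seed; per-model seeds are drawn from it.
#' @param format "SBML", "CellML", or "mixed" (half and half, echoing a
#'   two-repository corpus).
#' @param n_versions Versions per model, recycled over models.
#' @param spec Template [edit_spec()]; its seed is replaced per model.
#' @param size Passed to [generate_seed_model()].
#' @return List of `generate_history()` results, one per model.
#' @export
generate_corpus <- function(n_models, rng_seed = 1L, format = "mixed",
                            n_versions = 5L, spec = edit_spec(),
                            size = list()) {
  local_seed(rng_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_models + 1L)
    fmts <- if (format == "mixed")
      rep(c("SBML", "CellML"), length.out = n_models)
    else rep(format, n_models)
    nv <- rep(n_versions, length.out = n_models)
    starts <- as.POSIXct("2005-04-11", tz = "UTC") +
      sort(sample.int(3650L, n_models, replace = TRUE)) * 86400
    out <- vector("list", n_models)
    for (i in seq_len(n_models)) {
      mid <- sprintf("%s%04d", if (fmts[i] == "SBML") "SYN" else "PSYN", i)
      sd <- generate_seed_model(fmts[i], size = size, rng_seed = seeds[i],
                                model_id = mid, timestamp = starts[i])
      sp <- spec
      sp$rng_seed <- seeds[i] %% 2147483646L + 1L
      out[[i]] <- generate_history(sd, nv[i], sp)
    }
    out
  })
}
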