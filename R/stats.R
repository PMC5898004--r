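# The three aggregate tables: filestats, diffstats, repo-evolution.

as_histories <- function(histories) {
  if (inherits(histories, "model_history")) return(list(histories))
  lapply(histories, function(h) {
    if (inherits(h, "model_history")) h
    else if (is.list(h) && inherits(h$history, "model_history")) h$history
    else stop("not a model_history: ", class(h)[1])
  })
}

version_doc <- function(vr, model_id) {
  if (!is.null(vr$doc)) return(vr$doc)
  parse_model(vr$file, model_id = model_id, version_id = vr$version_id,
              timestamp = vr$timestamp, source_uri = vr$file)
}

empty_filestats <- function() {
  cbind(data.frame(model_id = character(), version_id = character(),
                   format = character(), curation_status = character(),
                   file_url = character(), stringsAsFactors = FALSE),
        as.data.frame(setNames(rep(list(integer()), length(ENTITY_COLS)),
                               ENTITY_COLS)),
        data.frame(repository = character(), timestamp = as.POSIXct(character())))
}

#' Build the per-version filestats table
#'
#' One row per (model, version) with the entity-count feature vector.
#' Versions whose files cannot be parsed are skipped with a warning and
#' listed in the `exclusions` attribute of the result.
#'
#' @param histories A list of `model_history` objects (or of
#'   [generate_history()] results).
#' @return `data.frame`; see [count_entities()] for the count columns, plus
#'   `repository` and `timestamp`.
#' @export
build_filestats <- function(histories) {
  histories <- as_histories(histories)
  rows <- list()
  excl <- list()
  for (h in histories) {
    for (vr in h$versions) {
      row <- tryCatch({
        doc <- version_doc(vr, h$model_id)
        cbind(count_entities(doc, vr$curation_status),
              data.frame(repository = h$repository, timestamp = vr$timestamp))
      }, error = function(e) {
        warning("skipping ", h$model_id, " version ", vr$version_id, ": ",
                conditionMessage(e), call. = FALSE)
        excl[[length(excl) + 1L]] <<- data.frame(
          model_id = h$model_id, version_id = vr$version_id,
          reason = conditionMessage(e), stringsAsFactors = FALSE)
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_filestats()
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl)
    else data.frame(model_id = character(), version_id = character(),
                    reason = character())
  out
}

empty_diffstats <- function() {
  data.frame(model_id = character(), version_from = character(),
             version_to = character(), line_inserts = integer(),
             line_deletes = integer(), op_inserts = integer(),
             op_deletes = integer(), op_updates = integer(),
             op_moves = integer(), triggered_count = integer(),
             stringsAsFactors = FALSE)
}

delta_row <- function(d) {
  s <- d$summary$by_type_kind
  data.frame(model_id = d$model_id, version_from = d$version_from,
             version_to = d$version_to,
             line_inserts = d$line_inserts, line_deletes = d$line_deletes,
             op_inserts = sum(s["insert", ]), op_deletes = sum(s["delete", ]),
             op_updates = sum(s["update", ]), op_moves = sum(s["move", ]),
             triggered_count = d$summary$triggered, stringsAsFactors = FALSE)
}

#' Build the per-transition diffstats table
#'
#' One row per consecutive version pair of each model (n versions give
#' n - 1 rows). Identical consecutive versions produce an all-zero row, not
#' a dropped one: a release that re-publishes an unchanged document is still
#' a version transition. Triggered operations are included in the op counts.
#'
#' @inheritParams build_filestats
#' @param deltas_out Environment; when supplied, every computed `delta` is
#'   stored in it keyed by `modelid|from|to` (for downstream classification
#'   without recomputation).
#' @return `data.frame` with columns `model_id`, `version_from`,
#'   `version_to`, `line_inserts`, `line_deletes`, `op_inserts`,
#'   `op_deletes`, `op_updates`, `op_moves`, `triggered_count`.
#' @export
build_diffstats <- function(histories, deltas_out = NULL) {
  histories <- as_histories(histories)
  rows <- list()
  for (h in histories) {
    n <- length(h$versions)
    if (n < 2L) next
    prev <- NULL
    for (i in seq_len(n)) {
      doc <- tryCatch(version_doc(h$versions[[i]], h$model_id),
                      error = function(e) {
                        warning("skipping ", h$model_id, " version ",
                                h$versions[[i]]$version_id, ": ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (is.null(doc)) next
      if (!is.null(prev)) {
        d <- diff_models(prev, doc)
        if (!is.null(deltas_out))
          deltas_out[[paste(d$model_id, d$version_from, d$version_to,
                            sep = "|")]] <- d
        rows[[length(rows) + 1L]] <- delta_row(d)
      }
      prev <- doc
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_diffstats()
}

#' Build the repository-evolution time series
#'
#' For each grid date, each model contributes its latest version at or
#' before that date; entity counts are accumulated into one feature vector
#' per repository plus a combined vector (always the elementwise sum).
#'
#' @inheritParams build_filestats
#' @param date_grid Sorted `POSIXct`/`Date` vector; defaults to a monthly
#'   grid spanning the corpus.
#' @return `data.frame` with one row per (date, repository) including the
#'   pseudo-repository `"combined"`: `date`, `repository`, `models`, and the
#'   summed entity-count columns.
#' @export
build_repo_evolution <- function(histories, date_grid = NULL) {
  fs <- build_filestats(histories)
  if (is.null(date_grid)) {
    if (!nrow(fs)) return(data.frame(date = as.POSIXct(character()),
                                     repository = character(),
                                     models = integer()))
    date_grid <- seq(min(fs$timestamp), max(fs$timestamp) + 86400 * 31,
                     by = "1 month")
  }
  date_grid <- sort(as.POSIXct(date_grid, tz = "UTC"))
  repos <- sort(unique(fs$repository))
  rows <- list()
  for (d in seq_along(date_grid)) {
    at <- date_grid[[d]]
    vis <- fs[fs$timestamp <= at, , drop = FALSE]
    latest <- vis[order(vis$model_id, vis$timestamp, vis$version_id), ]
    latest <- latest[!duplicated(latest$model_id, fromLast = TRUE), , drop = FALSE]
    per_repo <- lapply(c(repos, "combined"), function(r) {
      sub <- if (r == "combined") latest else latest[latest$repository == r, ]
      cbind(data.frame(date = at, repository = r, models = nrow(sub)),
            as.data.frame(as.list(colSums(sub[, ENTITY_COLS, drop = FALSE]))))
    })
    rows[[length(rows) + 1L]] <- do.call(rbind, per_repo)
  }
  do.call(rbind, rows)
}

#' Summary statistics over the tables
#'
#' Derived summaries: mean number of versions per model within the first
#' `window_years` after its first release (closed interval), mean
#' operations per version transition, mean element nodes per model by
#' format (latest version of each model), and the release-by-model change
#' matrix behind the update-heatmap view.
#'
#' @param diffstats From [build_diffstats()].
#' @param filestats From [build_filestats()].
#' @param window_years Window for the versions-per-model mean.
#' @param include_zero_transitions Count all-zero transitions in the
#'   ops-per-transition mean (repositories create a version per release even
#'   when nothing changed; default `TRUE`).
#' @param include_triggered Include triggered operations in op totals
#'   (default `TRUE`; totals appear triggered-inclusive in the field).
#' @return List `mean_versions_window`, `mean_ops_per_transition`,
#'   `mean_nodes_by_format` (named vector), `change_matrix`
#'   (version-to x model). Means over empty tables are `NA`, not zero.
#' @export
summarize_evolution <- function(diffstats, filestats, window_years = 5,
                                include_zero_transitions = TRUE,
                                include_triggered = TRUE) {
  mean_versions <- if (!nrow(filestats)) NA_real_ else {
    per_model <- split(filestats, filestats$model_id)
    mean(vapply(per_model, function(m) {
      lim <- min(m$timestamp) + window_years * 365.25 * 86400
      sum(m$timestamp <= lim)
    }, numeric(1)))
  }
  ops_total <- function(df) {
    tot <- df$op_inserts + df$op_deletes + df$op_updates + df$op_moves
    if (!include_triggered) tot <- tot - df$triggered_count
    tot
  }
  mean_ops <- if (!nrow(diffstats)) NA_real_ else {
    tot <- ops_total(diffstats)
    if (!include_zero_transitions) tot <- tot[tot > 0]
    if (length(tot)) mean(tot) else NA_real_
  }
  mean_nodes <- if (!nrow(filestats)) setNames(numeric(0), character(0)) else {
    latest <- filestats[order(filestats$model_id, filestats$timestamp), ]
    latest <- latest[!duplicated(latest$model_id, fromLast = TRUE), ]
    vapply(split(latest, latest$format), function(m) mean(m$nodes), numeric(1))
  }
  change_matrix <- if (!nrow(diffstats)) {
    matrix(0L, 0, 0)
  } else {
    tot <- ops_total(diffstats)
    rels <- sort(unique(diffstats$version_to))
    mods <- sort(unique(diffstats$model_id))
    m <- matrix(0L, length(rels), length(mods), dimnames = list(rels, mods))
    for (i in seq_len(nrow(diffstats)))
      m[diffstats$version_to[i], diffstats$model_id[i]] <-
        m[diffstats$version_to[i], diffstats$model_id[i]] + tot[i]
    m
  }
  list(mean_versions_window = mean_versions,
       mean_ops_per_transition = mean_ops,
       mean_nodes_by_format = mean_nodes,
       change_matrix = change_matrix)
}
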