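# On-disk ingestion layout:
#   <root>/<repository>/<model_id>/<NNN>_<version_id>/model.xml
#   <root>/<repository>/<model_id>/manifest.json
#   <root>/<repository>/<model_id>/ledger.json        (synthetic corpora)
# Live repository crawling is out of scope; this layout is the local
# stand-in for a repository snapshot.

iso_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a corpus to the ingestion layout
#'
#' @param corpus A list of [generate_history()] results or `model_history`
#'   objects.
#' @param root Output directory (created).
#' @param write_ledgers Write `ledger.json` alongside synthetic models.
#' @return `root`, invisibly.
#' @export
write_corpus <- function(corpus, root, write_ledgers = TRUE) {
  for (entry in corpus) {
    h <- if (inherits(entry, "model_history")) entry else entry$history
    ledger <- if (inherits(entry, "model_history")) NULL else entry$ledger
    mdir <- file.path(root, h$repository, h$model_id)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(model_id = h$model_id, repository = h$repository,
                     versions = list())
    for (i in seq_along(h$versions)) {
      vr <- h$versions[[i]]
      vdir <- file.path(mdir, sprintf("%03d_%s", i, vr$version_id))
      dir.create(vdir, showWarnings = FALSE)
      doc <- version_doc(vr, h$model_id)
      writeLines(sub("\n$", "", canonical_serialize(doc)),
                 file.path(vdir, "model.xml"))
      manifest$versions[[i]] <- list(
        version_id = vr$version_id, timestamp = iso_ts(vr$timestamp),
        curation_status = vr$curation_status,
        file = file.path(sprintf("%03d_%s", i, vr$version_id), "model.xml"))
    }
    jsonlite::write_json(manifest, file.path(mdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (write_ledgers && !is.null(ledger)) {
      led <- lapply(ledger, function(tr) list(
        version_from = tr$version_from, version_to = tr$version_to,
        entity_delta = as.list(tr$entity_delta),
        ops = lapply(tr$ops, op_to_list)))
      jsonlite::write_json(led, file.path(mdir, "ledger.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  invisible(root)
}

#' Read a corpus from the ingestion layout
#'
#' @param root Corpus directory.
#' @param model_prefix Optional model-id prefix filter.
#' @param formats Optional format filter ("SBML"/"CellML").
#' @param date_range Optional length-2 date range; versions outside it are
#'   dropped.
#' @return List of `model_history` objects with documents loaded.
#' @export
read_corpus <- function(root, model_prefix = NULL, formats = NULL,
                        date_range = NULL) {
  if (!dir.exists(root)) stop("corpus directory not found: ", root)
  manifests <- list.files(root, pattern = "^manifest\\.json$", recursive = TRUE,
                          full.names = TRUE)
  out <- list()
  for (mf in manifests) {
    man <- jsonlite::read_json(mf)
    if (!is.null(model_prefix) && !startsWith(man$model_id, model_prefix)) next
    mdir <- dirname(mf)
    versions <- list()
    for (v in man$versions) {
      ts <- as.POSIXct(v$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      if (!is.null(date_range) &&
          (ts < as.POSIXct(date_range[[1]], tz = "UTC") ||
           ts > as.POSIXct(date_range[[2]], tz = "UTC"))) next
      fp <- file.path(mdir, v$file)
      doc <- tryCatch(
        parse_model(fp, model_id = man$model_id, version_id = v$version_id,
                    timestamp = ts, source_uri = fp),
        error = function(e) {
          warning("skipping ", man$model_id, " version ", v$version_id, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(doc)) next
      if (!is.null(formats) && !(doc$format %in% formats)) next
      versions[[length(versions) + 1L]] <- list(
        version_id = v$version_id, timestamp = ts,
        curation_status = v$curation_status %||% "unknown",
        file = fp, doc = doc)
    }
    if (!length(versions)) next
    out[[length(out) + 1L]] <- new_model_history(
      man$model_id, man$repository %||% "other", versions)
  }
  out
}
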