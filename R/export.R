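# Delta renderings: JSON, XML patch dialect, and a human-readable report.

op_to_list <- function(op) {
  out <- list(op = op$op_type, kind = op$entity_kind)
  for (f in c("old_path", "new_path", "old_value", "new_value"))
    if (!is.na(op[[f]])) out[[f]] <- op[[f]]
  out$triggered <- op$triggered
  # extension fields required for lossless replay
  if (!is.na(op$label)) out$label <- op$label
  if (!is.na(op$ns) && nzchar(op$ns)) out$ns <- op$ns
  if (!is.na(op$new_index)) out$new_index <- op$new_index
  if (!is.null(op$payload)) out$payload <- canonical_serialize(op$payload)
  out
}

#' Render a delta as JSON
#' @param d A `delta`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` given).
#' @export
delta_to_json <- function(d, path = NULL) {
  s <- d$summary$by_type_kind
  obj <- list(
    model_id = d$model_id, version_from = d$version_from,
    version_to = d$version_to,
    summary = c(as.list(setNames(as.integer(as.vector(s)),
                                 as.vector(outer(rownames(s), colnames(s),
                                                 paste, sep = "_")))),
                list(triggered = d$summary$triggered, total = d$summary$total)),
    line_inserts = d$line_inserts, line_deletes = d$line_deletes,
    ops = lapply(d$ops, op_to_list))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Render a delta in the XML patch dialect
#'
#' One element per operation with attributes `op`, `kind`, `oldPath`,
#' `newPath`, `triggered` (plus extension attributes for replay).
#' @inheritParams delta_to_json
#' @export
delta_to_xml <- function(d, path = NULL) {
  doc <- xml2::xml_new_root("patch", modelId = d$model_id,
                            versionFrom = d$version_from,
                            versionTo = d$version_to)
  for (op in d$ops) {
    el <- xml2::xml_add_child(doc, "operation", op = op$op_type,
                              kind = op$entity_kind,
                              triggered = tolower(as.character(op$triggered)))
    if (!is.na(op$old_path)) xml2::xml_set_attr(el, "oldPath", op$old_path)
    if (!is.na(op$new_path)) xml2::xml_set_attr(el, "newPath", op$new_path)
    if (!is.na(op$old_value)) xml2::xml_set_attr(el, "oldValue", op$old_value)
    if (!is.na(op$new_value)) xml2::xml_set_attr(el, "newValue", op$new_value)
    if (!is.na(op$new_index)) xml2::xml_set_attr(el, "newIndex", as.character(op$new_index))
    if (!is.null(op$payload))
      xml2::xml_set_attr(el, "payload", canonical_serialize(op$payload))
  }
  txt <- as.character(doc)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Render a delta as a human-readable report
#' @inheritParams delta_to_json
#' @param include_triggered Include triggered operations in the listing.
#' @export
delta_to_text <- function(d, path = NULL, include_triggered = TRUE) {
  ops <- d$ops
  if (!include_triggered) ops <- Filter(function(o) !o$triggered, ops)
  header <- sprintf("Model %s: version %s -> %s", d$model_id, d$version_from,
                    d$version_to)
  body <- if (!length(d$ops)) {
    "No differences: the documents are canonically identical (0 operations)."
  } else {
    c(sprintf("%d operations (%d triggered); line diff +%d/-%d",
              d$summary$total, d$summary$triggered,
              d$line_inserts, d$line_deletes),
      vapply(ops, format, character(1)))
  }
  out <- c(header, strrep("-", nchar(header)), body)
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  paste(out, collapse = "\n")
}
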