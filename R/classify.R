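# COMODI-style annotation of diff operations.
#
# Three branches are populated automatically: Change (what kind of edit),
# XmlEntity (which XML construct), and Target (which part of the model,
# derived from the nearest enclosing recognized container on the op's
# path). Intention and Reason cannot be inferred from a structural diff and
# are deliberately not guessed: unrecognized containers yield an empty
# target set.

CHANGE_TERMS <- c(insert = "Insertion", delete = "Deletion",
                  update = "Update", move = "Move")
XML_ENTITY_TERMS <- c(element = "Node", attribute = "Attribute", text = "Text")

# container local-name -> Target term; nearest enclosing container wins
TARGET_TABLE <- c(
  # SBML
  species = "SpeciesSetup", listOfSpecies = "SpeciesSetup",
  speciesReference = "ReactionDefinition",
  reaction = "ReactionDefinition", listOfReactions = "ReactionDefinition",
  kineticLaw = "ReactionDefinition",
  compartment = "CompartmentSetup", listOfCompartments = "CompartmentSetup",
  parameter = "ParameterSetup", listOfParameters = "ParameterSetup",
  localParameter = "ParameterSetup",
  functionDefinition = "FunctionDefinition",
  listOfFunctionDefinitions = "FunctionDefinition",
  unitDefinition = "UnitDefinition", listOfUnitDefinitions = "UnitDefinition",
  event = "EventDefinition", listOfEvents = "EventDefinition",
  listOfRules = "MathematicalModel",
  algebraicRule = "MathematicalModel", assignmentRule = "MathematicalModel",
  rateRule = "MathematicalModel",
  math = "MathematicalModel",
  annotation = "ModelAnnotation",
  notes = "TextualDescription", documentation = "TextualDescription",
  # CellML
  component = "ComponentDefinition", variable = "VariableDefinition",
  connection = "VariableConnection", map_variables = "VariableConnection",
  map_components = "VariableConnection",
  units = "UnitDefinition")

#' The container-to-Target lookup table
#'
#' Returns (and optionally overrides from a JSON mapping file) the fixed
#' table mapping container element names to Target terms, so the term set
#' can track ontology revisions without a code change.
#'
#' @param mapping_file Optional path to a JSON object of
#'   `{"containerName": "TermName", ...}` entries that replace or extend the
#'   built-in table.
#' @return Named character vector.
#' @export
comodi_target_table <- function(mapping_file = NULL) {
  tab <- TARGET_TABLE
  if (!is.null(mapping_file)) {
    extra <- unlist(jsonlite::read_json(mapping_file))
    tab[names(extra)] <- unname(extra)
  }
  tab
}

path_labels <- function(path) {
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  parts <- parts[!startsWith(parts, "@") & !startsWith(parts, "text()")]
  sub("\\[\\d+\\]$", "", parts)
}

nearest_target <- function(path, table) {
  labs <- rev(path_labels(path))
  for (l in labs) {
    if (l %in% names(table)) return(unname(table[[l]]))
  }
  character(0)
}

#' Classify one diff operation with COMODI-style terms
#'
#' @param op A `diff_op`.
#' @param doc_context The document the op's anchored path resolves in (the
#'   base document for deletes/updates/moves, the target document for
#'   inserts); used only to validate that the path resolves.
#' @param target_table Lookup from [comodi_target_table()].
#' @param validate Set `FALSE` to skip the path-resolution check.
#' @return List with `change_term`, `xml_entity_term`, `target_terms`
#'   (character vector, possibly empty).
#' @export
classify_op <- function(op, doc_context = NULL,
                        target_table = comodi_target_table(),
                        validate = !is.null(doc_context)) {
  anchor <- if (!is.na(op$old_path)) op$old_path else op$new_path
  if (validate) {
    stopifnot(is_model_document(doc_context))
    if (is.null(resolve_path(doc_context$root, anchor)))
      stop("classification error: path does not resolve in context document: ",
           anchor, call. = FALSE)
  }
  targets <- unique(c(
    if (!is.na(op$old_path)) nearest_target(op$old_path, target_table),
    if (!is.na(op$new_path)) nearest_target(op$new_path, target_table)))
  list(change_term = unname(CHANGE_TERMS[[op$op_type]]),
       xml_entity_term = unname(XML_ENTITY_TERMS[[op$entity_kind]]),
       target_terms = targets)
}

#' Classify every op of one or more deltas
#'
#' @param deltas A `delta` or list of deltas.
#' @inheritParams classify_op
#' @return A `data.frame`, one row per op: `model_id`, `version_from`,
#'   `version_to`, `op_type`, `entity_kind`, `change_term`,
#'   `xml_entity_term`, `target_terms` (comma-joined), `triggered`.
#' @export
classify_delta <- function(deltas, target_table = comodi_target_table()) {
  if (inherits(deltas, "delta")) deltas <- list(deltas)
  rows <- list()
  for (d in deltas) {
    for (op in d$ops) {
      ann <- classify_op(op, target_table = target_table, validate = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = d$model_id, version_from = d$version_from,
        version_to = d$version_to, op_type = op$op_type,
        entity_kind = op$entity_kind, change_term = ann$change_term,
        xml_entity_term = ann$xml_entity_term,
        target_terms = paste(ann$target_terms, collapse = ","),
        triggered = op$triggered, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(model_id = character(), version_from = character(),
                      version_to = character(), op_type = character(),
                      entity_kind = character(), change_term = character(),
                      xml_entity_term = character(), target_terms = character(),
                      triggered = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Term-frequency table across deltas
#'
#' Counts, per COMODI branch, how often each term was assigned across all
#' operations of all deltas — the data behind a coverage heat rendering.
#' All Change and XmlEntity terms appear with zero counts when unused.
#'
#' @inheritParams classify_delta
#' @return `data.frame` with columns `branch`, `term`, `count`.
#' @export
summarize_comodi <- function(deltas, target_table = comodi_target_table()) {
  cl <- classify_delta(deltas, target_table)
  count_of <- function(values, universe) {
    tab <- table(factor(values, levels = universe))
    data.frame(term = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  ch <- count_of(cl$change_term, unname(CHANGE_TERMS))
  xe <- count_of(cl$xml_entity_term, unname(XML_ENTITY_TERMS))
  tt <- unlist(strsplit(cl$target_terms[nzchar(cl$target_terms)], ",", fixed = TRUE))
  tg <- count_of(tt, sort(unique(unname(TARGET_TABLE))))
  rbind(cbind(branch = "Change", ch),
        cbind(branch = "XmlEntity", xe),
        cbind(branch = "Target", tg))
}

#' Heat-color an SVG template by COMODI term frequency
#'
#' Takes an SVG whose shapes carry `id` attributes equal to term names and
#' sets each shape's `fill-opacity` to the term's relative frequency within
#' its branch (colours are scaled per branch, so intensities are only
#' comparable within a branch).
#'
#' @param freq Output of [summarize_comodi()].
#' @param template_svg Path to the SVG template.
#' @param out_svg Output path.
#' @return `out_svg`, invisibly.
#' @export
render_comodi_svg <- function(freq, template_svg, out_svg) {
  doc <- xml2::read_xml(template_svg)
  for (br in unique(freq$branch)) {
    sub <- freq[freq$branch == br, ]
    mx <- max(sub$count, 1L)
    for (i in seq_len(nrow(sub))) {
      node <- xml2::xml_find_first(doc, sprintf("//*[@id='%s']", sub$term[i]))
      if (!inherits(node, "xml_missing"))
        xml2::xml_set_attr(node, "fill-opacity",
                           sprintf("%.3f", 0.1 + 0.9 * sub$count[i] / mx))
    }
  }
  xml2::write_xml(doc, out_svg)
  invisible(out_svg)
}
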