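# Per-version feature vector: the filestats row.

SBML_RULE_LABELS <- c("algebraicRule", "assignmentRule", "rateRule", "rule",
                      "specieConcentrationRule", "speciesConcentrationRule",
                      "compartmentVolumeRule", "parameterRule")

#' Count model entities in a document
#'
#' Tallies the feature vector stored per model version: total XML element
#' nodes plus ten entity-specific counts. "XML nodes" counts element nodes
#' only — attributes and text are excluded — so the figure is comparable
#' across SBML and CellML. Counts are format-native: an SBML document always
#' reports `variables = components = 0`, a CellML document reports zero for
#' the SBML-only entities. All SBML rule dialects (algebraic, assignment,
#' rate, and the Level 1 variants) fold into the single `rules` count.
#'
#' @param doc A `model_document`.
#' @param curation_status "curated", "non-curated" or "unknown"; carried
#'   through from the ingestion manifest, never inferred from content.
#' @return A one-row `data.frame` with columns `model_id`, `version_id`,
#'   `format`, `curation_status`, `file_url`, `nodes`, `species`,
#'   `reactions`, `compartments`, `functions`, `parameters`, `rules`,
#'   `events`, `units`, `variables`, `components`.
#' @export
count_entities <- function(doc, curation_status = "unknown") {
  stopifnot(is_model_document(doc))
  labels <- character(0)
  rec <- function(node) {
    if (!is_element(node)) return(invisible(NULL))
    labels[[length(labels) + 1L]] <<- node$label
    for (k in node$children) rec(k)
  }
  rec(doc$root)
  tally <- function(lab) sum(labels %in% lab)
  sbml <- doc$format == "SBML"
  data.frame(
    model_id = doc$model_id, version_id = doc$version_id,
    format = doc$format, curation_status = curation_status,
    file_url = doc$source_uri,
    nodes = length(labels),
    species = if (sbml) tally(c("species", "specie")) else 0L,
    reactions = if (sbml) tally("reaction") else 0L,
    compartments = if (sbml) tally("compartment") else 0L,
    functions = if (sbml) tally("functionDefinition") else 0L,
    parameters = if (sbml) tally(c("parameter", "localParameter")) else 0L,
    rules = if (sbml) tally(SBML_RULE_LABELS) else 0L,
    events = if (sbml) tally("event") else 0L,
    units = if (sbml) tally("unitDefinition") else tally("units"),
    variables = if (sbml) 0L else tally("variable"),
    components = if (sbml) 0L else tally("component"),
    stringsAsFactors = FALSE)
}

ENTITY_COLS <- c("nodes", "species", "reactions", "compartments", "functions",
                 "parameters", "rules", "events", "units", "variables",
                 "components")
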