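test_that("classification maps op type, entity kind and path container", {
  base <- fix_sbml_small()
  a <- parse_fix(base)
  # insert a species
  b <- parse_fix(sub("</listOfSpecies>",
                     '<species id="S3" compartment="c1"/></listOfSpecies>',
                     base, fixed = TRUE), version_id = "2")
  d <- diff_models(a, b)
  ins <- Filter(function(o) o$op_type == "insert" &&
                  o$entity_kind == "element", d$ops)[[1]]
  ann <- classify_op(ins, b)
  expect_identical(ann$change_term, "Insertion")
  expect_identical(ann$xml_entity_term, "Node")
  expect_identical(ann$target_terms, "SpeciesSetup")
})

test_that("a text update inside notes is (Update, Text, TextualDescription)", {
  op <- modevol:::new_op("update", "text",
                         old_path = "/sbml[1]/model[1]/notes[1]/p[1]/text()[1]",
                         new_path = "/sbml[1]/model[1]/notes[1]/p[1]/text()[1]",
                         old_value = "a", new_value = "b")
  ann <- classify_op(op)
  expect_identical(ann$change_term, "Update")
  expect_identical(ann$xml_entity_term, "Text")
  expect_identical(ann$target_terms, "TextualDescription")
})

test_that("a CellML variable move carries variable/component targets", {
  op <- modevol:::new_op("move", "element",
                         old_path = "/model[1]/component[1]/variable[2]",
                         new_path = "/model[1]/component[3]/variable[1]")
  ann <- classify_op(op)
  expect_identical(ann$change_term, "Move")
  expect_identical(ann$target_terms, "VariableDefinition")
})

test_that("classification errors on an unresolvable path", {
  a <- parse_fix(fix_sbml_small())
  op <- modevol:::new_op("delete", "element",
                         old_path = "/sbml[1]/model[1]/listOfSpecies[1]/species[9]")
  expect_error(classify_op(op, a), "classification error")
})

test_that("unrecognized containers yield an empty target set, never a guess", {
  op <- modevol:::new_op("update", "attribute",
                         old_path = "/sbml[1]/model[1]/@name",
                         new_path = "/sbml[1]/model[1]/@name",
                         old_value = "a", new_value = "b")
  expect_length(classify_op(op)$target_terms, 0L)
})

test_that("the target table is overridable from a mapping file", {
  mf <- withr::local_tempfile(fileext = ".json")
  writeLines('{"model": "WholeModel"}', mf)
  tab <- comodi_target_table(mf)
  op <- modevol:::new_op("update", "attribute", old_path = "/model[1]/@name",
                         new_path = "/model[1]/@name",
                         old_value = "a", new_value = "b")
  expect_identical(classify_op(op, target_table = tab)$target_terms, "WholeModel")
})

test_that("every op gets exactly one Change and one XmlEntity term", {
  corpus <- generate_corpus(4, rng_seed = 31, n_versions = 3)
  denv <- new.env()
  ds <- build_diffstats(corpus, deltas_out = denv)
  deltas <- lapply(ls(denv), function(k) denv[[k]])
  cl <- classify_delta(deltas)
  n_ops <- sum(vapply(deltas, function(d) d$summary$total, integer(1)))
  expect_equal(nrow(cl), n_ops)
  expect_true(all(cl$change_term %in% c("Insertion", "Deletion", "Update", "Move")))
  expect_true(all(cl$xml_entity_term %in% c("Node", "Attribute", "Text")))
  # Change-branch totals equal the op-type totals computed independently
  freq <- summarize_comodi(deltas)
  ch <- freq[freq$branch == "Change", ]
  expect_equal(ch$count[ch$term == "Insertion"], sum(ds$op_inserts))
  expect_equal(ch$count[ch$term == "Deletion"], sum(ds$op_deletes))
  expect_equal(ch$count[ch$term == "Update"], sum(ds$op_updates))
  expect_equal(ch$count[ch$term == "Move"], sum(ds$op_moves))
  expect_equal(sum(ch$count), n_ops)
  # classification is a pure function: identical tables on a re-run
  expect_identical(freq, summarize_comodi(deltas))
})

test_that("comodi frequencies match planted ground truth on an insert-only corpus", {
  gh <- generate_history(generate_seed_model("SBML", rng_seed = 8), 4,
                         edit_spec(rng_seed = 8, n_edits = c(insert = 4),
                                   entity_mix = c(element = 1, attribute = 0,
                                                  text = 0)))
  deltas <- lapply(1:3, function(i)
    diff_models(gh$history$versions[[i]]$doc, gh$history$versions[[i + 1]]$doc))
  freq <- summarize_comodi(deltas)
  ch <- freq[freq$branch == "Change", ]
  total <- sum(vapply(deltas, function(d) d$summary$total, integer(1)))
  expect_equal(ch$count[ch$term == "Insertion"], total)
  expect_equal(sum(ch$count[ch$term != "Insertion"]), 0L)
})

test_that("empty delta list gives an all-zero table", {
  freq <- summarize_comodi(list())
  expect_true(all(freq$count == 0L))
  expect_setequal(unique(freq$branch), c("Change", "XmlEntity", "Target"))
})

test_that("SVG template heat-coloring sets per-branch opacities", {
  svg <- withr::local_tempfile(fileext = ".svg")
  writeLines(paste0('<svg xmlns="http://www.w3.org/2000/svg">',
                    '<rect id="Insertion"/><rect id="Deletion"/>',
                    '<rect id="SpeciesSetup"/></svg>'), svg)
  freq <- data.frame(branch = c("Change", "Change", "Target"),
                     term = c("Insertion", "Deletion", "SpeciesSetup"),
                     count = c(10L, 5L, 2L))
  out <- withr::local_tempfile(fileext = ".svg")
  render_comodi_svg(freq, svg, out)
  doc <- xml2::read_xml(out)
  opac <- function(id) as.numeric(xml2::xml_attr(
    xml2::xml_find_first(doc, sprintf("//*[@id='%s']", id)), "fill-opacity"))
  expect_equal(opac("Insertion"), 1.0)
  expect_lt(opac("Deletion"), opac("Insertion"))
  expect_equal(opac("SpeciesSetup"), 1.0)  # scaled within its own branch
})
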