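test_that("format detection follows the root element", {
  sb <- parse_fix('<sbml xmlns="http://www.sbml.org/sbml/level2"><model/></sbml>')
  expect_s3_class(sb, "model_document")
  expect_identical(sb$format, "SBML")
  expect_length(sb$root$children, 1L)

  cm <- parse_fix('<model xmlns="http://www.cellml.org/cellml/1.0#"/>')
  expect_identical(cm$format, "CellML")

  expect_error(parse_fix("<html><body/></html>"), "unsupported format")
  expect_error(parse_fix("<sbml><model></sbml>"), "parse error")
})

test_that("entity counts match manual enumeration on hand-built fixtures", {
  doc <- parse_fix(fix_sbml_small())
  ec <- count_entities(doc)
  expect_equal(ec$species, 2L)
  expect_equal(ec$reactions, 1L)
  expect_equal(ec$compartments, 1L)
  expect_equal(ec$parameters, 1L)
  expect_equal(ec$variables, 0L)
  expect_equal(ec$components, 0L)
  # independent XPath enumeration of element nodes
  expect_equal(ec$nodes, oracle_element_count(fix_sbml_small()))

  cdoc <- parse_fix(fix_cellml_small())
  cc <- count_entities(cdoc)
  expect_equal(cc$components, 2L)
  expect_equal(cc$variables, 3L)
  expect_equal(cc$units, 1L)
  expect_equal(cc$species, 0L)
  expect_equal(cc$nodes, oracle_element_count(fix_cellml_small()))

  empty <- parse_fix('<sbml xmlns="http://www.sbml.org/sbml/level2"><model/></sbml>')
  ee <- count_entities(empty)
  expect_equal(ee$nodes, 2L)
  expect_true(all(unlist(ee[setdiff(modevol:::ENTITY_COLS, "nodes")]) == 0L))
})

test_that("nodes is at least the sum of entity counts, incl. generated docs", {
  for (s in 1:5) {
    for (fmt in c("SBML", "CellML")) {
      doc <- generate_seed_model(fmt, rng_seed = s)
      ec <- count_entities(doc)
      expect_gte(ec$nodes,
                 sum(unlist(ec[setdiff(modevol:::ENTITY_COLS, "nodes")])))
      expect_equal(ec$nodes, oracle_element_count(canonical_serialize(doc)))
    }
  }
})

test_that("canonical serialization is idempotent and order-insensitive", {
  txts <- list(fix_sbml_small(), fix_cellml_small())
  for (txt in txts) {
    s1 <- canonical_serialize(parse_fix(txt))
    s2 <- canonical_serialize(parse_fix(s1))
    expect_identical(s1, s2)
  }
  # attribute reordering is cosmetic
  a <- parse_fix('<sbml xmlns="x:sbml"><model id="m" name="n"/></sbml>')
  b <- parse_fix('<sbml xmlns="x:sbml"><model name="n" id="m"/></sbml>')
  expect_identical(canonical_serialize(a), canonical_serialize(b))
  # a changed value is not
  c2 <- parse_fix('<sbml xmlns="x:sbml"><model name="n2" id="m"/></sbml>')
  expect_false(identical(canonical_serialize(a), canonical_serialize(c2)))
  # whitespace between elements is cosmetic
  w1 <- parse_fix("<sbml xmlns=\"x:sbml\">\n\n   <model/>\n</sbml>")
  w2 <- parse_fix('<sbml xmlns="x:sbml"><model/></sbml>')
  expect_identical(canonical_serialize(w1), canonical_serialize(w2))
})

test_that("namespace prefixes are rewritten to a stable table", {
  a <- parse_fix(paste0('<sbml xmlns="x:sbml"><model>',
                        '<m:math xmlns:m="x:mml"><m:ci>k</m:ci></m:math>',
                        "</model></sbml>"))
  b <- parse_fix(paste0('<sbml xmlns="x:sbml" xmlns:weird="x:mml"><model>',
                        "<weird:math><weird:ci>k</weird:ci></weird:math>",
                        "</model></sbml>"))
  expect_identical(canonical_serialize(a), canonical_serialize(b))
})

test_that("entity counts are invariant under cosmetic changes", {
  base <- fix_sbml_small()
  shuffled <- sub('id="S1" compartment="c1" initialConcentration="1"',
                  'initialConcentration="1" id="S1" compartment="c1"',
                  base, fixed = TRUE)
  expect_identical(count_entities(parse_fix(base)),
                   count_entities(parse_fix(shuffled)))
})

test_that("text inside notes is verbatim, other text is normalized", {
  doc <- parse_fix(paste0('<sbml xmlns="x:s"><model>',
                          "<notes><p>two  spaces kept </p></notes>",
                          "<math><ci>  k1\n </ci></math></model></sbml>"))
  s <- canonical_serialize(doc)
  expect_match(s, "two  spaces kept ", fixed = TRUE)
  expect_match(s, "<ci>k1</ci>", fixed = TRUE)
})
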