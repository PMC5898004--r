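test_that("identical documents give an empty delta and zero line changes", {
  a <- parse_fix(fix_sbml_small())
  d <- diff_models(a, a)
  expect_equal(d$summary$total, 0L)
  expect_equal(d$line_inserts, 0L)
  expect_equal(d$line_deletes, 0L)
})

test_that("distinct model ids are refused", {
  a <- parse_fix(fix_sbml_small(), model_id = "A")
  b <- parse_fix(fix_sbml_small(), model_id = "B")
  expect_error(diff_models(a, b), "model_id mismatch")
})

test_that("matching: identical trees map totally, label-disjoint trees map roots only", {
  a <- parse_fix(fix_sbml_small())
  m <- match_trees(a, a)
  ea <- m$a$tab[m$a$tab$kind == "element", ]
  expect_true(all(!is.na(m$map[ea$uid])))
  # partner has the same path in the identical copy
  expect_identical(m$a$tab$path[match(ea$uid, m$a$tab$uid)],
                   m$b$tab$path[match(m$map[ea$uid], m$b$tab$uid)])

  x <- parse_fix('<sbml xmlns="x:s"><alpha/><beta/></sbml>')
  y <- parse_fix('<sbml xmlns="x:s"><gamma/><delta/></sbml>')
  m2 <- match_trees(x, y)
  expect_equal(sum(!is.na(m2$map)), 1L)  # roots only
})

test_that("a renamed species is still matched structurally", {
  base <- fix_sbml_small()
  renamed <- sub('id="S2"', 'id="S2renamed"', base, fixed = TRUE)
  a <- parse_fix(base)
  b <- parse_fix(renamed)
  d <- diff_models(a, b)
  # exactly one op: the id attribute update (no delete+insert of the species)
  expect_equal(d$summary$total, 1L)
  op <- d$ops[[1]]
  expect_identical(op$op_type, "update")
  expect_identical(op$entity_kind, "attribute")
  expect_identical(op$old_value, "S2")
  expect_identical(op$new_value, "S2renamed")
})

test_that("single attribute change yields exactly one update op", {
  base <- fix_sbml_small()
  b <- parse_fix(sub('initialConcentration="1"', 'initialConcentration="2"',
                     base, fixed = TRUE), version_id = "2")
  a <- parse_fix(base)
  d <- diff_models(a, b)
  expect_equal(d$summary$total, 1L)
  expect_equal(d$summary$by_type_kind["update", "attribute"], 1L)
  expect_false(d$ops[[1]]$triggered)
})

test_that("relocating an id-bearing species is a single non-triggered move", {
  base <- fix_sbml_small()
  moved <- sub(paste0('<species id="S1" compartment="c1" initialConcentration="1"/>\n',
                      '      <species id="S2" compartment="c1" initialConcentration="0.5"/>'),
               paste0('<species id="S2" compartment="c1" initialConcentration="0.5"/>\n',
                      '      <species id="S1" compartment="c1" initialConcentration="1"/>'),
               base, fixed = TRUE)
  a <- parse_fix(base)
  b <- parse_fix(moved, version_id = "2")
  d <- diff_models(a, b)
  expect_equal(d$summary$total, 1L)
  expect_equal(d$summary$by_type_kind["move", "element"], 1L)
  expect_false(d$ops[[1]]$triggered)
  expect_true(canonical_equal(apply_delta(a, d), b))
})

test_that("deleting a subtree yields one root delete plus triggered ops", {
  full <- fix_sbml_plain_reaction()
  gutted <- sub("<reaction>.*</reaction>\n    ", "", full)
  a <- parse_fix(full)
  b <- parse_fix(gutted, version_id = "2")
  # the fixture reaction subtree has attribute-free descendants:
  # reaction > listOfReactants > speciesReference, listOfProducts > speciesReference
  n_desc <- 4L
  d <- diff_models(a, b)
  dels <- Filter(function(o) o$op_type == "delete", d$ops)
  expect_equal(length(dels), 1L + n_desc)
  expect_equal(sum(vapply(dels, function(o) !o$triggered, logical(1))), 1L)
  expect_equal(sum(vapply(dels, `[[`, logical(1), "triggered")), n_desc)
  expect_true(canonical_equal(apply_delta(a, d), b))
})

test_that("line_diff agrees with the quadratic LCS oracle", {
  expect_equal(unname(line_diff("a\nb", "a\nb")), c(0L, 0L))
  expect_equal(unname(line_diff("a\nb", "a\nb\nc\nd\ne")), c(3L, 0L))
  set.seed(77)
  for (i in 1:25) {
    a <- sample(letters[1:6], sample(0:40, 1), replace = TRUE)
    b <- sample(letters[1:6], sample(0:40, 1), replace = TRUE)
    expect_equal(line_diff(a, b), oracle_line_counts(a, b))
  }
})

test_that("apply_delta round-trips arbitrary generated pairs", {
  for (s in 1:6) {
    fmt <- if (s %% 2) "SBML" else "CellML"
    gh <- generate_history(generate_seed_model(fmt, rng_seed = 400 + s), 3,
                           edit_spec(rng_seed = s, n_edits = 10))
    for (i in 1:2) {
      va <- gh$history$versions[[i]]$doc
      vb <- gh$history$versions[[i + 1]]$doc
      expect_true(canonical_equal(apply_delta(va, diff_models(va, vb)), vb))
    }
  }
})

test_that("applying a delta to the wrong base is an inconsistent-delta error", {
  a <- parse_fix(fix_sbml_small())
  b <- parse_fix(sub('initialConcentration="1"', 'initialConcentration="2"',
                     fix_sbml_small(), fixed = TRUE), version_id = "2")
  d <- diff_models(a, b)
  wrong <- parse_fix(sub('value="0.1"', 'value="9"',
                         sub('initialConcentration="1"', 'initialConcentration="3"',
                             fix_sbml_small(), fixed = TRUE)))
  expect_error(apply_delta(wrong, d), class = "modevol_inconsistent_delta")
  # path that does not exist at all
  d2 <- d
  d2$ops[[1]]$old_path <- "/sbml[1]/model[1]/listOfSpecies[1]/species[9]/@initialConcentration"
  expect_error(apply_delta(a, d2), class = "modevol_inconsistent_delta")
})

test_that("cosmetic differences produce an empty delta", {
  base <- fix_sbml_small()
  cosmetic <- gsub('id="S1" compartment="c1" initialConcentration="1"',
                   'initialConcentration="1"   compartment="c1" id="S1"',
                   base, fixed = TRUE)
  cosmetic <- gsub("\n    ", "\n        ", cosmetic)
  d <- diff_models(parse_fix(base), parse_fix(cosmetic, version_id = "2"))
  expect_equal(d$summary$total, 0L)
  expect_equal(d$line_inserts + d$line_deletes, 0L)
})

test_that("symmetry: op tallies mirror when diffing in reverse", {
  for (s in 1:4) {
    fmt <- if (s %% 2) "SBML" else "CellML"
    gh <- generate_history(generate_seed_model(fmt, rng_seed = 500 + s), 2,
                           edit_spec(rng_seed = s))
    va <- gh$history$versions[[1]]$doc
    vb <- gh$history$versions[[2]]$doc
    sab <- summarize_ops(diff_models(va, vb)$ops)$by_type_kind
    sba <- summarize_ops(diff_models(vb, va)$ops)$by_type_kind
    expect_equal(sum(sab["insert", ]), sum(sba["delete", ]))
    expect_equal(sum(sab["delete", ]), sum(sba["insert", ]))
    expect_equal(sum(sab["update", ]), sum(sba["update", ]))
    expect_equal(sum(sab["move", ]), sum(sba["move", ]))
  }
})

test_that("deltas are deterministic and export round-trips structurally", {
  gh <- generate_history(generate_seed_model("SBML", rng_seed = 9), 2,
                         edit_spec(rng_seed = 2))
  va <- gh$history$versions[[1]]$doc
  vb <- gh$history$versions[[2]]$doc
  d1 <- diff_models(va, vb); d2 <- diff_models(va, vb)
  expect_identical(delta_to_json(d1), delta_to_json(d2))
  js <- jsonlite::fromJSON(delta_to_json(d1), simplifyVector = FALSE)
  expect_equal(length(js$ops), d1$summary$total)
  expect_equal(js$summary$total, d1$summary$total)
  xp <- xml2::read_xml(delta_to_xml(d1))
  expect_equal(length(xml2::xml_find_all(xp, "//operation")), d1$summary$total)
  txt <- delta_to_text(d1)
  expect_match(txt, sprintf("%d operations", d1$summary$total))
})
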