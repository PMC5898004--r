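test_that("seed models honour requested sizes and are seed-deterministic", {
  doc <- generate_seed_model("SBML", size = list(species = 5, reactions = 3),
                             rng_seed = 42)
  ec <- count_entities(doc)
  expect_equal(ec$species, 5L)
  expect_equal(ec$reactions, 3L)
  expect_identical(canonical_serialize(doc),
                   canonical_serialize(
                     generate_seed_model("SBML",
                                         size = list(species = 5, reactions = 3),
                                         rng_seed = 42)))
  cd <- generate_seed_model("CellML", size = list(components = 4, variables = 8),
                            rng_seed = 7)
  cc <- count_entities(cd)
  expect_equal(cc$components, 4L)
  expect_equal(cc$variables, 8L)
})

test_that("histories are deterministic and timestamps strictly increase", {
  sd <- generate_seed_model("SBML", rng_seed = 1)
  g1 <- generate_history(sd, 4, edit_spec(rng_seed = 3))
  g2 <- generate_history(sd, 4, edit_spec(rng_seed = 3))
  for (i in 1:4)
    expect_identical(canonical_serialize(g1$history$versions[[i]]$doc),
                     canonical_serialize(g2$history$versions[[i]]$doc))
  ts <- vapply(g1$history$versions, function(v) as.numeric(v$timestamp),
               numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("n_versions = 1 gives the seed only; n_edits = 0 gives empty deltas", {
  sd <- generate_seed_model("CellML", rng_seed = 2)
  g <- generate_history(sd, 1)
  expect_length(g$history$versions, 1L)
  expect_length(g$ledger, 0L)

  g0 <- generate_history(sd, 3, edit_spec(rng_seed = 2, n_edits = 0))
  for (i in 1:2) {
    va <- g0$history$versions[[i]]$doc
    vb <- g0$history$versions[[i + 1]]$doc
    expect_true(canonical_equal(va, vb))
    expect_equal(diff_models(va, vb)$summary$total, 0L)
  }
})

test_that("replaying the ledger reproduces every stored version byte-exactly", {
  for (s in c(12, 13)) {
    fmt <- if (s %% 2) "SBML" else "CellML"
    gh <- generate_history(generate_seed_model(fmt, rng_seed = s), 4,
                           edit_spec(rng_seed = s, n_edits = 8))
    cur <- gh$history$versions[[1]]$doc
    for (i in seq_along(gh$ledger)) {
      d <- modevol:::new_delta(cur$model_id, gh$ledger[[i]]$version_from,
                               gh$ledger[[i]]$version_to, gh$ledger[[i]]$ops)
      cur <- apply_delta(cur, d)
      expect_identical(canonical_serialize(cur),
                       canonical_serialize(gh$history$versions[[i + 1]]$doc))
    }
  }
})

test_that("diff recovers the planted op multiset exactly on id-stable histories", {
  for (s in c(61, 62, 63, 64)) {
    fmt <- if (s %% 2) "SBML" else "CellML"
    gh <- generate_history(generate_seed_model(fmt, rng_seed = s), 4,
                           edit_spec(rng_seed = s, n_edits = 12))
    for (i in seq_along(gh$ledger)) {
      d <- diff_models(gh$history$versions[[i]]$doc,
                       gh$history$versions[[i + 1]]$doc)
      expect_identical(sort(vapply(d$ops, op_key, character(1))),
                       sort(vapply(gh$ledger[[i]]$ops, op_key, character(1))),
                       info = paste("seed", s, "transition", i))
    }
  }
})

test_that("ledger entity deltas agree with recounting each version", {
  gh <- generate_history(generate_seed_model("SBML", rng_seed = 33), 3,
                         edit_spec(rng_seed = 33))
  for (i in seq_along(gh$ledger)) {
    before <- count_entities(gh$history$versions[[i]]$doc)
    after <- count_entities(gh$history$versions[[i + 1]]$doc)
    expect_equal(unlist(after[modevol:::ENTITY_COLS]) -
                   unlist(before[modevol:::ENTITY_COLS]),
                 gh$ledger[[i]]$entity_delta)
  }
})

test_that("edit_spec validates its probability vectors", {
  expect_error(edit_spec(op_mix = c(insert = 0.9, delete = 0.9,
                                    update = 0, move = 0)))
  expect_error(edit_spec(n_edits = -1))
  sp <- edit_spec(cellml_like = TRUE)
  expect_gt(sp$op_mix[["move"]], edit_spec()$op_mix[["move"]])
})

test_that("corpora are regenerable and mixed-format", {
  c1 <- generate_corpus(4, rng_seed = 9, n_versions = 2)
  c2 <- generate_corpus(4, rng_seed = 9, n_versions = 2)
  for (i in seq_along(c1))
    for (j in 1:2)
      expect_identical(canonical_serialize(c1[[i]]$history$versions[[j]]$doc),
                       canonical_serialize(c2[[i]]$history$versions[[j]]$doc))
  expect_setequal(vapply(c1, function(e) e$history$repository, character(1)),
                  c("biomodels-like", "pmr-like"))
})
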