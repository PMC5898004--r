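make_corpus <- function() generate_corpus(6, rng_seed = 21, n_versions = 3)

test_that("filestats has one row per version and counts match the oracle", {
  corpus <- make_corpus()
  fs <- build_filestats(corpus)
  expect_equal(nrow(fs), sum(vapply(corpus, function(e)
    length(e$history$versions), integer(1))))
  for (i in sample(nrow(fs), 5)) {
    h <- Filter(function(e) e$history$model_id == fs$model_id[i], corpus)[[1]]
    vr <- Filter(function(v) v$version_id == fs$version_id[i],
                 h$history$versions)[[1]]
    expect_equal(fs$nodes[i],
                 oracle_element_count(canonical_serialize(vr$doc)))
  }
  expect_equal(nrow(build_filestats(list())), 0L)
})

test_that("diffstats: one row per consecutive pair; zero-change rows are kept", {
  corpus <- make_corpus()
  ds <- build_diffstats(corpus)
  expect_equal(nrow(ds), sum(vapply(corpus, function(e)
    length(e$history$versions) - 1L, integer(1))))

  # single version -> no rows
  one <- generate_history(generate_seed_model("SBML", rng_seed = 3), 1)
  expect_equal(nrow(build_diffstats(list(one))), 0L)

  # identical consecutive versions -> an all-zero row, not a dropped row
  doc <- generate_seed_model("SBML", rng_seed = 4)
  gh0 <- generate_history(doc, 3, edit_spec(rng_seed = 4, n_edits = 0))
  ds0 <- build_diffstats(list(gh0))
  expect_equal(nrow(ds0), 2L)
  expect_true(all(ds0[, c("line_inserts", "line_deletes", "op_inserts",
                          "op_deletes", "op_updates", "op_moves",
                          "triggered_count")] == 0L))
})

test_that("diffstats columns equal planted ledger tallies", {
  corpus <- make_corpus()
  ds <- build_diffstats(corpus)
  for (e in corpus) {
    for (tr in e$ledger) {
      row <- ds[ds$model_id == e$history$model_id &
                  ds$version_from == tr$version_from &
                  ds$version_to == tr$version_to, ]
      expect_equal(nrow(row), 1L)
      types <- vapply(tr$ops, `[[`, character(1), "op_type")
      expect_equal(row$op_inserts, sum(types == "insert"))
      expect_equal(row$op_deletes, sum(types == "delete"))
      expect_equal(row$op_updates, sum(types == "update"))
      expect_equal(row$op_moves, sum(types == "move"))
      expect_equal(row$triggered_count,
                   sum(vapply(tr$ops, `[[`, logical(1), "triggered")))
    }
  }
})

test_that("every diffstats row links to filestats rows", {
  corpus <- make_corpus()
  fs <- build_filestats(corpus)
  ds <- build_diffstats(corpus)
  keys <- paste(fs$model_id, fs$version_id)
  expect_true(all(paste(ds$model_id, ds$version_from) %in% keys))
  expect_true(all(paste(ds$model_id, ds$version_to) %in% keys))
})

test_that("repo evolution accumulates latest-version vectors and sums repos", {
  corpus <- make_corpus()
  re <- build_repo_evolution(corpus)
  comb <- re[re$repository == "combined", ]
  per <- re[re$repository != "combined", ]
  for (cn in c("models", modevol:::ENTITY_COLS)) {
    agg <- tapply(per[[cn]], per$date, sum)
    expect_equal(unname(agg[as.character(comb$date)]), comb[[cn]],
                 ignore_attr = TRUE)
  }
  # model counts never decrease on a withdrawal-free corpus
  for (r in unique(re$repository))
    expect_true(all(diff(re$models[re$repository == r]) >= 0))
  # a date before every timestamp yields zero vectors
  early <- build_repo_evolution(corpus,
                                date_grid = as.POSIXct("1999-01-01", tz = "UTC"))
  expect_true(all(early$models == 0L))
  expect_true(all(early$nodes == 0L))
})

test_that("two models appearing at t1 < t2 give counts 1 then 2", {
  d1 <- generate_seed_model("SBML", rng_seed = 1, model_id = "A",
                            timestamp = as.POSIXct("2006-01-01", tz = "UTC"))
  d2 <- generate_seed_model("SBML", rng_seed = 2, model_id = "B",
                            timestamp = as.POSIXct("2007-01-01", tz = "UTC"))
  hs <- list(generate_history(d1, 1), generate_history(d2, 1))
  re <- build_repo_evolution(hs, date_grid = c(d1$timestamp, d2$timestamp))
  comb <- re[re$repository == "combined", ]
  expect_equal(comb$models, c(1L, 2L))
})

test_that("summaries match hand-computed values and degrade to NA", {
  # single model, 2 versions, known op count
  gh <- generate_history(generate_seed_model("SBML", rng_seed = 10), 2,
                         edit_spec(rng_seed = 10, n_edits = 5))
  fs <- build_filestats(list(gh))
  ds <- build_diffstats(list(gh))
  sm <- summarize_evolution(ds, fs)
  planted_total <- length(gh$ledger[[1]]$ops)
  expect_equal(sm$mean_ops_per_transition, planted_total)
  expect_equal(sm$mean_versions_window, 2)
  expect_equal(dim(sm$change_matrix), c(1L, 1L))
  expect_equal(unname(sm$change_matrix[1, 1]), planted_total)

  # empty diffstats -> absent, not zero
  sm0 <- summarize_evolution(modevol:::empty_diffstats(), fs)
  expect_true(is.na(sm0$mean_ops_per_transition))
  sm00 <- summarize_evolution(modevol:::empty_diffstats(),
                              modevol:::empty_filestats())
  expect_true(is.na(sm00$mean_versions_window))
})

test_that("unparseable versions are skipped with a warning and recorded", {
  td <- withr::local_tempdir()
  corpus <- generate_corpus(2, rng_seed = 5, format = "SBML", n_versions = 2)
  write_corpus(corpus, td)
  # corrupt one version file
  f <- list.files(td, pattern = "model.xml", recursive = TRUE,
                  full.names = TRUE)[[2]]
  writeLines("<sbml><broken", f)
  expect_warning(hs <- read_corpus(td), "skipping")
  fs <- build_filestats(hs)
  expect_equal(nrow(fs), 3L)
})
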