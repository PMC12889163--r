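# end-to-end task runners on generated fixtures

perfectProfiles <- function(n = 3) lapply(seq_len(n), function(i)
  list(name = paste0("perfect", i), coverage = 1,
       accuracy = c(1, 1, 1, 1), noise = 0))

test_that("simulate -> evaluate reports weighted F1 1.0 for a perfect
           model at every level", {
  d <- withr::local_tempdir()
  fixtures <- file.path(d, "fix")
  runSimulate(list(out = fixtures, n_proteins = 60, seed = 11,
                   multi_label_rate = 0, incomplete_rate = 0,
                   model_profiles = perfectProfiles(1)))
  out <- file.path(d, "eval")
  runEvaluate(list(out = out, truth = file.path(fixtures, "truth.tsv"),
                   predictions = list(
                     perfect1 = file.path(fixtures, "model_perfect1.tsv")),
                   seed = 11))
  report <- readReport(file.path(out, "metrics_perfect1.json"))
  for (lm in report)
    expect_equal(lm@aggregates[["weighted_f1"]], 1)
  expect_true(file.exists(file.path(out, "manifest_evaluate.json")))
  expect_true(file.exists(file.path(out, "sunburst_perfect1.json")))
})

test_that("runs are reproducible: same config and seed give byte-identical
           reports", {
  d <- withr::local_tempdir()
  fixtures <- file.path(d, "fix")
  runSimulate(list(out = fixtures, n_proteins = 40, seed = 5))
  cfg <- function(out) list(out = out,
                            truth = file.path(fixtures, "truth.tsv"),
                            predictions = list(
                              alpha = file.path(fixtures, "model_alpha.tsv"),
                              bravo = file.path(fixtures, "model_bravo.tsv")),
                            seed = 5)
  runEvaluate(cfg(file.path(d, "e1")))
  runEvaluate(cfg(file.path(d, "e2")))
  for (f in c("metrics_alpha.json", "metrics_alpha.tsv",
              "metrics_alpha_batched.tsv", "sunburst_bravo.json"))
    expect_identical(readLines(file.path(d, "e1", f)),
                     readLines(file.path(d, "e2", f)))
})

test_that("runComplete reports agreement 1.0 when all models are perfect", {
  d <- withr::local_tempdir()
  fixtures <- file.path(d, "fix")
  runSimulate(list(out = fixtures, n_proteins = 60, seed = 13,
                   multi_label_rate = 0, incomplete_rate = 0.4,
                   model_profiles = perfectProfiles(3)))
  out <- file.path(d, "comp")
  runComplete(list(out = out, truth = file.path(fixtures, "truth.tsv"),
                   predictions = setNames(as.list(file.path(
                     fixtures, sprintf("model_perfect%d.tsv", 1:3))),
                     paste0("perfect", 1:3)),
                   seed = 13))
  summary <- jsonlite::read_json(file.path(out, "completion_summary.json"))
  expect_equal(summary$agreement_rate, 1)
  expect_gt(summary$n_entries, 0)
})

test_that("runRecommend reports weighted similarity 1.0 for a perfect model
           at full coverage", {
  d <- withr::local_tempdir()
  fixtures <- file.path(d, "fix")
  runSimulate(list(out = fixtures, n_proteins = 40, seed = 7,
                   multi_label_rate = 0, incomplete_rate = 0,
                   held_out_fraction = 0,
                   model_profiles = perfectProfiles(1)))
  out <- file.path(d, "rec")
  runRecommend(list(out = out, truth = file.path(fixtures, "truth.tsv"),
                    reactions = file.path(fixtures, "reactions.tsv"),
                    predictions = list(
                      perfect1 = file.path(fixtures, "model_perfect1.tsv")),
                    seed = 7))
  summary <- jsonlite::read_json(file.path(out, "similarity_summary.json"),
                                 simplifyVector = TRUE)
  expect_equal(summary$coverage, 100)
  expect_equal(summary$weighted_similarity, 1)
})

test_that("runEnsemble and runCompare produce their artifacts", {
  d <- withr::local_tempdir()
  fixtures <- file.path(d, "fix")
  runSimulate(list(out = fixtures, n_proteins = 50, seed = 3))
  preds <- list(alpha = file.path(fixtures, "model_alpha.tsv"),
                bravo = file.path(fixtures, "model_bravo.tsv"),
                charlie = file.path(fixtures, "model_charlie.tsv"))
  out <- file.path(d, "ens")
  runEnsemble(list(out = out, base = preds, method = "vote"))
  expect_true(file.exists(file.path(out, "ensemble_vote.tsv")))
  runEnsemble(list(out = out, base = preds, method = "stack",
                   validation_truth = file.path(fixtures, "truth.tsv"),
                   validation_base = preds, seed = 3))
  expect_true(file.exists(file.path(out, "ensemble_stack.tsv")))

  cmp <- file.path(d, "cmp")
  runCompare(list(out = cmp, truth = file.path(fixtures, "truth.tsv"),
                  predictions = preds[1:2], seed = 3))
  expect_true(file.exists(file.path(cmp, "sunburst_diff.json")))
  # comparing a model with itself gives an all-zero difference tree
  cmp2 <- file.path(d, "cmp2")
  runCompare(list(out = cmp2, truth = file.path(fixtures, "truth.tsv"),
                  predictions = preds[c(1, 1)], seed = 3))
  diff <- jsonlite::read_json(file.path(cmp2, "sunburst_diff.json"))
  collectF1 <- function(n) c(if (!is.null(n$f1)) n$f1,
                             unlist(lapply(n$children, collectF1)))
  expect_true(all(unlist(collectF1(diff)) == 0))
})

test_that("runCurate writes filtered training data with a provenance log", {
  d <- withr::local_tempdir()
  set.seed(1101)
  base <- randomAA(80)
  writeFasta(c(T1 = base, T2 = randomAA(80), T3 = randomAA(80)),
             file.path(d, "train.fasta"))
  writeAnnotations(mkAnnot(T1 = "1.1.1.1", T2 = "2.2.2.2", T3 = "3.3.3.3"),
                   file.path(d, "train.tsv"))
  writeFasta(c(X1 = base), file.path(d, "test.fasta"))
  writeAnnotations(mkAnnot(X1 = "1.1.1.1"), file.path(d, "test.tsv"))
  out <- file.path(d, "cur")
  runCurate(list(out = out, train_fasta = file.path(d, "train.fasta"),
                 train_truth = file.path(d, "train.tsv"),
                 test_fasta = file.path(d, "test.fasta"),
                 test_truth = file.path(d, "test.tsv"),
                 threshold = 100))
  kept <- readFasta(file.path(out, "train_filtered.fasta"))
  expect_setequal(names(kept), c("T2", "T3"))
  prov <- jsonlite::read_json(file.path(out, "provenance.json"),
                              simplifyVector = TRUE)
  expect_true("filter_similar_100" %in% prov$step)
})

test_that("a failing run removes its partial outputs", {
  d <- withr::local_tempdir()
  out <- file.path(d, "bad")
  expect_error(runEvaluate(list(out = out, truth = file.path(d, "nope.tsv"),
                                predictions = list(m = "also-missing"))),
               "no such file")
  expect_length(list.files(out, pattern = "^(metrics|sunburst)"), 0L)
})
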