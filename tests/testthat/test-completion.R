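test_that("findIncomplete lists exactly the depth<4 (protein, label) pairs", {
  at <- mkAnnot(P1 = c("1.1.1.1", "2.-.-.-"), P2 = "1.1.-.-",
                P3 = "3.3.3.3")
  inc <- findIncomplete(at)
  expect_identical(nrow(inc), 2L)
  expect_setequal(inc$partial_ec, c("2.-.-.-", "1.1.-.-"))
  expect_identical(nrow(findIncomplete(mkAnnot(P1 = "1.1.1.1"))), 0L)
})

test_that("topPrediction takes the highest score with lexicographic ties
           and NA for absent proteins", {
  pt <- mkPred("m", rep("P1", 2), c("1.1.1.1", "2.1.1.1"), c(0.8, 0.6))
  expect_identical(unname(topPrediction(pt, "P1")), "1.1.1.1")
  tie <- mkPred("m", rep("P1", 2), c("2.1.1.1", "1.1.1.1"), c(0.8, 0.8))
  expect_identical(unname(topPrediction(tie, "P1")), "1.1.1.1")
  expect_true(is.na(topPrediction(pt, "P9")))
})

test_that("strict >half majority semantics, including the 2-2 split", {
  ids <- c("E1", "E2", "E3")
  entries <- data.frame(protein_id = ids,
                        partial_ec = rep("1.1.-.-", 3))
  # 5 models: tops per entry designed by hand
  tops <- rbind(E1 = c("1.1.1.1", "1.1.1.1", "1.1.1.1", "1.1.1.2", NA),
                E2 = c("1.1.1.1", "1.1.1.1", "1.1.1.2", "1.1.1.2", NA),
                E3 = c("1.1.1.9", "1.1.1.9", "1.1.1.9", "1.1.1.9",
                       "1.1.1.9"))
  models <- lapply(1:5, function(j)
    mkTopModel(paste0("m", j), setNames(tops[, j], ids)))
  res <- agreementRateEval(models, entries)
  expect_identical(res@perEntry$majority_ec, c("1.1.1.1", NA, "1.1.1.9"))
  expect_equal(res@agreementRate, 2 / 3)
  expect_identical(unname(res@perModelCount), c(2L, 2L, 2L, 1L, 1L))

  # 4 models, 2-2 split: 2 is not > 2 -> no majority
  m4 <- lapply(1:4, function(j)
    mkTopModel(paste0("m", j),
               c(E1 = c("1.1.1.1", "1.1.1.1", "2.1.1.1", "2.1.1.1")[j])))
  r4 <- agreementRateEval(m4[1:4],
                          data.frame(protein_id = "E1",
                                     partial_ec = "1.1.-.-"))
  expect_true(is.na(r4@perEntry$majority_ec))
  expect_equal(r4@agreementRate, 0)
})

test_that("agreement equals an exhaustive tally on random vote patterns and
           is model-order invariant", {
  set.seed(801)
  pool <- c("1.1.1.1", "1.1.1.2", "2.1.1.1", "3.1.1.1")
  for (i in 1:40) {
    nModels <- sample(3:7, 1L)
    nEntries <- sample(3:12, 1L)
    ids <- paste0("E", seq_len(nEntries))
    tops <- matrix(sample(c(pool, NA), nModels * nEntries, replace = TRUE),
                   nrow = nEntries, dimnames = list(ids, NULL))
    entries <- data.frame(protein_id = ids, partial_ec = "1.1.-.-")
    models <- lapply(seq_len(nModels), function(j)
      mkTopModel(paste0("m", j), tops[, j]))
    res <- agreementRateEval(models, entries)
    want <- oracleAgreement(tops)
    expect_equal(res@agreementRate, want$rate)
    expect_identical(unname(res@perModelCount), as.integer(want$counts))
    perm <- sample(nModels)
    res2 <- agreementRateEval(models[perm], entries)
    expect_equal(res2@agreementRate, res@agreementRate)
    expect_identical(res2@perModelCount[paste0("m", seq_len(nModels))],
                     res@perModelCount[paste0("m", seq_len(nModels))])
  }
})

test_that("an always-abstaining extra model can only break majorities", {
  set.seed(802)
  pool <- c("1.1.1.1", "2.1.1.1")
  for (i in 1:20) {
    ids <- paste0("E", 1:6)
    tops <- matrix(sample(c(pool, NA), 18, replace = TRUE), nrow = 6,
                   dimnames = list(ids, NULL))
    entries <- data.frame(protein_id = ids, partial_ec = "1.1.-.-")
    models <- lapply(1:3, function(j) mkTopModel(paste0("m", j), tops[, j]))
    withAbst <- c(models, list(mkTopModel("abst",
                                          setNames(rep(NA_character_, 6),
                                                   ids))))
    r1 <- agreementRateEval(models, entries)
    r2 <- agreementRateEval(withAbst, entries)
    had <- !is.na(r1@perEntry$majority_ec)
    still <- !is.na(r2@perEntry$majority_ec)
    expect_true(all(still[!had] == FALSE))
    expect_true(all(r2@perEntry$majority_ec[still] ==
                      r1@perEntry$majority_ec[still]))
  }
})

test_that("prefix consistency reports the fraction of tops completing the
           partial label", {
  entries <- data.frame(protein_id = c("E1", "E2"),
                        partial_ec = c("1.1.-.-", "2.-.-.-"))
  consistent <- mkTopModel("c", c(E1 = "1.1.1.1", E2 = "2.3.1.4"))
  half <- mkTopModel("h", c(E1 = "1.1.1.1", E2 = "9.9.9.9"))
  other <- mkTopModel("o", c(E1 = "5.5.5.5", E2 = "9.9.9.9"))
  res <- agreementRateEval(list(consistent, half, other), entries)
  expect_equal(unname(res@prefixConsistency[c("c", "h", "o")]),
               c(1, 0.5, 0))
})

test_that("agreement batching reports per-model mean and sd over a seeded
           partition", {
  set.seed(803)
  ids <- paste0("E", 1:25)
  entries <- data.frame(protein_id = ids, partial_ec = "1.1.-.-")
  models <- lapply(1:3, function(j)
    mkTopModel(paste0("m", j), setNames(rep("1.1.1.1", 25), ids)))
  res <- agreementRateEval(models, entries, nBatches = 5, seed = 3)
  expect_identical(res@batchStats$mean, rep(5, 3))
  expect_identical(res@batchStats$sd, rep(0, 3))
  r2 <- agreementRateEval(models, entries, nBatches = 5, seed = 3)
  expect_identical(res@batchStats, r2@batchStats)
})

test_that("validateAgreement correlates agreement counts with F1", {
  spec <- syntheticSpec(nProteins = 400, incompleteRate = 0.3, seed = 47)
  tr <- generateTruth(spec)
  preds <- generatePredictions(spec, tr)
  va <- validateAgreement(preds, tr$annots, level = 4)
  expect_identical(nrow(va$perModel), 5L)
  # planted quality ordering: designed-better models agree and score higher
  expect_gt(va$r, 0.5)
  expect_lt(va$p, 0.2)

  # identical models on identical truth: zero variance -> NA
  perfect <- syntheticSpec(nProteins = 30, multiLabelRate = 0,
                           incompleteRate = 0,
                           modelProfiles = lapply(1:3, function(i) list(
                             name = paste0("p", i), coverage = 1,
                             accuracy = c(1, 1, 1, 1), noise = 0)),
                           seed = 5)
  trP <- generateTruth(perfect)
  vaP <- validateAgreement(generatePredictions(perfect, trP), trP$annots)
  expect_true(is.na(vaP$r))
})
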