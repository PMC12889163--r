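# small hand-built reaction table: two 3-level families with near-identical
# reactions inside a family, one EC deliberately absent from the table
mkToyTable <- function() {
  ReactionTable(data.frame(
    ec = c("1.1.1.1", "1.1.1.2", "1.1.1.3",
           "2.2.2.1", "2.2.2.2"),
    reaction = c("CCO.O>>CCC.N", "CCO.O>>CCC.C", "CCO.N>>CCC.N",
                 "c1ccccc1.P>>SSS.P", "c1ccccc1.P>>SSS.S"),
    stringsAsFactors = FALSE))
}

test_that("tanimoto is intersection over union on bit sets", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(1L, 2L), 0)
  fp <- fingerprintTokenHash("CCO.O>>CC=O")
  expect_identical(fp, fingerprintTokenHash("CCO.O>>CC=O"))  # deterministic
  expect_true(all(fp >= 0 & fp < 1024))
})

test_that("reaction similarity is 1 on self, symmetric, and bounded", {
  tab <- mkToyTable()
  for (e in reactionECs(tab))
    expect_equal(reactionSimilarity(e, e, tab), 1)
  set.seed(901)
  ecs <- reactionECs(tab)
  for (i in 1:20) {
    a <- sample(ecs, 1); b <- sample(ecs, 1)
    sab <- reactionSimilarity(a, b, tab)
    expect_equal(sab, reactionSimilarity(b, a, tab))
    expect_gte(sab, 0); expect_lte(sab, 1)
  }
})

test_that("a held-out EC falls back to the seeded sibling-sample average", {
  tab <- mkToyTable()
  # "1.1.1.9" is absent; its 3-level siblings are 1.1.1.{1,2,3}
  sibs <- c("1.1.1.1", "1.1.1.2", "1.1.1.3")
  want <- mean(vapply(sibs, function(s)
    reactionSimilarity(s, "2.2.2.1", tab), 1))
  got <- reactionSimilarity("1.1.1.9", "2.2.2.1", tab, maxSamples = 10)
  expect_equal(got, want, tolerance = 1e-12)
  # with maxSamples < #siblings the sampled subset is seed-stable
  s1 <- reactionSimilarity("1.1.1.9", "2.2.2.1", tab, seed = 5,
                           maxSamples = 2)
  s2 <- reactionSimilarity("1.1.1.9", "2.2.2.1", tab, seed = 5,
                           maxSamples = 2)
  expect_identical(s1, s2)
})

test_that("fallback relaxes the shared prefix from 3 levels down to 1 and
           warns when nothing matches", {
  tab <- mkToyTable()
  # no 1.9.* family: relax to level 1 siblings (the 1.1.1.* entries)
  lvl1 <- mean(vapply(c("1.1.1.1", "1.1.1.2", "1.1.1.3"), function(s)
    reactionSimilarity(s, "2.2.2.1", tab), 1))
  expect_equal(reactionSimilarity("1.9.9.9", "2.2.2.1", tab), lvl1,
               tolerance = 1e-12)
  expect_warning(
    z <- reactionSimilarity("7.7.7.7", "2.2.2.1", tab), "similarity 0")
  expect_equal(z, 0)
  # partial query labels use their defined prefix
  expect_equal(reactionSimilarity("2.2.-.-", "2.2.2.1", tab),
               mean(vapply(c("2.2.2.1", "2.2.2.2"), function(s)
                 reactionSimilarity(s, "2.2.2.1", tab), 1)),
               tolerance = 1e-12)
})

test_that("best-pair similarity is the exhaustive cross-product maximum", {
  tab <- mkToyTable()
  pred <- c("1.1.1.1", "2.2.2.1")
  true <- c("2.2.2.2", "1.1.1.3")
  want <- max(vapply(pred, function(p) vapply(true, function(t)
    reactionSimilarity(p, t, tab), 1), numeric(2L)))
  expect_equal(bestPairSimilarity(pred, true, tab), want)
  expect_equal(bestPairSimilarity("1.1.1.1", "1.1.1.1", tab), 1)
  expect_error(bestPairSimilarity(character(0), "1.1.1.1", tab))
})

test_that("similarity reports satisfy the weighted = average x coverage/100
           identity", {
  tab <- mkToyTable()
  truth <- mkAnnot(P1 = "1.1.1.1", P2 = "2.2.2.1", P3 = "1.1.1.2",
                   P4 = "2.2.2.2")
  preds <- list(P1 = "1.1.1.1", P2 = "2.2.2.2", P3 = "1.1.1.3")
  rep <- similarityReport(preds, truth, tab)
  expect_equal(rep@coverage, 75)
  expect_equal(rep@weightedSimilarity,
               rep@averageSimilarity * rep@coverage / 100,
               tolerance = 1e-12)
  # no predictions: coverage 0, average NA, weighted 0
  repNone <- similarityReport(setNames(list(), character(0)), truth, tab)
  expect_equal(repNone@coverage, 0)
  expect_true(is.na(repNone@averageSimilarity))
  expect_equal(repNone@weightedSimilarity, 0)
})

test_that("within-family similarity exceeds cross-family similarity on the
           planted synthetic reaction structure", {
  spec <- syntheticSpec(nProteins = 10, reactionFamilyNoise = 0.2,
                        heldOutFraction = 0, seed = 59)
  tab <- generateReactionTable(spec)
  ecs <- reactionECs(tab)
  fam <- ecTruncate(ecs, 3)
  set.seed(902)
  pairs <- t(replicate(200, sample(seq_along(ecs), 2)))
  sims <- apply(pairs, 1, function(ij)
    reactionSimilarity(ecs[ij[1]], ecs[ij[2]], tab))
  same <- fam[pairs[, 1]] == fam[pairs[, 2]]
  skipIf <- !any(same)
  expect_true(any(!same))
  if (!skipIf)
    expect_gt(mean(sims[same]), mean(sims[!same]))
  # noise 0 -> sibling reactions identical -> within-family similarity 1
  spec0 <- syntheticSpec(nProteins = 10, reactionFamilyNoise = 0,
                         heldOutFraction = 0, seed = 59)
  tab0 <- generateReactionTable(spec0)
  e0 <- reactionECs(tab0)
  sib <- e0[ecTruncate(e0, 3) == ecTruncate(e0[1], 3)]
  expect_equal(reactionSimilarity(sib[1], sib[2], tab0), 1)
})

test_that("selectUnseen keeps only (protein, label) pairs new to training", {
  train <- mkAnnot(T1 = "1.1.1.1")
  test <- mkAnnot(P1 = "1.1.1.1", P2 = "1.1.1.2",
                  P3 = c("1.1.1.1", "2.2.2.2"))
  out <- selectUnseen(test, train)
  expect_setequal(proteins(out), c("P2", "P3"))
  expect_identical(labelSets(out)$P3, "2.2.2.2")
})

test_that("additionalPredictions keeps proteins matching truth plus extras", {
  truth <- mkAnnot(P1 = "1.1.1.1", P2 = "1.1.1.1",
                   P3 = c("1.1.1.1", "2.2.2.2"))
  preds <- list(P1 = c("1.1.1.1", "3.3.3.3"),   # matched + extra -> kept
                P2 = "4.4.4.4",                 # truth unmatched -> dropped
                P3 = c("1.1.1.1", "2.2.2.2"))   # no extras -> dropped
  out <- additionalPredictions(preds, truth)
  expect_identical(out$protein_id, "P1")
  expect_identical(out$extra, "3.3.3.3")
})
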