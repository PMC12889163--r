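test_that("evaluateLevel matches hand-counted confusion on the basic cases", {
  truth <- mkAnnot(P1 = "1.1.1.1")
  lm <- lapply(1:4, function(l) evaluateLevel(truth, list(P1 = "1.1.1.1"), l))
  expect_true(all(vapply(lm, function(x)
    x@aggregates[["weighted_f1"]], 1) == 1))

  truth <- mkAnnot(P1 = "1.1.1.1", P2 = "2.3.1.4")
  pred <- list(P1 = "1.1.1.1", P2 = "2.3.1.5")
  expect_equal(evaluateLevel(truth, pred, 3)@aggregates[["weighted_f1"]], 1)
  l4 <- evaluateLevel(truth, pred, 4)
  pc <- l4@perClass
  expect_equal(pc$f1[pc$ec == "1.1.1.1"], 1)
  expect_equal(pc$f1[pc$ec == "2.3.1.4"], 0)
  expect_equal(l4@aggregates[["weighted_f1"]], 0.5)
  expect_equal(unname(l4@aggregates[c("micro_precision", "micro_recall",
                                      "micro_f1")]), rep(0.5, 3))
})

test_that("proteins with only shallow truth are excluded at deeper levels", {
  truth <- mkAnnot(P1 = "1.1.-.-", P2 = "2.3.1.4")
  pred <- list(P1 = "1.1.1.1", P2 = "2.3.1.4")
  expect_identical(evaluateLevel(truth, pred, 2)@nProteins, 2L)
  l3 <- evaluateLevel(truth, pred, 3)
  expect_identical(l3@nProteins, 1L)           # P1 excluded
  expect_false("1.1.1.-" %in% l3@perClass$ec[l3@perClass$support > 0])
  # partial predicted labels are dropped at deeper levels too
  l4 <- evaluateLevel(mkAnnot(P1 = "1.1.1.1"), list(P1 = "1.1.-.-"), 4)
  expect_equal(l4@aggregates[["micro_precision"]], 0)
  expect_error(evaluateLevel(AnnotationTable(list()), pred, 1),
               "empty truth")
})

test_that("metrics equal the brute-force confusion oracle on random instances", {
  set.seed(501)
  for (i in 1:60) {
    inst <- randomInstance()
    for (level in 1:4) {
      got <- evaluateLevel(inst$truth, inst$predSets, level)
      want <- oracleLevel(inst$truthSets, inst$predSets, level)
      expect_equal(got@aggregates, want$aggregates, tolerance = 1e-12)
      expect_equal(got@perClass$f1, want$perClass$f1, tolerance = 1e-12)
      expect_identical(got@perClass$ec, want$perClass$ec)
    }
  }
})

test_that("micro metrics are relabeling-invariant; support-0 classes do not
           move the weighted average", {
  set.seed(502)
  inst <- randomInstance()
  base <- evaluateLevel(inst$truth, inst$predSets, 4)
  # add a prediction-only class (support 0)
  pred2 <- inst$predSets
  pred2[[1L]] <- unique(c(pred2[[1L]], "7.7.7.7"))
  with0 <- evaluateLevel(inst$truth, pred2, 4)
  expect_equal(with0@aggregates[["weighted_f1"]],
               base@aggregates[["weighted_f1"]], tolerance = 1e-12)
  expect_true(with0@aggregates[["micro_precision"]] <=
                base@aggregates[["micro_precision"]])
  # single-label truth/pred: micro P == micro R == exact-match accuracy
  ids <- paste0("Q", 1:40)
  labs <- replicate(40, randomLabel(depth = 4))
  truth1 <- AnnotationTable(setNames(as.list(labs), ids))
  pred1 <- setNames(as.list(ifelse(runif(40) < 0.6, labs,
                                   replicate(40, randomLabel(depth = 4)))),
                    ids)
  m <- evaluateLevel(truth1, pred1, 4)@aggregates
  acc <- mean(unlist(pred1) == labs)
  expect_equal(unname(m[["micro_precision"]]), acc, tolerance = 1e-12)
  expect_equal(unname(m[["micro_recall"]]), acc, tolerance = 1e-12)
})

test_that("batched evaluation partitions proteins 94/94/94/93/93-style", {
  set.seed(503)
  ids <- sprintf("P%03d", 1:468)
  truth <- AnnotationTable(setNames(as.list(
    replicate(468, randomLabel(depth = 4))), ids))
  batches <- enzEval:::.seededBatches(ids, 5L, seed = 9L)
  expect_identical(unname(lengths(batches)), c(94L, 94L, 94L, 93L, 93L))
  expect_setequal(unlist(batches), ids)

  # identical per-protein performance -> sd 0
  pred <- labelSets(truth)
  res <- evaluateBatched(truth, pred, 4, nBatches = 5, seed = 1)
  expect_true(all(res$mean == 1))
  expect_true(all(res$sd == 0))
  expect_error(evaluateBatched(truth[ids[1:3]], pred, 4, nBatches = 5),
               "fewer")
})

test_that("batched micro-F1 tracks pooled micro-F1 on homogeneous data", {
  set.seed(504)
  n <- 2000L
  ids <- sprintf("P%04d", seq_len(n))
  labs <- replicate(n, randomLabel(depth = 4))
  truth <- AnnotationTable(setNames(as.list(labs), ids))
  pred <- setNames(as.list(ifelse(runif(n) < 0.7, labs,
                                  replicate(n, randomLabel(depth = 4)))),
                   ids)
  pooled <- evaluateLevel(truth, pred, 4)@aggregates[["micro_f1"]]
  b <- evaluateBatched(truth, pred, 4, nBatches = 5, seed = 2)
  expect_lt(abs(b$mean[b$metric == "micro_f1"] - pooled), 0.05)
})

test_that("group evaluation is additive in micro counts and matches
           evaluateLevel for a single group", {
  set.seed(505)
  inst <- randomInstance()
  ids <- proteins(inst$truth)
  oneGroup <- setNames(rep("all", length(ids)), ids)
  byg <- evaluateByGroup(inst$truth, inst$predSets, 4, oneGroup)
  expect_equal(byg$all@aggregates,
               evaluateLevel(inst$truth, inst$predSets, 4)@aggregates)

  groups <- setNames(sample(c("euk", "bac"), length(ids), replace = TRUE),
                     ids)
  byg2 <- evaluateByGroup(inst$truth, inst$predSets, 4, groups)
  pooledTp <- sum(evaluateLevel(inst$truth, inst$predSets, 4)@perClass$tp)
  expect_equal(sum(vapply(byg2, function(lm) sum(lm@perClass$tp), 1)),
               pooledTp)
  # proteins without a group land in "ungrouped"
  byg3 <- evaluateByGroup(inst$truth, inst$predSets, 4, groups[-1])
  expect_true("ungrouped" %in% names(byg3))
})

test_that("perClassTable nodes agree with evaluateLevel per-class values", {
  set.seed(506)
  inst <- randomInstance()
  pc <- perClassTable(inst$truth, inst$predSets)
  for (level in unique(pc$level)) {
    lm <- evaluateLevel(inst$truth, inst$predSets, level)
    sub <- pc[pc$level == level, , drop = FALSE]
    expect_identical(sub$ec, lm@perClass$ec)
    expect_equal(sub$f1, lm@perClass$f1, tolerance = 0)
    expect_identical(sub$support, lm@perClass$support)
  }
  # prediction-only nodes carry support 0 and f1 0
  pc2 <- perClassTable(mkAnnot(P1 = "1.1.1.1"),
                       list(P1 = c("1.1.1.1", "2.2.2.2")))
  node <- pc2[pc2$ec == "2.2.2.2", ]
  expect_identical(node$support, 0L)
  expect_equal(node$f1, 0)
})
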