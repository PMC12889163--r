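# independent oracles: plain-loop reference implementations used to
# cross-check the vectorized package code

# explicit one-vs-rest confusion counting at one EC level
oracleLevel <- function(truthSets, predSets, level) {
  keep <- names(truthSets)[vapply(truthSets, function(s)
    any(ecDepth(s) >= level), TRUE)]
  tset <- lapply(truthSets[keep], function(s)
    unique(ecTruncate(s[ecDepth(s) >= level], level)))
  pset <- lapply(keep, function(p) {
    s <- predSets[[p]]
    if (is.null(s)) return(character(0))
    unique(ecTruncate(s[ecDepth(s) >= level], level))
  })
  names(pset) <- keep
  classes <- sort(unique(c(unlist(tset), unlist(pset))))
  if (is.null(classes)) classes <- character(0)
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (cl in classes) for (p in keep) {
    it <- cl %in% tset[[p]]
    ip <- cl %in% pset[[p]]
    if (it && ip) tp[cl] <- tp[cl] + 1
    else if (ip) fp[cl] <- fp[cl] + 1
    else if (it) fn[cl] <- fn[cl] + 1
  }
  support <- tp + fn
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  mp <- if (TP + FP == 0) 0 else TP / (TP + FP)
  mr <- if (TP + FN == 0) 0 else TP / (TP + FN)
  s <- support > 0
  # no evaluable protein at this level: every aggregate is undefined (NA),
  # matching the package's documented convention
  naAll <- length(keep) == 0L
  list(perClass = data.frame(ec = classes, support = support, tp = tp,
                             fp = fp, fn = fn, precision = prec,
                             recall = rec, f1 = f1, row.names = NULL,
                             stringsAsFactors = FALSE),
       aggregates = if (naAll) c(
         micro_precision = NA_real_, micro_recall = NA_real_,
         micro_f1 = NA_real_, macro_precision = NA_real_,
         macro_recall = NA_real_, macro_f1 = NA_real_,
         weighted_precision = NA_real_, weighted_recall = NA_real_,
         weighted_f1 = NA_real_) else c(
         micro_precision = mp, micro_recall = mr,
         micro_f1 = if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr),
         macro_precision = if (!any(s)) 0 else mean(prec[s]),
         macro_recall = if (!any(s)) 0 else mean(rec[s]),
         macro_f1 = if (!any(s)) 0 else mean(f1[s]),
         weighted_precision = if (sum(support) == 0) 0 else
           sum(prec * support) / sum(support),
         weighted_recall = if (sum(support) == 0) 0 else
           sum(rec * support) / sum(support),
         weighted_f1 = if (sum(support) == 0) 0 else
           sum(f1 * support) / sum(support)))
}

# binary F1 of emitting class `cls` at threshold t, by direct counting
oracleClassF1 <- function(scores, isPositive, nPositives, t) {
  emit <- scores >= t
  tp <- sum(emit & isPositive)
  fp <- sum(emit & !isPositive)
  fn <- nPositives - tp
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# modal labels of a vote vector (NA = abstention, ignored)
oracleMode <- function(votes) {
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0L) return(character(0))
  counts <- table(votes)
  sort(names(counts)[counts == max(counts)])
}

# strict >half majority tally over a tops matrix (rows = entries,
# cols = models, NA = abstain); denominator = all models
oracleAgreement <- function(tops) {
  nModels <- ncol(tops)
  majority <- apply(tops, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    counts <- table(v)
    m <- max(counts)
    if (m > nModels / 2) names(counts)[which.max(counts)] else NA_character_
  })
  counts <- vapply(seq_len(nModels), function(j)
    sum(!is.na(majority) & !is.na(tops[, j]) & tops[, j] == majority),
    integer(1L))
  list(rate = mean(!is.na(majority)), counts = counts, majority = majority)
}

# all-pairs greedy clustering without any prefilter, one alignment at a
# time (reference for builtinCluster)
oracleGreedyCluster <- function(seqs, identity) {
  seqs <- as.character(Biostrings::AAStringSet(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  assign <- setNames(character(length(ids)), ids)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      pid <- enzEval:::.alignIdentity(seqs[[r]], seqs[[id]])
      if (pid >= identity) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, id); assign[id] <- id }
    else assign[id] <- hit
  }
  assign
}

# mutated family of sequences around a common ancestor
mkFamily <- function(base, n, mutRate, prefix) {
  out <- vapply(seq_len(n), function(i) {
    s <- strsplit(base, "")[[1L]]
    k <- rbinom(1L, length(s), mutRate)
    if (k > 0) {
      pos <- sample(length(s), k)
      s[pos] <- sample(Biostrings::AA_STANDARD, k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  setNames(out, paste0(prefix, seq_len(n)))
}

randomAA <- function(n) paste(sample(Biostrings::AA_STANDARD, n,
                                     replace = TRUE), collapse = "")
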