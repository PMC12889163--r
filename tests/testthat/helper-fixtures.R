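# fixture builders shared across test files; everything is generated in
# code under fixed seeds, nothing is read from disk

mkAnnot <- function(...) AnnotationTable(list(...))

mkPred <- function(model, protein_id, ec, score) {
  PredictionTable(data.frame(protein_id = protein_id, ec = ec,
                             score = score, stringsAsFactors = FALSE),
                  model)
}

# a model that predicts exactly `tops` (named character, NA = abstain),
# all with score 1
mkTopModel <- function(model, tops) {
  keep <- !is.na(tops)
  mkPred(model, names(tops)[keep], tops[keep], rep(1, sum(keep)))
}

# random canonical EC label from a small hierarchy; depth sampled unless
# fixed
randomLabel <- function(shape = c(3, 3, 3, 3), depth = NULL) {
  if (is.null(depth)) depth <- sample(1:4, 1L, prob = c(1, 1, 1, 5))
  tok <- rep("-", 4L)
  for (k in seq_len(depth)) tok[k] <- sample.int(shape[k], 1L)
  paste(tok, collapse = ".")
}

# random evaluation instance: <= nProteins proteins, classes drawn from a
# pool of <= nClasses complete labels, truth possibly partial/multi-label
randomInstance <- function(nProteins = 30L, nClasses = 10L) {
  pool <- unique(replicate(nClasses, randomLabel(depth = 4L)))
  ids <- paste0("P", seq_len(sample.int(nProteins, 1L)))
  truthSets <- lapply(ids, function(p) {
    labs <- sample(pool, sample(1:2, 1L))
    if (runif(1) < 0.25) labs[1L] <- ecTruncate(labs[1L], sample(1:3, 1L))
    unique(labs)
  })
  names(truthSets) <- ids
  predSets <- lapply(ids, function(p) {
    if (runif(1) < 0.15) return(NULL)   # abstain
    labs <- sample(pool, sample(1:3, 1L))
    if (runif(1) < 0.15) labs[1L] <- ecTruncate(labs[1L], sample(1:3, 1L))
    unique(labs)
  })
  names(predSets) <- ids
  predSets <- predSets[!vapply(predSets, is.null, TRUE)]
  list(truth = AnnotationTable(truthSets), truthSets = truthSets,
       predSets = predSets)
}
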