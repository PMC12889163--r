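#' Reaction similarity between two EC numbers
#'
#' When both EC numbers have reaction records in the table, the similarity
#' is the maximum pairwise Tanimoto similarity over their cached reaction
#' fingerprints (an EC matches if any reaction it catalyzes matches). When
#' an EC is absent from the table — reaction datasets are incomplete — its
#' fourth level is ignored and up to \code{maxSamples} table ECs sharing the
#' first three defined levels are sampled without replacement (seeded); the
#' reported value is the average similarity of those surrogates to the
#' other EC. If no three-level siblings exist the specificity is
#' progressively reduced to two, then one shared levels; if still none, the
#' similarity is 0 with a warning.
#'
#' @param a,b canonical EC labels (complete or partial).
#' @param table a [ReactionTable-class].
#' @param seed integer seed for surrogate sampling.
#' @param maxSamples maximum number of sampled siblings (default 10).
#' @return similarity in [0,1]; symmetric when both ECs are in the table.
#' @export
reactionSimilarity <- function(a, b, table, seed = 17L, maxSamples = 10L) {
  stopifnot(is(table, "ReactionTable"), maxSamples >= 1L)
  if (nrow(table@entries) == 0L) stop("empty reaction table")
  a <- ecParse(a); b <- ecParse(b)
  .withSeed(seed, .recSim(a, b, table, as.integer(maxSamples)))
}

.recSim <- function(a, b, table, maxSamples) {
  known <- reactionECs(table)
  aIn <- a %in% known; bIn <- b %in% known
  if (aIn && bIn) return(.directSim(a, b, table))
  miss <- if (!aIn) a else b
  other <- if (!aIn) b else a
  sibs <- .siblingECs(miss, known)
  if (length(sibs) == 0L) {
    warning("no reaction-table EC shares any level with ", miss,
            "; similarity 0", call. = FALSE)
    return(0)
  }
  take <- if (length(sibs) > maxSamples)
    sample(sibs, maxSamples) else sibs
  mean(vapply(take, function(s) .recSim(s, other, table, maxSamples),
              numeric(1L)))
}

# table ECs sharing the deepest possible defined prefix with `ec`
# (at most 3 levels: the fourth level is ignored)
.siblingECs <- function(ec, known) {
  d <- min(3L, ecDepth(ec))
  while (d >= 1L) {
    sibs <- known[ecTruncate(known, d) == ecTruncate(ec, d)]
    if (length(sibs)) return(sibs)
    d <- d - 1L
  }
  character(0)
}

.directSim <- function(a, b, table) {
  fa <- table@fingerprints[table@entries$ec == a]
  fb <- table@fingerprints[table@entries$ec == b]
  max(vapply(fa, function(x)
    max(vapply(fb, function(y) tanimoto(x, y), numeric(1L))), numeric(1L)))
}

#' Best-pair similarity between predicted and true EC sets
#'
#' Multi-label enzymes can have several predicted and several true EC
#' numbers; the score is the maximum [reactionSimilarity()] over all
#' (predicted, true) pairs.
#'
#' @param predicted,true non-empty character vectors of EC labels.
#' @inheritParams reactionSimilarity
#' @return similarity in [0,1].
#' @export
bestPairSimilarity <- function(predicted, true, table, seed = 17L,
                               maxSamples = 10L) {
  stopifnot(length(predicted) >= 1L, length(true) >= 1L)
  max(vapply(predicted, function(p)
    vapply(true, function(t)
      reactionSimilarity(p, t, table, seed = seed, maxSamples = maxSamples),
      numeric(1L)), numeric(length(true))))
}

#' Coverage, average and weighted similarity for one model
#'
#' Aggregates per-protein best-pair reaction similarities into the three
#' model-level quantities of the recommendation task:
#' \deqn{Coverage = 100 \times \frac{\#proteins\ with\ predictions}
#'   {\#proteins\ in\ the\ dataset}}
#' \deqn{Average = \frac{\sum_p similarity(p)}{\#proteins\ with\ predictions}}
#' \deqn{Weighted = Average \times Coverage / 100}
#' so that models predicting for more proteins are not penalized unfairly.
#' With no predicted proteins, coverage is 0, the average is NA and the
#' weighted score is 0.
#'
#' @param preds named list mapping protein to a non-empty set of predicted
#'   EC labels (e.g. from [applyThresholds()]).
#' @param truth an [AnnotationTable-class] defining the evaluated proteins.
#' @inheritParams reactionSimilarity
#' @param model model name recorded in the report.
#' @param truncateTo optional integer 1..3: truncate predicted labels to
#'   this level before scoring (the partial-recommendation mode); NULL
#'   (default) scores the labels as emitted.
#' @return a [SimilarityReport-class].
#' @export
similarityReport <- function(preds, truth, table, seed = 17L,
                             maxSamples = 10L, model = "model",
                             truncateTo = NULL) {
  stopifnot(is(truth, "AnnotationTable"))
  if (length(truth) == 0L) stop("empty truth table")
  preds <- .assertLabelSets(preds)
  preds <- .dropEmptySets(preds)
  ids <- proteins(truth)
  covered <- intersect(names(preds), ids)
  coverage <- 100 * length(covered) / length(ids)
  truthSets <- labelSets(truth)
  per <- vapply(covered, function(p) {
    pl <- preds[[p]]
    if (!is.null(truncateTo)) pl <- unique(ecTruncate(pl, truncateTo))
    bestPairSimilarity(pl, truthSets[[p]], table,
                       seed = .deriveSeed(seed, p), maxSamples = maxSamples)
  }, numeric(1L))
  avg <- if (length(covered) == 0L) NA_real_ else mean(per)
  new("SimilarityReport", model = model, coverage = coverage,
      averageSimilarity = avg,
      weightedSimilarity = if (is.na(avg)) 0 else avg * coverage / 100,
      perProtein = per)
}

setMethod("show", "SimilarityReport", function(object) {
  cat(sprintf(
    "SimilarityReport '%s': coverage %.1f%%, average %.4f, weighted %.4f\n",
    object@model, object@coverage, object@averageSimilarity,
    object@weightedSimilarity))
})

#' Restrict a test set to (protein, label) pairs unseen in training
#'
#' Keeps test annotations whose full label occurs in no training
#' annotation; proteins left with empty sets are dropped. Used to evaluate
#' generalization to EC numbers never seen in the training data.
#'
#' @param testTruth,trainTruth [AnnotationTable-class] objects.
#' @return an [AnnotationTable-class].
#' @export
selectUnseen <- function(testTruth, trainTruth) {
  stopifnot(is(testTruth, "AnnotationTable"),
            is(trainTruth, "AnnotationTable"))
  seen <- unique(trainTruth@entries$ec)
  e <- testTruth@entries
  AnnotationTable(e[!(e$ec %in% seen), , drop = FALSE])
}

#' Find proteins with correctly matched plus additional predictions
#'
#' Retains proteins where the predictions contain at least one true label
#' and at least one label beyond the truth — candidate additional enzyme
#' functions. Each extra label can then be scored against the true set with
#' [bestPairSimilarity()].
#'
#' @param preds named list mapping protein to predicted EC label sets.
#' @param truth an [AnnotationTable-class].
#' @return data.frame with columns \code{protein_id}, \code{matched},
#'   \code{extra} (semicolon-joined label lists).
#' @export
additionalPredictions <- function(preds, truth) {
  stopifnot(is(truth, "AnnotationTable"))
  preds <- .assertLabelSets(preds)
  truthSets <- labelSets(truth)
  rows <- lapply(intersect(names(preds), names(truthSets)), function(p) {
    pl <- unique(ecParse(preds[[p]]))
    tl <- truthSets[[p]]
    matched <- intersect(pl, tl)
    extra <- setdiff(pl, tl)
    if (length(matched) == 0L || length(extra) == 0L) return(NULL)
    data.frame(protein_id = p,
               matched = paste(sort(matched), collapse = ";"),
               extra = paste(sort(extra), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(protein_id = character(0),
                                         matched = character(0),
                                         extra = character(0)))))
}
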