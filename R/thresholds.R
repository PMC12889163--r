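#' Fixed-rule ("regular") thresholding
#'
#' Converts scored predictions to label sets with the fixed rule: each
#' protein always receives its top-scoring label (argmax, score ties broken
#' by the lexicographically smallest canonical EC string), plus every
#' additional label whose score is at least \code{tExtra}. This emulates the
#' fixed probability-based assignment rule that emits multiple EC numbers
#' when confidence is high.
#'
#' @param preds a [PredictionTable-class].
#' @param tExtra extra-label cutoff in [0,1] (default 0.5).
#' @return named list mapping protein to a character vector of EC labels.
#' @examples
#' pt <- PredictionTable(data.frame(protein_id = "P1",
#'                                  ec = c("1.1.1.1", "2.1.1.1"),
#'                                  score = c(0.9, 0.7)), "toy")
#' applyRegular(pt, 0.5)
#' @export
applyRegular <- function(preds, tExtra = 0.5) {
  stopifnot(is(preds, "PredictionTable"), tExtra >= 0, tExtra <= 1)
  e <- preds@entries
  if (nrow(e) == 0L) return(setNames(list(), character(0)))
  e <- e[order(e$protein_id, -e$score, e$ec), , drop = FALSE]
  isTop <- !duplicated(e$protein_id)
  keep <- isTop | e$score >= tExtra
  sets <- split(e$ec[keep], e$protein_id[keep])
  lapply(sets, function(s) sort(unique(s)))
}

#' Learn per-class F1-optimal thresholds
#'
#' For every EC class observed in the validation predictions, scans the
#' class's unique observed scores as candidate thresholds and keeps the one
#' maximizing that class's binary F1 on the validation truth (a label is
#' emitted when its score is greater than or equal to the threshold;
#' validation positives the model never scored count as false negatives at
#' every candidate). Ties choose the smallest candidate, favoring recall.
#' Classes with no validation positive are mapped to the NEVER sentinel and
#' are never emitted.
#'
#' @param validationTruth an [AnnotationTable-class].
#' @param validationPreds a [PredictionTable-class] with scores.
#' @param default threshold applied to classes not seen in validation
#'   (default 0.5).
#' @return a [ThresholdMap-class].
#' @export
learnThresholds <- function(validationTruth, validationPreds,
                            default = 0.5) {
  stopifnot(is(validationTruth, "AnnotationTable"),
            is(validationPreds, "PredictionTable"))
  if (length(validationTruth) == 0L) stop("empty validation set")
  te <- validationTruth@entries
  pe <- validationPreds@entries
  classes <- sort(unique(pe$ec))
  th <- vapply(classes, function(cls) {
    positives <- unique(te$protein_id[te$ec == cls])
    if (length(positives) == 0L) return(Inf)          # NEVER
    sub <- pe[pe$ec == cls, , drop = FALSE]
    isPos <- sub$protein_id %in% positives
    candidates <- sort(unique(sub$score))
    best <- candidates[1L]
    bestF1 <- -1
    for (t in candidates) {
      emit <- sub$score >= t
      tp <- sum(emit & isPos)
      fp <- sum(emit & !isPos)
      fn <- length(positives) - tp
      f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      if (f1 > bestF1) {   # strict improvement: ties keep smallest candidate
        bestF1 <- f1
        best <- t
      }
    }
    best
  }, numeric(1L))
  new("ThresholdMap", default = default, thresholds = setNames(th, classes))
}

#' Apply a per-class threshold map
#'
#' Emits a label iff its score is greater than or equal to its class
#' threshold (the map's default for classes without a learnt entry; the
#' NEVER sentinel suppresses the class regardless of score). A protein whose
#' every label is suppressed ends with no prediction and is absent from the
#' result, which drives the coverage denominator downstream.
#'
#' @param preds a [PredictionTable-class].
#' @param tm a [ThresholdMap-class].
#' @return named list mapping protein to a character vector of EC labels
#'   (proteins with empty result sets are dropped).
#' @export
applyThresholds <- function(preds, tm) {
  stopifnot(is(preds, "PredictionTable"), is(tm, "ThresholdMap"))
  e <- preds@entries
  if (nrow(e) == 0L) return(setNames(list(), character(0)))
  t <- tm@thresholds[e$ec]
  t[is.na(t)] <- tm@default
  keep <- e$score >= t
  sets <- split(e$ec[keep], e$protein_id[keep])
  .dropEmptySets(lapply(sets, function(s) sort(unique(s))))
}

setMethod("show", "ThresholdMap", function(object) {
  th <- object@thresholds
  cat("ThresholdMap:", length(th), "per-class thresholds (",
      sum(is.infinite(th)), "NEVER ), default", object@default, "\n")
})
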