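#' Hierarchical multi-label accuracy at one EC level
#'
#' Task 1 of the benchmark: model performance is evaluated at increasing
#' levels of EC specificity (1 through 4). Both the true and the predicted
#' label sets are truncated to \code{level} and de-duplicated per protein;
#' per-class binary confusion counts are computed one-vs-rest over the union
#' label space, and micro / macro / support-weighted precision, recall and
#' F1 are derived.
#'
#' Partial labels shallower than \code{level} carry no ground truth (or
#' prediction) there: such true labels are dropped, proteins whose every
#' true label is shallower than \code{level} are excluded from that level's
#' evaluation, and shallow predicted labels are likewise dropped. All 0/0
#' metric cells are defined as 0. Classes appearing only in predictions have
#' support 0: they get weight 0 in the weighted average but their false
#' positives still count in the micro aggregates.
#'
#' @param truth an [AnnotationTable-class] of ground-truth labels.
#' @param predicted named list mapping protein identifier to a character
#'   vector of predicted EC labels (as produced by [applyRegular()],
#'   [applyThresholds()] or [labelSets()]); an [AnnotationTable-class] is
#'   also accepted. Predictions for proteins absent from \code{truth} are
#'   ignored.
#' @param level integer in 1..4.
#' @return a [LevelMetrics-class].
#' @examples
#' truth <- AnnotationTable(list(P1 = "1.1.1.1", P2 = "2.3.1.4"))
#' pred <- list(P1 = "1.1.1.1", P2 = "2.3.1.5")
#' evaluateLevel(truth, pred, 4)@aggregates
#' @export
evaluateLevel <- function(truth, predicted, level) {
  stopifnot(is(truth, "AnnotationTable"), length(level) == 1L,
            level >= 1, level <= 4)
  level <- as.integer(level)
  if (length(truth) == 0L) stop("empty truth table")
  predicted <- .assertLabelSets(predicted)

  te <- truth@entries
  te <- te[ecDepth(te$ec) >= level, , drop = FALSE]
  keep <- unique(te$protein_id)   # proteins with >= 1 truth label at depth
  truthPairs <- unique(data.frame(protein_id = te$protein_id,
                                  class = ecTruncate(te$ec, level),
                                  stringsAsFactors = FALSE))
  predicted <- predicted[names(predicted) %in% keep]
  predPairs <- data.frame(
    protein_id = rep(names(predicted), lengths(predicted)),
    class = unlist(lapply(predicted, ecParse), use.names = FALSE) %||%
      character(0), stringsAsFactors = FALSE)
  if (nrow(predPairs)) {
    predPairs <- predPairs[ecDepth(predPairs$class) >= level, , drop = FALSE]
    predPairs$class <- ecTruncate(predPairs$class, level)
    predPairs <- unique(predPairs)
  }
  .levelMetricsFromPairs(truthPairs, predPairs, level, length(keep))
}

# confusion counting over (protein, class) pair sets
.levelMetricsFromPairs <- function(truthPairs, predPairs, level, nProteins) {
  classes <- sort(unique(c(truthPairs$class, predPairs$class)))
  tKey <- paste(truthPairs$protein_id, truthPairs$class, sep = "\r")
  pKey <- paste(predPairs$protein_id, predPairs$class, sep = "\r")
  tpPairs <- truthPairs[tKey %in% pKey, , drop = FALSE]
  tab <- function(df) {
    t <- table(factor(df$class, levels = classes))
    as.integer(t)
  }
  tp <- tab(tpPairs)
  fn <- tab(truthPairs) - tp
  fp <- tab(predPairs) - tp
  support <- tp + fn
  div0 <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  perClass <- data.frame(ec = classes, support = support, tp = tp, fp = fp,
                         fn = fn, precision = precision, recall = recall,
                         f1 = f1, stringsAsFactors = FALSE)
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  microP <- div0(TP, TP + FP)
  microR <- div0(TP, TP + FN)
  withSupp <- support > 0
  wmean <- function(x) if (sum(support) == 0) 0 else
    sum(x * support) / sum(support)
  mmean <- function(x) if (!any(withSupp)) 0 else mean(x[withSupp])
  agg <- c(
    micro_precision = microP, micro_recall = microR,
    micro_f1 = div0(2 * microP * microR, microP + microR),
    macro_precision = mmean(precision), macro_recall = mmean(recall),
    macro_f1 = mmean(f1),
    weighted_precision = wmean(precision), weighted_recall = wmean(recall),
    weighted_f1 = wmean(f1))
  if (nProteins == 0L) agg[] <- NA_real_
  new("LevelMetrics", level = level, perClass = perClass, aggregates = agg,
      nProteins = as.integer(nProteins))
}

setMethod("show", "LevelMetrics", function(object) {
  cat("LevelMetrics (EC level ", object@level, "): ", object@nProteins,
      " proteins, ", nrow(object@perClass), " classes\n", sep = "")
  a <- object@aggregates
  cat(sprintf("  weighted P/R/F1: %.4f / %.4f / %.4f\n",
              a["weighted_precision"], a["weighted_recall"],
              a["weighted_f1"]))
  cat(sprintf("  micro F1: %.4f   macro F1: %.4f\n",
              a["micro_f1"], a["macro_f1"]))
})

#' Batched evaluation: aggregate mean and standard deviation
#'
#' Shuffles the truth proteins with \code{seed}, splits them into
#' \code{nBatches} equal-sized non-overlapping subsets that together cover
#' the whole set (the first batches absorb the remainder: 468 proteins in 5
#' batches gives 94,94,94,93,93), runs [evaluateLevel()] on each subset, and
#' reports the mean and standard deviation of every aggregate metric.
#'
#' @inheritParams evaluateLevel
#' @param nBatches number of batches (>= 2; default 5).
#' @param seed integer seed for the shuffle.
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd}.
#' @export
evaluateBatched <- function(truth, predicted, level, nBatches = 5L,
                            seed = 17L) {
  stopifnot(nBatches >= 2L)
  predicted <- .assertLabelSets(predicted)
  batches <- .seededBatches(proteins(truth), nBatches, seed)
  per <- vapply(batches, function(ids) {
    lm <- evaluateLevel(truth[ids], predicted[names(predicted) %in% ids],
                        level)
    lm@aggregates
  }, numeric(9L))
  data.frame(metric = rownames(per),
             mean = apply(per, 1L, mean, na.rm = TRUE),
             sd = apply(per, 1L, stats::sd, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group evaluation (e.g. taxonomic domains)
#'
#' @inheritParams evaluateLevel
#' @param groups named character vector mapping protein identifier to a
#'   group label (e.g. Eukaryota / Bacteria); truth proteins without a group
#'   are evaluated under \code{"ungrouped"}.
#' @return named list of [LevelMetrics-class], one per group.
#' @export
evaluateByGroup <- function(truth, predicted, level, groups) {
  predicted <- .assertLabelSets(predicted)
  ids <- proteins(truth)
  g <- groups[ids]
  g[is.na(g)] <- "ungrouped"
  names(g) <- ids
  lapply(split(ids, g), function(sub)
    evaluateLevel(truth[sub], predicted[names(predicted) %in% sub], level))
}

#' Per-class metrics across all four EC levels (sunburst input)
#'
#' Runs [evaluateLevel()] at levels 1-4 and stacks the per-class tables.
#' The node set is the union of truncations of all true and predicted
#' labels; node F1 values equal the corresponding [evaluateLevel()]
#' per-class values. Levels at which no protein is evaluable are omitted.
#'
#' @inheritParams evaluateLevel
#' @return data.frame with columns \code{level, ec, support, tp, fp, fn,
#'   precision, recall, f1}.
#' @export
perClassTable <- function(truth, predicted) {
  predicted <- .assertLabelSets(predicted)
  out <- lapply(1:4, function(lv) {
    lm <- evaluateLevel(truth, predicted, lv)
    if (lm@nProteins == 0L) return(NULL)
    cbind(data.frame(level = lv), lm@perClass)
  })
  do.call(rbind, out)
}
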