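#' Enumerate incomplete annotation entries
#'
#' Partially annotated enzymes carry dashes in place of the unknown EC
#' levels (e.g. \code{1.1.-.-}). Each (protein, partial label) pair with
#' depth < 4 is one completion entry.
#'
#' @param truth an [AnnotationTable-class].
#' @return data.frame with columns \code{protein_id}, \code{partial_ec}.
#' @export
findIncomplete <- function(truth) {
  stopifnot(is(truth, "AnnotationTable"))
  e <- truth@entries
  e <- e[ecDepth(e$ec) < 4L, , drop = FALSE]
  data.frame(protein_id = e$protein_id, partial_ec = e$ec,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Inter-model agreement on EC-number completion
#'
#' For every completion entry each model contributes its top prediction for
#' the protein (an abstaining model counts as a distinct non-matching vote).
#' A majority label exists iff some label's vote count strictly exceeds half
#' the number of models being compared (so a 2-2 split of 4 models has no
#' majority). The agreement rate is the fraction of entries with a majority;
#' the per-model agreement count is the number of entries where the model's
#' top equals the majority label. With \code{denominator = "voters"} the
#' strict-majority bar is half the models that actually predicted for the
#' protein instead of all models.
#'
#' Because the task is called completion but scored purely by consensus, the
#' fraction of each model's tops that actually extend the partial prefix is
#' reported separately as \code{prefixConsistency}.
#'
#' @param models list of at least three [PredictionTable-class] objects.
#' @param entries data.frame from [findIncomplete()] (or compatible, columns
#'   \code{protein_id}, \code{partial_ec}).
#' @param denominator \code{"all"} (default) or \code{"voters"}.
#' @param nBatches if not NULL, entries are shuffled with \code{seed} and
#'   split into this many equal-sized non-overlapping batches; per-model
#'   agreement counts are then also reported as mean and sd over batches.
#' @param seed integer seed for batching.
#' @return an [AgreementResult-class].
#' @export
agreementRateEval <- function(models, entries, denominator = c("all", "voters"),
                              nBatches = NULL, seed = 17L) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(models), length(models) >= 3L,
            all(vapply(models, is, TRUE, "PredictionTable")))
  if (nrow(entries) == 0L) stop("no incomplete entries to evaluate")
  modelNames <- vapply(models, modelName, "")
  if (anyDuplicated(modelNames)) stop("model names must be unique")
  ids <- unique(entries$protein_id)
  tops <- vapply(models, topPrediction, character(length(ids)),
                 proteinIds = ids)
  tops <- matrix(tops, nrow = length(ids),
                 dimnames = list(ids, modelNames))

  majority <- vapply(entries$protein_id, function(p) {
    votes <- tops[p, ]
    cast <- votes[!is.na(votes)]
    if (length(cast) == 0L) return(NA_character_)
    bar <- if (denominator == "all") length(models) / 2 else length(cast) / 2
    counts <- table(cast)
    top <- counts[which.max(counts)]
    if (as.integer(top) > bar) names(top) else NA_character_
  }, character(1L), USE.NAMES = FALSE)

  perEntry <- data.frame(entries[c("protein_id", "partial_ec")],
                         majority_ec = majority,
                         tops[entries$protein_id, , drop = FALSE],
                         row.names = NULL, check.names = FALSE,
                         stringsAsFactors = FALSE)
  agree <- !is.na(majority)
  counts <- vapply(modelNames, function(m) {
    sum(agree & tops[entries$protein_id, m] == majority, na.rm = TRUE)
  }, integer(1L))
  prefixCons <- vapply(modelNames, function(m) {
    t <- tops[entries$protein_id, m]
    cast <- !is.na(t)
    if (!any(cast)) return(NA_real_)
    mean(ecCompletes(t[cast], entries$partial_ec[cast]))
  }, numeric(1L))

  batchStats <- data.frame(model = character(0), mean = numeric(0),
                           sd = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(nBatches)) {
    idx <- .seededBatches(seq_len(nrow(entries)), nBatches, seed)
    perBatch <- vapply(idx, function(i) {
      vapply(modelNames, function(m) {
        sum(agree[i] & tops[entries$protein_id[i], m] == majority[i],
            na.rm = TRUE)
      }, integer(1L))
    }, integer(length(modelNames)))
    perBatch <- matrix(perBatch, nrow = length(modelNames),
                       dimnames = list(modelNames, NULL))
    batchStats <- data.frame(model = modelNames,
                             mean = apply(perBatch, 1L, mean),
                             sd = apply(perBatch, 1L, stats::sd),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  new("AgreementResult", perEntry = perEntry,
      agreementRate = mean(agree),
      perModelCount = counts,
      prefixConsistency = prefixCons,
      batchStats = batchStats)
}

setMethod("show", "AgreementResult", function(object) {
  cat("AgreementResult:", nrow(object@perEntry), "entries, agreement rate",
      sprintf("%.4f", object@agreementRate), "\n")
  print(object@perModelCount)
})

#' Validate agreement as a confidence proxy on completely annotated proteins
#'
#' Runs the majority-agreement machinery on proteins whose every true label
#' is complete (depth 4), pairs each model's agreement count with its
#' weighted F1 at \code{level} from the exact-prediction task, and reports
#' the Pearson product-moment correlation between the two with its
#' two-sided t-test p-value. A strong positive correlation justifies using
#' majority agreement as a confidence measure when true completions are
#' unknown. Zero variance in either variable leaves r undefined (NA).
#'
#' @param models list of at least three [PredictionTable-class] objects.
#' @param completeTruth an [AnnotationTable-class]; only proteins with all
#'   labels at depth 4 are used (at least 3 required).
#' @param level EC level for the F1 computation (default 4).
#' @return list with \code{perModel} (data.frame model, agreement_count,
#'   f1), \code{r}, and \code{p}.
#' @export
validateAgreement <- function(models, completeTruth, level = 4L) {
  stopifnot(length(models) >= 3L, is(completeTruth, "AnnotationTable"))
  sets <- labelSets(completeTruth)
  ids <- names(sets)[vapply(sets, function(s) all(ecDepth(s) == 4L), TRUE)]
  if (length(ids) < 3L) stop("need >= 3 completely annotated proteins")
  truth <- completeTruth[ids]
  entries <- data.frame(protein_id = ids, partial_ec = "-.-.-.-",
                        stringsAsFactors = FALSE)
  agr <- agreementRateEval(models, entries)
  perModel <- data.frame(
    model = names(agr@perModelCount),
    agreement_count = as.integer(agr@perModelCount),
    f1 = vapply(models, function(m) {
      top <- topPrediction(m, ids)
      sets <- as.list(top[!is.na(top)])
      evaluateLevel(truth, sets, level)@aggregates[["weighted_f1"]]
    }, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (stats::sd(perModel$agreement_count) == 0 ||
      stats::sd(perModel$f1) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(perModel$agreement_count, perModel$f1,
                          method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(perModel = perModel, r = r, p = p)
}
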