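#' @import methods
NULL

#' AnnotationTable: ground-truth EC annotations
#'
#' Maps protein identifiers to non-empty sets of EC labels (multi-label,
#' partial labels allowed). Stored long-form as a two-column data.frame with
#' one row per (protein, label) pair; labels are canonical strings.
#'
#' @slot entries data.frame with columns \code{protein_id}, \code{ec};
#'   (protein, label) pairs unique, every protein has at least one label.
#' @seealso [AnnotationTable()], [readAnnotations()]
#' @export
setClass("AnnotationTable", representation(entries = "data.frame"))

setValidity("AnnotationTable", function(object) {
  e <- object@entries
  if (!all(c("protein_id", "ec") %in% names(e)))
    return("entries must have columns protein_id, ec")
  if (nrow(e) > 0L) {
    if (anyDuplicated(paste(e$protein_id, e$ec, sep = "\r")))
      return("duplicate (protein, ec) pairs")
    chk <- tryCatch(ecParse(e$ec), error = function(err) err)
    if (inherits(chk, "error")) return(conditionMessage(chk))
    if (!identical(chk, e$ec))
      return("ec labels must be canonical (use ecParse)")
  }
  TRUE
})

#' PredictionTable: one model's scored EC predictions
#'
#' @slot modelName single string naming the model.
#' @slot entries data.frame with columns \code{protein_id}, \code{ec},
#'   \code{score}; scores in [0,1]; at most one row per (protein, label).
#'   Proteins with no prediction are simply absent.
#' @seealso [PredictionTable()], [readPredictions()]
#' @export
setClass("PredictionTable",
         representation(modelName = "character", entries = "data.frame"))

setValidity("PredictionTable", function(object) {
  if (length(object@modelName) != 1L) return("modelName must be one string")
  e <- object@entries
  if (!all(c("protein_id", "ec", "score") %in% names(e)))
    return("entries must have columns protein_id, ec, score")
  if (nrow(e) > 0L) {
    if (any(e$score < 0 | e$score > 1 | is.na(e$score)))
      return("scores must lie in [0,1]")
    if (anyDuplicated(paste(e$protein_id, e$ec, sep = "\r")))
      return("duplicate (protein, ec) pairs")
    if (!identical(ecParse(e$ec), e$ec))
      return("ec labels must be canonical (use ecParse)")
  }
  TRUE
})

#' ReactionTable: EC numbers mapped to reactions with cached fingerprints
#'
#' Each complete (depth-4) EC label maps to one or more reaction strings in
#' \code{"reactants>>products"} notation (molecules \code{.}-separated).
#' Fingerprints are computed once at construction and cached; they are
#' deterministic given the reaction string and the backend.
#'
#' @slot entries data.frame with columns \code{ec}, \code{reaction}.
#' @slot fingerprints list of sorted integer vectors (set-bit indices),
#'   parallel to \code{entries} rows.
#' @slot backend single string naming the fingerprint backend.
#' @seealso [ReactionTable()], [reactionSimilarity()]
#' @export
setClass("ReactionTable",
         representation(entries = "data.frame", fingerprints = "list",
                        backend = "character"))

setValidity("ReactionTable", function(object) {
  e <- object@entries
  if (!all(c("ec", "reaction") %in% names(e)))
    return("entries must have columns ec, reaction")
  if (nrow(e) != length(object@fingerprints))
    return("one cached fingerprint per reaction record required")
  if (nrow(e) > 0L && any(ecDepth(e$ec) != 4L))
    return("reaction table keys must be complete (depth-4) EC labels")
  TRUE
})

#' ThresholdMap: per-class decision thresholds
#'
#' Scores at or above the class threshold are emitted (inclusive comparison).
#' Classes absent from \code{thresholds} use \code{default}; a threshold of
#' \code{Inf} is the NEVER sentinel — the class is never emitted regardless
#' of score (serialized as \code{"NEVER"}).
#'
#' @slot default single numeric in [0,1] used for unseen classes.
#' @slot thresholds named numeric vector (names are canonical EC labels);
#'   values in [0,1] or \code{Inf}.
#' @seealso [learnThresholds()], [applyThresholds()]
#' @export
setClass("ThresholdMap",
         representation(default = "numeric", thresholds = "numeric"))

setValidity("ThresholdMap", function(object) {
  if (length(object@default) != 1L ||
      object@default < 0 || object@default > 1)
    return("default threshold must be a single value in [0,1]")
  th <- object@thresholds
  if (length(th) > 0L) {
    if (is.null(names(th)) || any(names(th) == ""))
      return("per-class thresholds must be named by EC label")
    if (any(is.na(th) | (th != Inf & (th < 0 | th > 1))))
      return("thresholds must lie in [0,1] or be Inf (NEVER)")
  }
  TRUE
})

#' StackerModel: fitted stacking ensemble
#'
#' Base models' scores over a shared label space are concatenated into a
#' feature vector per protein; a one-vs-rest ridge-penalized logistic
#' regression per output class is the meta-model.
#'
#' @slot labelSpace ordered character vector of feature labels (shared label
#'   space; each base model owns one contiguous slice of the feature vector).
#' @slot outputLabels character vector of classes the stacker can emit
#'   (classes seen in validation truth).
#' @slot baseModels character vector of base model names, in feature order.
#' @slot fits list of per-output-class fitted parameters (opaque).
#' @slot seed integer seed recorded at fit time.
#' @seealso [fitStacker()], [applyStacker()]
#' @export
setClass("StackerModel",
         representation(labelSpace = "character", outputLabels = "character",
                        baseModels = "character", fits = "list",
                        seed = "integer"))

#' LevelMetrics: per-class and aggregate metrics at one EC level
#'
#' @slot level integer 1..4.
#' @slot perClass data.frame keyed by truncated EC label with columns
#'   \code{ec, support, tp, fp, fn, precision, recall, f1}. 0/0 metric cells
#'   are defined as 0.
#' @slot aggregates named numeric: \code{micro_/macro_/weighted_} x
#'   \code{precision/recall/f1}. Micro derives from summed counts; macro is
#'   the unweighted mean over classes with support > 0; weighted weights by
#'   true support.
#' @slot nProteins number of proteins evaluated at this level.
#' @seealso [evaluateLevel()]
#' @export
setClass("LevelMetrics",
         representation(level = "integer", perClass = "data.frame",
                        aggregates = "numeric", nProteins = "integer"))

#' AgreementResult: inter-model agreement on EC completion entries
#'
#' @slot perEntry data.frame: one row per (protein, partial EC) entry with
#'   the majority label (or NA when no label gets strictly more than half of
#'   the votes) and each model's top prediction.
#' @slot agreementRate fraction of entries with a majority.
#' @slot perModelCount named integer: entries in which each model's top
#'   equals the majority label.
#' @slot prefixConsistency named numeric: per model, fraction of its
#'   non-abstaining tops that complete the partial prefix.
#' @slot batchStats data.frame of per-model mean and sd of agreement counts
#'   over seeded batches (zero rows when batching is off).
#' @seealso [agreementRateEval()]
#' @export
setClass("AgreementResult",
         representation(perEntry = "data.frame", agreementRate = "numeric",
                        perModelCount = "integer",
                        prefixConsistency = "numeric",
                        batchStats = "data.frame"))

#' SimilarityReport: reaction-similarity scoring of one model's predictions
#'
#' Holds the three aggregate quantities of the recommendation task: coverage
#' (percentage of truth proteins with at least one prediction), average
#' similarity (mean best-pair reaction similarity over predicted proteins),
#' and weighted similarity = average x coverage/100.
#'
#' @slot model single string.
#' @slot coverage percentage in [0,100].
#' @slot averageSimilarity fraction in [0,1] (NA when nothing is predicted).
#' @slot weightedSimilarity fraction in [0,1] (0 when nothing is predicted).
#' @slot perProtein named numeric of best-pair similarities.
#' @seealso [similarityReport()]
#' @export
setClass("SimilarityReport",
         representation(model = "character", coverage = "numeric",
                        averageSimilarity = "numeric",
                        weightedSimilarity = "numeric",
                        perProtein = "numeric"))

setValidity("SimilarityReport", function(object) {
  w <- object@weightedSimilarity
  if (object@coverage < 0 || object@coverage > 100)
    return("coverage must be a percentage in [0,100]")
  expected <- if (is.na(object@averageSimilarity)) 0 else
    object@averageSimilarity * object@coverage / 100
  if (abs(w - expected) > 1e-12)
    return("weightedSimilarity must equal averageSimilarity * coverage/100")
  TRUE
})
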