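#' Majority-voting ensemble
#'
#' Each base model casts its top prediction per protein as one vote
#' (abstaining models cast none). Every modal label — all labels tied at the
#' maximum vote count — is emitted, so voting ties yield multiple labels,
#' each scored \code{count / n} where \code{n} is by default the number of
#' models that voted for that protein (\code{denominator = "voters"});
#' set \code{denominator = "all"} to divide by the total number of base
#' models instead.
#'
#' @param base list of at least two [PredictionTable-class] objects.
#' @param denominator \code{"voters"} (default) or \code{"all"}.
#' @return a [PredictionTable-class] named \code{"majority_vote"}.
#' @examples
#' one <- function(m, ec) PredictionTable(
#'   data.frame(protein_id = "P1", ec = ec, score = 1), m)
#' tableEntries(majorityVote(list(one("a", "1.1.1.1"), one("b", "1.1.1.1"),
#'                                one("c", "2.1.1.1"))))
#' @export
majorityVote <- function(base, denominator = c("voters", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(base), length(base) >= 2L,
            all(vapply(base, is, TRUE, "PredictionTable")))
  allProteins <- unique(unlist(lapply(base, proteins)))
  tops <- vapply(base, topPrediction, character(length(allProteins)),
                 proteinIds = allProteins)
  tops <- matrix(tops, nrow = length(allProteins),
                 dimnames = list(allProteins, NULL))
  rows <- lapply(allProteins, function(p) {
    votes <- tops[p, ]
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0L) return(NULL)
    counts <- table(votes)
    modal <- names(counts)[counts == max(counts)]
    n <- if (denominator == "voters") length(votes) else length(base)
    data.frame(protein_id = p, ec = modal,
               score = as.numeric(counts[modal]) / n,
               stringsAsFactors = FALSE)
  })
  PredictionTable(do.call(rbind, c(rows, list(
    data.frame(protein_id = character(0), ec = character(0),
               score = numeric(0))))), "majority_vote")
}

#' Fit a stacking ensemble
#'
#' Concatenates each base model's score vector over the shared label space
#' (the union of labels any base model predicted on validation; missing
#' scores imputed as 0) into one feature vector per validation protein, and
#' fits a one-vs-rest ridge-penalized logistic regression per output class
#' (classes observed in the validation truth). Deterministic given the seed
#' and inputs. Classes whose validation response is constant are fit as
#' intercept-only prevalence models, so a stacker trained on all-abstaining
#' base models falls back to the validation majority class.
#'
#' @param baseOnValidation list of [PredictionTable-class] objects scored on
#'   the validation proteins.
#' @param validationTruth an [AnnotationTable-class].
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @param lambda ridge penalty (default 0.001; light regularization keeps
#'   the fit deterministic on separable features without drowning rare
#'   classes below the majority-class base rate).
#' @return a [StackerModel-class].
#' @export
fitStacker <- function(baseOnValidation, validationTruth, seed = 17L,
                       lambda = 0.001) {
  stopifnot(is.list(baseOnValidation), length(baseOnValidation) >= 1L,
            all(vapply(baseOnValidation, is, TRUE, "PredictionTable")),
            is(validationTruth, "AnnotationTable"))
  if (length(validationTruth) == 0L) stop("empty validation truth")
  labelSpace <- sort(unique(unlist(
    lapply(baseOnValidation, function(p) p@entries$ec))))
  if (length(labelSpace) == 0L) stop("empty feature space (no predictions)")
  baseNames <- vapply(baseOnValidation, modelName, "")
  if (anyDuplicated(baseNames)) stop("base model names must be unique")
  ids <- proteins(validationTruth)
  X <- .stackerFeatures(baseOnValidation, labelSpace, ids)
  outputLabels <- sort(unique(validationTruth@entries$ec))
  te <- validationTruth@entries
  fits <- .withSeed(seed, lapply(outputLabels, function(cls) {
    y <- as.integer(ids %in% te$protein_id[te$ec == cls])
    .fitRidgeLogit(X, y, lambda)
  }))
  names(fits) <- outputLabels
  new("StackerModel", labelSpace = labelSpace, outputLabels = outputLabels,
      baseModels = baseNames, fits = fits, seed = as.integer(seed))
}

# features: one column per (base model, label-space label), scores imputed 0
.stackerFeatures <- function(base, labelSpace, ids) {
  blocks <- lapply(base, function(pt) {
    m <- matrix(0, nrow = length(ids), ncol = length(labelSpace),
                dimnames = list(ids, labelSpace))
    e <- pt@entries
    e <- e[e$protein_id %in% ids & e$ec %in% labelSpace, , drop = FALSE]
    if (nrow(e))
      m[cbind(match(e$protein_id, ids), match(e$ec, labelSpace))] <- e$score
    m
  })
  do.call(cbind, blocks)
}

# ridge logistic via glmnet; constant responses become intercept-only and
# classes too small for glmnet (fewer than 2 members on either side) use a
# ridge IRLS fit with the same penalty
.fitRidgeLogit <- function(X, y, lambda) {
  if (length(unique(y)) < 2L)
    return(list(kind = "const", p = mean(y)))
  if (min(table(y)) < 2L) {
    fit <- .ridgeLogitIRLS(X, y, lambda * nrow(X))
    return(list(kind = "glmnet", intercept = fit$intercept,
                beta = fit$beta))
  }
  Xfit <- if (ncol(X) < 2L) cbind(X, 0) else X   # glmnet needs >= 2 columns
  # fit down a decreasing lambda path: coordinate descent needs the warm
  # starts to converge at light penalties on separable one-hot features
  path <- if (lambda >= 0.5) lambda else
    exp(seq(log(0.5), log(lambda), length.out = 20L))
  # rare classes are inherent to long-tailed EC label spaces: silence
  # glmnet's small-class advisory, keep everything else
  fit <- withCallingHandlers(
    glmnet::glmnet(Xfit, y, family = "binomial", alpha = 0,
                   lambda = path, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  k <- length(fit$lambda)   # last fitted value == target lambda
  list(kind = "glmnet",
       intercept = as.numeric(fit$a0[k]),
       beta = as.numeric(fit$beta[seq_len(ncol(X)), k]))
}

# Newton/IRLS for logistic regression with an L2 penalty on the slopes
# (intercept unpenalized); deterministic
.ridgeLogitIRLS <- function(X, y, penalty, maxIter = 50L, tol = 1e-10) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(penalty, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxIter)) {
    eta <- as.numeric(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Xi, y - mu) - pen %*% beta
    hess <- crossprod(Xi * w, Xi) + pen
    step <- solve(hess, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1L], beta = beta[-1L])
}

#' Apply a fitted stacker to base predictions on test proteins
#'
#' Base tables are matched to the training layout by model name (order may
#' differ); a missing or extra base model is an error. Output scores cover
#' the classes seen in validation truth — labels unseen at fit time are
#' never emitted.
#'
#' @param model a [StackerModel-class].
#' @param baseOnTest list of [PredictionTable-class] objects, one per base
#'   model used at fit time.
#' @return a [PredictionTable-class] named \code{"stacker"}.
#' @export
applyStacker <- function(model, baseOnTest) {
  stopifnot(is(model, "StackerModel"), is.list(baseOnTest))
  testNames <- vapply(baseOnTest, modelName, "")
  idx <- match(model@baseModels, testNames)
  if (anyNA(idx))
    stop("base model mismatch: missing ",
         paste(model@baseModels[is.na(idx)], collapse = ", "))
  baseOnTest <- baseOnTest[idx]
  ids <- unique(unlist(lapply(baseOnTest, proteins)))
  if (length(ids) == 0L)
    return(PredictionTable(data.frame(protein_id = character(0),
                                      ec = character(0), score = numeric(0)),
                           "stacker"))
  X <- .stackerFeatures(baseOnTest, model@labelSpace, ids)
  rows <- lapply(seq_along(model@fits), function(k) {
    fit <- model@fits[[k]]
    p <- if (identical(fit$kind, "const")) rep(fit$p, nrow(X)) else
      stats::plogis(fit$intercept + as.numeric(X %*% fit$beta))
    data.frame(protein_id = ids, ec = model@outputLabels[k], score = p,
               stringsAsFactors = FALSE)
  })
  PredictionTable(do.call(rbind, rows), "stacker")
}

setMethod("show", "StackerModel", function(object) {
  cat("StackerModel:", length(object@baseModels), "base models x",
      length(object@labelSpace), "feature labels ->",
      length(object@outputLabels), "output classes (seed",
      object@seed, ")\n")
})
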