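#' Specification for the synthetic fixture generator
#'
#' The generator emulates every input the evaluation tasks consume: a
#' hierarchical EC label space, multi-label enzymes, partial ("dash")
#' annotations, per-model accuracy/coverage profiles with calibration-noisy
#' scores, random protein sequences, and family-structured toy reaction
#' tables. Everything is deterministic given \code{seed}.
#'
#' @param nProteins number of proteins.
#' @param hierarchyShape integer vector of children per EC level; the
#'   default 4 x 3 x 3 x 4 tree has 144 complete labels.
#' @param multiLabelRate probability a protein carries a second, distinct
#'   EC label (multi-function enzymes).
#' @param incompleteRate probability a truth label is truncated to a random
#'   depth 1-3 (partial annotation).
#' @param modelProfiles list of model profiles; each a list with
#'   \code{name}, \code{coverage} (fraction of proteins predicted),
#'   \code{accuracy} (length-4 vector: probability the predicted label is
#'   correct at each level; errors are drawn from siblings at the deepest
#'   erred level), and \code{noise} (half-width of the uniform score
#'   calibration noise, default 0.1). The default set of five profiles
#'   spans strong to weak predictors with varied coverage, mimicking the
#'   performance spread of real EC predictors.
#' @param reactionFamilyNoise fraction of reaction tokens mutated between
#'   sibling (same three-level family) ECs in the toy reaction table.
#' @param heldOutFraction fraction of complete ECs left out of the reaction
#'   table, to exercise the sibling-sampling fallback.
#' @param seed integer seed.
#' @return a validated spec (list) for [generateTruth()],
#'   [generatePredictions()] and [generateReactionTable()].
#' @export
syntheticSpec <- function(nProteins = 500L,
                          hierarchyShape = c(4L, 3L, 3L, 4L),
                          multiLabelRate = 0.1,
                          incompleteRate = 0.15,
                          modelProfiles = NULL,
                          reactionFamilyNoise = 0.2,
                          heldOutFraction = 0.1,
                          seed = 17L) {
  if (is.null(modelProfiles))
    modelProfiles <- list(
      list(name = "alpha", coverage = 0.95,
           accuracy = c(0.95, 0.90, 0.85, 0.80), noise = 0.1),
      list(name = "bravo", coverage = 0.90,
           accuracy = c(0.90, 0.82, 0.74, 0.66), noise = 0.1),
      list(name = "charlie", coverage = 0.75,
           accuracy = c(0.85, 0.75, 0.65, 0.55), noise = 0.1),
      list(name = "delta", coverage = 0.60,
           accuracy = c(0.75, 0.62, 0.50, 0.40), noise = 0.1),
      list(name = "echo", coverage = 0.50,
           accuracy = c(0.60, 0.45, 0.35, 0.25), noise = 0.1))
  spec <- list(nProteins = as.integer(nProteins),
               hierarchyShape = as.integer(hierarchyShape),
               multiLabelRate = multiLabelRate,
               incompleteRate = incompleteRate,
               modelProfiles = modelProfiles,
               reactionFamilyNoise = reactionFamilyNoise,
               heldOutFraction = heldOutFraction,
               seed = as.integer(seed))
  stopifnot(spec$nProteins >= 1L, length(spec$hierarchyShape) == 4L,
            all(spec$hierarchyShape >= 1L),
            multiLabelRate >= 0, multiLabelRate <= 1,
            incompleteRate >= 0, incompleteRate <= 1,
            reactionFamilyNoise >= 0, reactionFamilyNoise <= 1,
            heldOutFraction >= 0, heldOutFraction <= 1)
  for (p in spec$modelProfiles)
    stopifnot(!is.null(p$name), p$coverage >= 0, p$coverage <= 1,
              length(p$accuracy) == 4L,
              all(p$accuracy >= 0 & p$accuracy <= 1))
  spec
}

# all complete labels of the toy hierarchy, in lexicographic tree order
.hierarchyLeaves <- function(shape) {
  g <- expand.grid(l4 = seq_len(shape[4]), l3 = seq_len(shape[3]),
                   l2 = seq_len(shape[2]), l1 = seq_len(shape[1]))
  paste(g$l1, g$l2, g$l3, g$l4, sep = ".")
}

# long-tailed leaf weights: geometric choice at each level of the tree
.leafWeights <- function(shape, rate = 0.6) {
  w <- function(n) {
    v <- rate ^ (seq_len(n) - 1L)
    v / sum(v)
  }
  g <- expand.grid(l4 = w(shape[4]), l3 = w(shape[3]), l2 = w(shape[2]),
                   l1 = w(shape[1]))
  g$l1 * g$l2 * g$l3 * g$l4
}

#' Generate synthetic ground truth
#'
#' Draws \code{nProteins} random amino-acid sequences (length 80-400) and
#' assigns each one complete EC label from the toy hierarchy with
#' long-tailed (geometric) frequencies, plus a second distinct label with
#' probability \code{multiLabelRate}. Each label is independently truncated
#' to a random depth 1-3 with probability \code{incompleteRate}.
#'
#' @param spec a [syntheticSpec()].
#' @return list with \code{seqs} (AAStringSet), \code{annots}
#'   ([AnnotationTable-class], possibly partial labels), and \code{leaves}
#'   (named list of the underlying complete labels per protein, used by
#'   [generatePredictions()] as the designed targets).
#' @export
generateTruth <- function(spec) {
  leaves <- .hierarchyLeaves(spec$hierarchyShape)
  if (length(leaves) < 2L) stop("degenerate hierarchy: need >= 2 leaves")
  wts <- .leafWeights(spec$hierarchyShape)
  .withSeed(.deriveSeed(spec$seed, "truth"), {
    ids <- sprintf("P%05d", seq_len(spec$nProteins))
    seqs <- vapply(ids, function(i) paste(
      sample(Biostrings::AA_STANDARD, sample(80:400, 1L), replace = TRUE),
      collapse = ""), "")
    primary <- sample(leaves, spec$nProteins, replace = TRUE, prob = wts)
    trueSets <- lapply(seq_len(spec$nProteins), function(i) {
      labs <- primary[i]
      if (stats::runif(1) < spec$multiLabelRate) {
        extra <- sample(leaves, 1L, prob = wts)
        while (extra == labs[1L]) extra <- sample(leaves, 1L, prob = wts)
        labs <- c(labs, extra)
      }
      labs
    })
    names(trueSets) <- ids
    annotSets <- lapply(trueSets, function(labs) {
      unique(vapply(labs, function(l)
        if (stats::runif(1) < spec$incompleteRate)
          ecTruncate(l, sample(1:3, 1L)) else l, "", USE.NAMES = FALSE))
    })
    list(seqs = Biostrings::AAStringSet(setNames(seqs, ids)),
         annots = AnnotationTable(annotSets),
         leaves = trueSets)
  })
}

#' Generate scored predictions for each synthetic model profile
#'
#' For each profile, a \code{coverage} fraction of proteins (independent
#' Bernoulli draws) receives one scored prediction targeting the protein's
#' primary complete label. A single uniform draw decides the deepest
#' correct level: with non-increasing designed accuracies
#' \eqn{a_1 \ge \dots \ge a_4}, the emitted label is correct at level k
#' with probability exactly \eqn{a_k}. At the first erred level a different
#' sibling token is drawn (errors stay within the parent's subtree), and
#' deeper tokens are drawn uniformly, so hierarchical metrics degrade
#' gracefully with depth. Scores are the designed probability that the
#' emitted label is fully correct (\eqn{a_4} for correct emissions,
#' \eqn{1-a_4} otherwise) plus uniform calibration noise, clipped to [0,1].
#'
#' @param spec a [syntheticSpec()].
#' @param truth the list returned by [generateTruth()].
#' @return list of [PredictionTable-class], one per model profile.
#' @export
generatePredictions <- function(spec, truth) {
  shape <- spec$hierarchyShape
  ids <- names(truth$leaves)
  lapply(spec$modelProfiles, function(profile) {
    acc <- cummin(profile$accuracy)   # nested correctness needs monotone acc
    noise <- profile$noise %||% 0.1
    .withSeed(.deriveSeed(spec$seed, paste0("model:", profile$name)), {
      covered <- ids[stats::runif(length(ids)) < profile$coverage]
      rows <- lapply(covered, function(p) {
        target <- as.integer(strsplit(truth$leaves[[p]][1L], ".",
                                      fixed = TRUE)[[1L]])
        u <- stats::runif(1)
        tok <- target
        erred <- FALSE
        for (k in 1:4) {
          if (!erred && u <= acc[k]) next
          if (!erred) {              # first erred level: a different sibling
            if (shape[k] > 1L) {
              others <- setdiff(seq_len(shape[k]), target[k])
              tok[k] <- if (length(others) == 1L) others else sample(others, 1L)
              erred <- TRUE
            }
          } else tok[k] <- sample.int(shape[k], 1L)
        }
        correct <- all(tok == target)
        p0 <- if (correct) acc[4] else 1 - acc[4]
        score <- min(1, max(0, p0 + stats::runif(1, -noise, noise)))
        data.frame(protein_id = p, ec = paste(tok, collapse = "."),
                   score = score, stringsAsFactors = FALSE)
      })
      PredictionTable(do.call(rbind, c(rows, list(
        data.frame(protein_id = character(0), ec = character(0),
                   score = numeric(0))))), profile$name)
    })
  })
}

#' Generate a family-structured toy reaction table
#'
#' Builds one base reaction per three-level EC family from a vocabulary of
#' simple valid SMILES tokens (two reactant and two product molecules of
#' six tokens each); each complete (level-4) child EC mutates a
#' \code{reactionFamilyNoise} fraction of the tokens. Reactions within a
#' family are therefore near-identical while unrelated families share only
#' coincidental tokens — the planted structure the recommendation task
#' assumes. A \code{heldOutFraction} of complete ECs is omitted from the
#' table to exercise the sibling-sampling fallback.
#'
#' @param spec a [syntheticSpec()].
#' @return a [ReactionTable-class].
#' @export
generateReactionTable <- function(spec) {
  shape <- spec$hierarchyShape
  vocab <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "CC", "CO", "C=O",
             "C#N", "CN", "c1ccccc1", "C(=O)O", "OP(=O)(O)O")
  leaves <- .hierarchyLeaves(shape)
  families <- unique(ecTruncate(leaves, 3L))
  .withSeed(.deriveSeed(spec$seed, "reactions"), {
    baseTokens <- lapply(families, function(f)
      sample(vocab, 24L, replace = TRUE))
    names(baseTokens) <- families
    held <- if (spec$heldOutFraction > 0)
      sample(leaves, floor(spec$heldOutFraction * length(leaves)))
    else character(0)
    kept <- setdiff(leaves, held)
    rows <- lapply(kept, function(ec) {
      toks <- baseTokens[[ecTruncate(ec, 3L)]]
      nMut <- round(spec$reactionFamilyNoise * length(toks))
      if (nMut > 0L) {
        pos <- sample(seq_along(toks), nMut)
        toks[pos] <- sample(vocab, nMut, replace = TRUE)
      }
      mol <- function(i) paste(toks[(6 * i - 5):(6 * i)], collapse = "")
      data.frame(ec = ec,
                 reaction = paste0(mol(1), ".", mol(2), ">>",
                                   mol(3), ".", mol(4)),
                 stringsAsFactors = FALSE)
    })
    ReactionTable(do.call(rbind, rows))
  })
}

#' Write a full synthetic fixture set to disk
#'
#' Emits \code{truth.tsv}, \code{seqs.fasta}, \code{reactions.tsv} and one
#' \code{model_<name>.tsv} per profile, all re-readable by the package's
#' readers.
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of written paths.
#' @export
writeSyntheticFixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generateTruth(spec)
  preds <- generatePredictions(spec, truth)
  paths <- list(truth = file.path(dir, "truth.tsv"),
                seqs = file.path(dir, "seqs.fasta"),
                reactions = file.path(dir, "reactions.tsv"))
  writeAnnotations(truth$annots, paths$truth)
  writeFasta(truth$seqs, paths$seqs)
  writeReactionTable(generateReactionTable(spec), paths$reactions)
  for (pt in preds) {
    f <- file.path(dir, paste0("model_", modelName(pt), ".tsv"))
    writePredictions(pt, f)
    paths[[paste0("model_", modelName(pt))]] <- f
  }
  invisible(paths)
}
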