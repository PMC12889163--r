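#' Task runners: evaluate, complete, recommend, ensemble, curate,
#' simulate, compare
#'
#' Each runner takes a configuration (a named list, or the path of a YAML
#' file with the same keys), executes one evaluation task end to end with
#' the package's functions, and writes its outputs plus a JSON manifest
#' (inputs with md5 hashes, package version, seed, and an efficiency record
#' with wall time, peak memory and output sizes) into \code{config$out}.
#' On error, partially written outputs are removed and the error is
#' re-thrown. Runs are reproducible from the manifest alone: the same
#' config and seed give byte-identical reports (manifests differ only in
#' timestamps and timings).
#'
#' Common keys: \code{out} (output directory), \code{seed} (default 17),
#' \code{truth} (annotation TSV), \code{predictions} (named list
#' model -> prediction TSV), \code{thresholds} ("regular" or "learnt"),
#' \code{t_extra} (default 0.5), \code{validation_truth} /
#' \code{validation_predictions} (for "learnt"), \code{n_batches}
#' (default 5). See the vignette for per-task keys.
#'
#' @param config named list or YAML file path.
#' @return invisibly, a named list of written file paths.
#' @name runners
NULL

#' @rdname runners
#' @export
runEvaluate <- function(config) {
  cfg <- .loadConfig(config)
  .runTask(cfg, "evaluate", function(cfg, emit) {
    truth <- readAnnotations(cfg$truth)
    levels <- as.integer(cfg$levels %||% 1:4)
    for (m in names(cfg$predictions)) {
      preds <- readPredictions(cfg$predictions[[m]], m)
      sets <- .thresholdSets(preds, cfg)
      report <- lapply(levels, function(lv) evaluateLevel(truth, sets, lv))
      batched <- do.call(rbind, lapply(levels, function(lv)
        cbind(level = lv,
              evaluateBatched(truth, sets, lv,
                              nBatches = cfg$n_batches %||% 5L,
                              seed = cfg$seed %||% 17L))))
      prefix <- file.path(cfg$out, paste0("metrics_", m))
      emit(writeReport(report, prefix))
      emit(.emitTsv(batched, paste0(prefix, "_batched.tsv")))
      sb <- file.path(cfg$out, paste0("sunburst_", m, ".json"))
      writeSunburst(perClassTable(truth, sets), sb)
      emit(sb)
    }
  })
}

#' @rdname runners
#' @export
runComplete <- function(config) {
  cfg <- .loadConfig(config)
  .runTask(cfg, "complete", function(cfg, emit) {
    truth <- readAnnotations(cfg$truth)
    models <- .readModels(cfg)
    entries <- findIncomplete(truth)
    res <- agreementRateEval(models, entries,
                             denominator = cfg$denominator %||% "all",
                             nBatches = cfg$n_batches %||% 5L,
                             seed = cfg$seed %||% 17L)
    emit(.emitTsv(res@perEntry, file.path(cfg$out, "completion_entries.tsv")))
    modelTable <- data.frame(model = names(res@perModelCount),
                             agreement_count = as.integer(res@perModelCount),
                             prefix_consistency =
                               as.numeric(res@prefixConsistency))
    modelTable <- merge(modelTable, res@batchStats, by = "model",
                        all.x = TRUE, sort = TRUE)
    emit(.emitTsv(modelTable, file.path(cfg$out, "completion_models.tsv")))
    emit({
      p <- file.path(cfg$out, "completion_summary.json")
      jsonlite::write_json(list(agreement_rate = res@agreementRate,
                                n_entries = nrow(res@perEntry)),
                           p, auto_unbox = TRUE, digits = NA)
      p
    })
  })
}

#' @rdname runners
#' @export
runRecommend <- function(config) {
  cfg <- .loadConfig(config)
  .runTask(cfg, "recommend", function(cfg, emit) {
    truth <- readAnnotations(cfg$truth)
    if (!is.null(cfg$train_truth))
      truth <- selectUnseen(truth, readAnnotations(cfg$train_truth))
    table <- readReactionTable(cfg$reactions)
    truncateTo <- cfg$truncate_to
    summaries <- lapply(names(cfg$predictions), function(m) {
      preds <- readPredictions(cfg$predictions[[m]], m)
      sets <- .thresholdSets(preds, cfg)
      rep <- similarityReport(sets, truth, table,
                              seed = cfg$seed %||% 17L,
                              maxSamples = cfg$max_samples %||% 10L,
                              model = m,
                              truncateTo = truncateTo)
      emit(.emitTsv(data.frame(protein_id = names(rep@perProtein),
                               similarity = as.numeric(rep@perProtein)),
                    file.path(cfg$out, paste0("similarity_", m, ".tsv"))))
      extras <- additionalPredictions(sets, truth)
      emit(.emitTsv(extras,
                    file.path(cfg$out, paste0("additional_", m, ".tsv"))))
      list(model = m, coverage = rep@coverage,
           average_similarity = rep@averageSimilarity,
           weighted_similarity = rep@weightedSimilarity)
    })
    emit({
      p <- file.path(cfg$out, "similarity_summary.json")
      jsonlite::write_json(summaries, p, auto_unbox = TRUE, digits = NA)
      p
    })
  })
}

#' @rdname runners
#' @export
runEnsemble <- function(config) {
  cfg <- .loadConfig(config)
  .runTask(cfg, "ensemble", function(cfg, emit) {
    base <- .readModels(cfg, key = "base")
    method <- cfg$method %||% "vote"
    out <- if (identical(method, "vote")) {
      majorityVote(base, denominator = cfg$denominator %||% "voters")
    } else if (identical(method, "stack")) {
      valTruth <- readAnnotations(cfg$validation_truth)
      valBase <- lapply(names(cfg$validation_base), function(m)
        readPredictions(cfg$validation_base[[m]], m))
      model <- fitStacker(valBase, valTruth, seed = cfg$seed %||% 17L)
      applyStacker(model, base)
    } else stop("unknown ensemble method: ", method)
    emit({
      p <- file.path(cfg$out, paste0("ensemble_", method, ".tsv"))
      writePredictions(out, p)
      p
    })
  })
}

#' @rdname runners
#' @export
runCurate <- function(config) {
  cfg <- .loadConfig(config)
  .runTask(cfg, "curate", function(cfg, emit) {
    load <- function(fa, tsv) list(seqs = readFasta(fa),
                                   annots = readAnnotations(tsv))
    train <- load(cfg$train_fasta, cfg$train_truth)
    test <- load(cfg$test_fasta, cfg$test_truth)
    log <- list()
    step <- function(x, side) {
      log[[length(log) + 1L]] <<- cbind(side = side, x$log)
      x[c("seqs", "annots")]
    }
    train <- step(do.call(dropNonEnzymes, train), "train")
    train <- step(do.call(dedupSequences, train), "train")
    test <- step(do.call(dropNonEnzymes, test), "test")
    test <- step(do.call(dedupSequences, test), "test")
    fs <- filterSimilar(train, test, cfg$threshold %||% 100)
    log[[length(log) + 1L]] <- cbind(side = "train", fs$log)
    train <- fs$train
    emit({
      p <- file.path(cfg$out, "train_filtered.fasta")
      writeFasta(train$seqs, p); p
    })
    emit(writeAnnotations(train$annots,
                          file.path(cfg$out, "train_filtered.tsv")))
    emit({
      p <- file.path(cfg$out, "provenance.json")
      jsonlite::write_json(do.call(rbind, log), p, auto_unbox = TRUE,
                           digits = NA)
      p
    })
  })
}

#' @rdname runners
#' @export
runSimulate <- function(config) {
  cfg <- .loadConfig(config)
  .runTask(cfg, "simulate", function(cfg, emit) {
    spec <- syntheticSpec(
      nProteins = cfg$n_proteins %||% 500L,
      hierarchyShape = as.integer(cfg$hierarchy_shape %||% c(4, 3, 3, 4)),
      multiLabelRate = cfg$multi_label_rate %||% 0.1,
      incompleteRate = cfg$incomplete_rate %||% 0.15,
      modelProfiles = cfg$model_profiles,
      reactionFamilyNoise = cfg$reaction_family_noise %||% 0.2,
      heldOutFraction = cfg$held_out_fraction %||% 0.1,
      seed = cfg$seed %||% 17L)
    for (p in writeSyntheticFixtures(spec, cfg$out)) emit(p)
  })
}

#' @rdname runners
#' @export
runCompare <- function(config) {
  cfg <- .loadConfig(config)
  stopifnot(length(cfg$predictions) == 2L)
  .runTask(cfg, "compare", function(cfg, emit) {
    truth <- readAnnotations(cfg$truth)
    tables <- lapply(names(cfg$predictions), function(m) {
      preds <- readPredictions(cfg$predictions[[m]], m)
      sets <- .thresholdSets(preds, cfg)
      pc <- perClassTable(truth, sets)
      emit({
        p <- file.path(cfg$out, paste0("sunburst_", m, ".json"))
        writeSunburst(pc, p); p
      })
      pc
    })
    emit({
      p <- file.path(cfg$out, "sunburst_diff.json")
      writeSunburstDiff(tables[[1L]], tables[[2L]], p); p
    })
  })
}

# ---- shared plumbing -------------------------------------------------------

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) config <-
      readConfig(config)
  stopifnot(is.list(config), !is.null(config$out))
  config
}

# run a task body, collect written files, write the manifest, clean up on
# failure
.runTask <- function(cfg, task, body) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(paths) {
    written <<- c(written, unlist(paths))
    invisible(paths)
  }
  gc(reset = TRUE)
  t0 <- proc.time()[["elapsed"]]
  ok <- FALSE
  tryCatch({
    body(cfg, emit)
    ok <- TRUE
  }, error = function(e) {
    unlink(written)
    stop(task, ": ", conditionMessage(e), call. = FALSE)
  })
  wall <- proc.time()[["elapsed"]] - t0
  g <- gc()
  manifest <- list(
    task = task,
    package_version = as.character(utils::packageVersion("enzEval")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed %||% 17L,
    config = cfg[setdiff(names(cfg), "out")],
    inputs = .inputHashes(cfg),
    outputs = basename(written),
    efficiency = list(phase = "inference",
                      wall_time_seconds = wall,
                      peak_memory_bytes = sum(g[, 6L]) * 2^20,
                      artifact_bytes = sum(file.size(written), na.rm = TRUE)))
  mp <- file.path(cfg$out, paste0("manifest_", task, ".json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .log("INFO", task, sprintf("wrote %d files to %s in %.2fs",
                             length(written), cfg$out, wall))
  invisible(c(as.list(setNames(written, basename(written))),
              manifest = mp))
}

# md5 of every config value that names an existing file
.inputHashes <- function(cfg) {
  paths <- unlist(cfg[setdiff(names(cfg), "out")], use.names = TRUE)
  paths <- paths[vapply(paths, function(p)
    is.character(p) && length(p) == 1L && file.exists(p) && !dir.exists(p),
    TRUE)]
  if (length(paths) == 0L) return(stats::setNames(list(), character(0)))
  as.list(tools::md5sum(paths))
}

# structured log line: timestamp, module, level, message
.log <- function(level, module, msg) {
  message(sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, module,
                  msg))
}

.thresholdSets <- function(preds, cfg) {
  mode <- cfg$thresholds %||% "regular"
  if (identical(mode, "regular")) {
    applyRegular(preds, tExtra = cfg$t_extra %||% 0.5)
  } else if (identical(mode, "learnt")) {
    if (is.null(cfg$validation_truth) || is.null(cfg$validation_predictions))
      stop("learnt thresholds need validation_truth and ",
           "validation_predictions (fit on held-out data, not the test set)")
    valTruth <- readAnnotations(cfg$validation_truth)
    valPreds <- readPredictions(
      cfg$validation_predictions[[modelName(preds)]] %||%
        cfg$validation_predictions, modelName(preds))
    applyThresholds(preds, learnThresholds(valTruth, valPreds))
  } else stop("unknown thresholding mode: ", mode)
}

.readModels <- function(cfg, key = "predictions") {
  lst <- cfg[[key]]
  stopifnot(!is.null(names(lst)))
  lapply(names(lst), function(m) readPredictions(lst[[m]], m))
}

.emitTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
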