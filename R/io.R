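#' Read ground-truth EC annotations from TSV
#'
#' Expects a tab-separated file with columns \code{protein_id} and
#' \code{ec_numbers} (semicolon-separated EC labels). Duplicate protein rows
#' are merged by set union. In strict mode (default) malformed rows abort
#' with their line number; in lenient mode they are skipped with a warning.
#'
#' @param path file path.
#' @param strict logical; error (TRUE) or warn-and-skip (FALSE) on bad rows.
#' @return an [AnnotationTable-class].
#' @export
readAnnotations <- function(path, strict = TRUE) {
  df <- .readTsv(path, c("protein_id", "ec_numbers"))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ecs <- strsplit(df$ec_numbers[i], ";", fixed = TRUE)[[1L]]
    ecs <- trimws(ecs)
    ecs <- ecs[nzchar(ecs)]
    parsed <- tryCatch(ecParse(ecs), error = function(e) e)
    if (inherits(parsed, "error") || length(parsed) == 0L) {
      msg <- sprintf("%s line %d: %s", path, i + 1L,
                     if (inherits(parsed, "error")) conditionMessage(parsed)
                     else "empty EC cell")
      if (strict) stop(msg) else {
        warning(msg, call. = FALSE)
        return(NULL)
      }
    }
    data.frame(protein_id = df$protein_id[i], ec = parsed,
               stringsAsFactors = FALSE)
  })
  AnnotationTable(do.call(rbind, c(rows,
    list(data.frame(protein_id = character(0), ec = character(0))))))
}

#' @rdname readAnnotations
#' @param annots an [AnnotationTable-class] to serialize.
#' @export
writeAnnotations <- function(annots, path) {
  stopifnot(is(annots, "AnnotationTable"))
  sets <- labelSets(annots)
  df <- data.frame(protein_id = names(sets),
                   ec_numbers = vapply(sets, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one model's scored predictions from TSV
#'
#' Expects columns \code{protein_id}, \code{ec_number}, \code{score}.
#' Scores must lie in [0,1]; rows duplicated on (protein, EC) keep the
#' maximum score.
#'
#' @inheritParams readAnnotations
#' @param modelName name recorded on the resulting table.
#' @return a [PredictionTable-class].
#' @export
readPredictions <- function(path, modelName, strict = TRUE) {
  df <- .readTsv(path, c("protein_id", "ec_number", "score"))
  score <- suppressWarnings(as.numeric(df$score))
  ec <- vapply(df$ec_number, function(x)
    tryCatch(ecParse(x), error = function(e) NA_character_),
    "", USE.NAMES = FALSE)
  bad <- is.na(score) | score < 0 | score > 1 | is.na(ec)
  if (any(bad)) {
    msg <- sprintf("%s line %d: %s", path, which(bad)[1L] + 1L,
                   if (is.na(ec[which(bad)[1L]])) "malformed EC"
                   else "score outside [0,1]")
    if (strict) stop(msg)
    warning(msg, " (and ", sum(bad) - 1L, " more rows skipped)",
            call. = FALSE)
  }
  PredictionTable(data.frame(protein_id = df$protein_id[!bad],
                             ec = ec[!bad], score = score[!bad],
                             stringsAsFactors = FALSE), modelName)
}

#' @rdname readPredictions
#' @param preds a [PredictionTable-class] to serialize.
#' @export
writePredictions <- function(preds, path) {
  stopifnot(is(preds, "PredictionTable"))
  e <- preds@entries
  utils::write.table(
    data.frame(protein_id = e$protein_id, ec_number = e$ec, score = e$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write protein sequences (FASTA)
#'
#' Thin wrappers over Biostrings with the package's contract checks:
#' duplicate identifiers and empty files are errors; sequences must be
#' non-empty.
#'
#' @param path FASTA file path.
#' @return \code{readFasta}: a [Biostrings::AAStringSet-class] named by
#'   identifier (first whitespace-delimited word of the header).
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA identifiers in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1L])
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence in ", path)
  seqs
}

#' @rdname readFasta
#' @param seqs an AAStringSet (or named character vector).
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read and write EC-to-reaction tables
#'
#' TSV with columns \code{ec_number} and \code{reaction}
#' (\code{"reactants>>products"}, molecules \code{.}-separated).
#'
#' @inheritParams readAnnotations
#' @inheritParams ReactionTable
#' @return a [ReactionTable-class].
#' @export
readReactionTable <- function(path, fingerprinter = fingerprintTokenHash,
                              backend = "token-hash") {
  df <- .readTsv(path, c("ec_number", "reaction"))
  ReactionTable(data.frame(ec = df$ec_number, reaction = df$reaction,
                           stringsAsFactors = FALSE),
                fingerprinter = fingerprinter, backend = backend)
}

#' @rdname readReactionTable
#' @param table a [ReactionTable-class] to serialize.
#' @export
writeReactionTable <- function(table, path) {
  stopifnot(is(table, "ReactionTable"))
  e <- table@entries
  utils::write.table(
    data.frame(ec_number = e$ec, reaction = e$reaction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize per-class threshold maps
#'
#' TSV with columns \code{ec} and \code{threshold}; the class-suppressing
#' sentinel is written as \code{"NEVER"}. The default threshold is stored on
#' a pseudo-row with ec \code{"*"}.
#'
#' @param tm a [ThresholdMap-class].
#' @param path file path.
#' @export
writeThresholdMap <- function(tm, path) {
  stopifnot(is(tm, "ThresholdMap"))
  th <- tm@thresholds
  df <- data.frame(
    ec = c("*", names(th)),
    threshold = c(format(tm@default, digits = 17),
                  ifelse(is.infinite(th), "NEVER",
                         format(th, digits = 17))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeThresholdMap
#' @export
readThresholdMap <- function(path) {
  df <- .readTsv(path, c("ec", "threshold"))
  isDefault <- df$ec == "*"
  default <- if (any(isDefault)) as.numeric(df$threshold[isDefault][1L]) else 0.5
  df <- df[!isDefault, , drop = FALSE]
  vals <- rep(Inf, nrow(df))
  num <- df$threshold != "NEVER"
  vals[num] <- as.numeric(df$threshold[num])
  new("ThresholdMap", default = default,
      thresholds = setNames(vals, if (nrow(df)) ecParse(df$ec) else character(0)))
}

#' Write and read metrics reports
#'
#' A metrics report is a list of [LevelMetrics-class] objects (one per
#' evaluated EC level). \code{writeReport} emits both a long-form TSV
#' (per-class rows plus aggregate rows) and a structured JSON document;
#' \code{readReport} reconstructs the report from the JSON losslessly
#' (numeric round-trip exact to full double precision).
#'
#' @param report a [LevelMetrics-class] or list of them.
#' @param pathPrefix output path without extension; \code{.tsv} and
#'   \code{.json} are appended.
#' @return invisibly, the two file paths.
#' @export
writeReport <- function(report, pathPrefix) {
  if (is(report, "LevelMetrics")) report <- list(report)
  stopifnot(all(vapply(report, is, TRUE, "LevelMetrics")))
  long <- do.call(rbind, lapply(report, function(lm) {
    pc <- lm@perClass
    pc$level <- lm@level
    pc
  }))
  agg <- do.call(rbind, lapply(report, function(lm)
    data.frame(level = lm@level, metric = names(lm@aggregates),
               value = unname(lm@aggregates), n_proteins = lm@nProteins)))
  tsv <- paste0(pathPrefix, ".tsv")
  jsonPath <- paste0(pathPrefix, ".json")
  utils::write.table(long, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  doc <- lapply(report, function(lm) list(
    level = lm@level, n_proteins = lm@nProteins,
    aggregates = as.list(lm@aggregates), per_class = lm@perClass))
  jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  # the aggregate rows ride along in the TSV for human consumption
  utils::write.table(agg, paste0(pathPrefix, "_aggregates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(tsv, jsonPath))
}

#' @rdname writeReport
#' @param path path to a report JSON written by \code{writeReport}.
#' @export
readReport <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc, function(lv) {
    pc <- data.frame(lapply(lv$per_class, function(col)
      unlist(col) %||% vector(mode = "character", 0L)),
      stringsAsFactors = FALSE)
    new("LevelMetrics", level = as.integer(lv$level),
        perClass = pc, aggregates = unlist(lv$aggregates),
        nProteins = as.integer(lv$n_proteins))
  })
}

#' Read a YAML run configuration
#'
#' @param path YAML file naming input paths, task parameters, thresholds and
#'   seed; see the vignette for the recognized keys.
#' @return named list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

# strict TSV reader: enforce required columns, keep cells as character
.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}
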