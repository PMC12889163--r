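#' Dataset curation: enzyme filtering, deduplication, leakage removal
#'
#' Implements the preprocessing pipeline for benchmark dataset
#' construction: non-enzymes (proteins without any EC annotation) are
#' dropped, duplicate sequences within a split are collapsed, and training
#' sequences similar to any test sequence are removed by clustering the
#' union of both splits at a sequence-identity threshold and discarding
#' every training member of a cluster that contains a test sequence. The
#' test split is never modified. Each step records before/after counts in a
#' provenance log.
#'
#' @param seqs an AAStringSet (or named character vector of sequences).
#' @param annots an [AnnotationTable-class].
#' @return \code{dropNonEnzymes}: list with \code{seqs}, \code{annots},
#'   \code{log} (data.frame step, n_before, n_after).
#' @export
dropNonEnzymes <- function(seqs, annots) {
  seqs <- .asAAStringSet(seqs)
  stopifnot(is(annots, "AnnotationTable"))
  keep <- intersect(names(seqs), proteins(annots))
  if (length(keep) == 0L)
    warning("no annotated enzymes remain after filtering", call. = FALSE)
  list(seqs = seqs[keep], annots = annots[keep],
       log = .provRow("drop_non_enzymes", length(seqs), length(keep)))
}

#' @rdname dropNonEnzymes
#' @details \code{dedupSequences} keeps, among identical sequence strings,
#'   the record with the lexicographically smallest identifier and merges
#'   the EC annotations of the duplicates by set union.
#' @export
dedupSequences <- function(seqs, annots) {
  seqs <- .asAAStringSet(seqs)
  stopifnot(is(annots, "AnnotationTable"))
  ids <- names(seqs)[order(names(seqs))]
  strs <- as.character(seqs[ids])
  rep_id <- ids[!duplicated(strs)]               # smallest id per string
  repOf <- setNames(rep_id[match(strs, strs[!duplicated(strs)])], ids)
  e <- annots@entries
  e <- e[e$protein_id %in% ids, , drop = FALSE]
  e$protein_id <- repOf[e$protein_id]
  list(seqs = seqs[rep_id], annots = AnnotationTable(e),
       log = .provRow("dedup_sequences", length(seqs), length(rep_id)))
}

#' Remove training sequences similar to test sequences
#'
#' Clusters the union of training and test sequences at \code{threshold}
#' percent identity and removes every training sequence sharing a cluster
#' with any test sequence (cluster-membership removal, which can over-remove
#' via transitive clustering — intentional). Typical thresholds are 30, 50,
#' 70, 90 and 100; any percentage is accepted. The retained training size is
#' monotone non-decreasing in the threshold.
#'
#' @param train,test lists with elements \code{seqs} (AAStringSet) and
#'   \code{annots} ([AnnotationTable-class]); identifiers must be disjoint
#'   across splits.
#' @param threshold percent identity in (0, 100].
#' @param clusterer function \code{(seqs, identity)} returning a named
#'   character vector mapping sequence id to cluster id; default
#'   [builtinCluster()]. Use [readClusterTsv()] to adapt an external
#'   clustering tool's representative/member TSV output.
#' @return list with filtered \code{train} and a provenance \code{log} row.
#' @export
filterSimilar <- function(train, test, threshold,
                          clusterer = builtinCluster) {
  stopifnot(threshold > 0, threshold <= 100)
  trainSeqs <- .asAAStringSet(train$seqs)
  testSeqs <- .asAAStringSet(test$seqs)
  if (length(intersect(names(trainSeqs), names(testSeqs))))
    stop("train and test identifiers must be disjoint")
  all <- c(trainSeqs, testSeqs)
  clusters <- clusterer(all, threshold)
  contaminated <- unique(clusters[names(testSeqs)])
  keep <- names(trainSeqs)[!(clusters[names(trainSeqs)] %in% contaminated)]
  list(train = list(seqs = trainSeqs[keep],
                    annots = train$annots[keep]),
       log = .provRow(sprintf("filter_similar_%g", threshold),
                      length(trainSeqs), length(keep)))
}

#' Greedy sequence-identity clustering
#'
#' Desk-scale clustering backend: sequences are sorted by decreasing length
#' (ties by identifier), and each sequence joins the first existing cluster
#' whose representative aligns to it with percent identity (matches divided
#' by alignment length, global alignment) at or above \code{identity};
#' otherwise it founds a new cluster. At thresholds of 60\% or more, a
#' 4-mer containment prefilter skips alignments against representatives
#' that share no 4-mer (such pairs cannot plausibly reach the threshold).
#' Deterministic.
#'
#' @param seqs an AAStringSet (or named character vector).
#' @param identity percent identity threshold in (0, 100].
#' @return named character vector: sequence id -> cluster id (the
#'   representative's id).
#' @export
builtinCluster <- function(seqs, identity) {
  seqs <- .asAAStringSet(seqs)
  stopifnot(identity > 0, identity <= 100, length(seqs) > 0L)
  ord <- order(-Biostrings::width(seqs), names(seqs))
  ids <- names(seqs)[ord]
  strs <- as.character(seqs)[ids]
  useKmer <- identity >= 60
  kmers <- if (useKmer) lapply(strs, .kmerSet, k = 4L)
  reps <- character(0)
  assign <- setNames(character(length(ids)), ids)
  for (i in seq_along(ids)) {
    cand <- reps
    if (useKmer && length(cand))
      cand <- cand[vapply(cand, function(r)
        length(intersect(kmers[[i]], kmers[[r]])) > 0L, TRUE)]
    hit <- NA_character_
    if (length(cand)) {
      pid <- .alignIdentity(strs[cand], strs[ids[i]])
      match <- which(pid >= identity)
      if (length(match)) hit <- cand[match[1L]]   # first in founding order
    }
    if (is.na(hit)) {
      reps <- c(reps, ids[i])
      assign[ids[i]] <- ids[i]
    } else assign[ids[i]] <- hit
  }
  assign
}

.kmerSet <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# percent identity = matches / alignment length, global alignment
.alignIdentity <- function(patterns, subject) {
  mat <- .aaSubstMatrix()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

.aaSubstMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                   "P","S","T","W","Y","V","X","*")
      m <- matrix(-1, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      m["X", ] <- -1; m[, "X"] <- -1; m["X", "X"] <- 0  # X never "matches"
      cache <<- m
    }
    cache
  }
})

#' Adapt an external clusterer's TSV output
#'
#' Reads the two-column (representative, member) TSV that standard
#' clustering tools emit and returns a clusterer-shaped function for
#' [filterSimilar()].
#'
#' @param path TSV path with columns representative, member (no header).
#' @return function \code{(seqs, identity)} returning the member-to-
#'   representative mapping restricted to \code{names(seqs)}.
#' @export
readClusterTsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("representative", "member"))
  map <- setNames(df$representative, df$member)
  function(seqs, identity) {
    ids <- names(.asAAStringSet(seqs))
    missing <- setdiff(ids, names(map))
    if (length(missing))
      stop("cluster file lacks members: ", paste(missing, collapse = ", "))
    map[ids]
  }
}

#' Structure and metadata hooks
#'
#' \code{structureFilter} keeps only the proteins satisfying a predicate
#' supplied as a local id list (emulating e.g. "has a predicted 3D
#' structure"); \code{attachMetadata} joins a local TSV of per-protein
#' metadata (e.g. GO terms) onto the annotation entries verbatim. Mapping
#' rows referencing unknown proteins are logged and ignored.
#'
#' @param seqs an AAStringSet.
#' @param annots an [AnnotationTable-class].
#' @param keepIds character vector of protein ids passing the predicate, or
#'   a path to a one-id-per-line file.
#' @export
structureFilter <- function(seqs, annots, keepIds) {
  seqs <- .asAAStringSet(seqs)
  if (length(keepIds) == 1L && file.exists(keepIds))
    keepIds <- readLines(keepIds)
  keep <- intersect(names(seqs), keepIds)
  if (length(keep) == 0L)
    warning("structure predicate removed every protein", call. = FALSE)
  list(seqs = seqs[keep], annots = annots[keep],
       log = .provRow("structure_filter", length(seqs), length(keep)))
}

#' @rdname structureFilter
#' @param mapping data.frame with a \code{protein_id} column plus metadata
#'   columns, or a path to such a TSV.
#' @return \code{attachMetadata}: data.frame of annotation entries joined
#'   with the metadata columns.
#' @export
attachMetadata <- function(annots, mapping) {
  stopifnot(is(annots, "AnnotationTable"))
  if (is.character(mapping)) mapping <- .readTsv(mapping, "protein_id")
  unknown <- setdiff(mapping$protein_id, proteins(annots))
  if (length(unknown))
    message("attachMetadata: ignoring ", length(unknown),
            " mapping rows for unknown proteins")
  mapping <- mapping[!(mapping$protein_id %in% unknown), , drop = FALSE]
  merge(annots@entries, mapping, by = "protein_id", all.x = TRUE,
        sort = TRUE)
}

.provRow <- function(step, before, after)
  data.frame(step = step, n_before = before, n_after = after,
             stringsAsFactors = FALSE)

.asAAStringSet <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  if (!is(seqs, "AAStringSet")) stop("sequences must be an AAStringSet")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs
}
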