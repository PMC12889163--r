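#' Build an AnnotationTable
#'
#' @param x either a data.frame with columns \code{protein_id} and \code{ec}
#'   (one row per (protein, label) pair; duplicates merged), or a named list
#'   of character vectors of EC labels.
#' @return an [AnnotationTable-class].
#' @examples
#' AnnotationTable(list(P1 = c("1.1.1.1", "2.3.1.4"), P2 = "1.1.-.-"))
#' @export
AnnotationTable <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) > 0L && is.null(names(x)))
      stop("list input must be named by protein identifier")
    x <- data.frame(
      protein_id = rep(names(x), lengths(x)),
      ec = unlist(x, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  e <- data.frame(protein_id = as.character(x$protein_id),
                  ec = if (nrow(x)) ecParse(x$ec) else character(0),
                  stringsAsFactors = FALSE)
  e <- unique(e)
  e <- e[order(e$protein_id, e$ec), , drop = FALSE]
  rownames(e) <- NULL
  new("AnnotationTable", entries = e)
}

#' @rdname accessors
#' @export
setMethod("proteins", "AnnotationTable",
          function(x) unique(x@entries$protein_id))

#' @rdname accessors
#' @export
setMethod("tableEntries", "AnnotationTable", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("labelSets", "AnnotationTable", function(x) {
  split(x@entries$ec, x@entries$protein_id)
})

#' @export
setMethod("length", "AnnotationTable",
          function(x) length(unique(x@entries$protein_id)))

#' Subset an AnnotationTable by protein identifier
#' @param x an [AnnotationTable-class]
#' @param i character vector of protein identifiers to keep
#' @param j,...,drop ignored
#' @export
setMethod("[", "AnnotationTable", function(x, i, j, ..., drop = FALSE) {
  new("AnnotationTable",
      entries = x@entries[x@entries$protein_id %in% i, , drop = FALSE])
})

setMethod("show", "AnnotationTable", function(object) {
  e <- object@entries
  cat("AnnotationTable with", length(unique(e$protein_id)), "proteins,",
      nrow(e), "(protein, EC) pairs\n")
  np <- sum(ecDepth(unique(e$ec)) < 4L)
  cat("  distinct labels:", length(unique(e$ec)),
      sprintf("(%d partial)\n", np))
})
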