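#' Build a PredictionTable
#'
#' @param entries data.frame with columns \code{protein_id}, \code{ec},
#'   \code{score}. Rows duplicated on (protein, ec) keep the maximum score.
#' @param modelName single string naming the model.
#' @return a [PredictionTable-class].
#' @examples
#' PredictionTable(data.frame(protein_id = "P1", ec = "1.1.1.1", score = 0.9),
#'                 modelName = "toy")
#' @export
PredictionTable <- function(entries, modelName) {
  stopifnot(is.data.frame(entries), is.character(modelName))
  e <- data.frame(protein_id = as.character(entries$protein_id),
                  ec = if (nrow(entries)) ecParse(entries$ec) else character(0),
                  score = as.numeric(entries$score),
                  stringsAsFactors = FALSE)
  if (nrow(e)) {
    key <- paste(e$protein_id, e$ec, sep = "\r")
    # duplicate (protein, ec) rows keep the maximum score
    e <- e[order(key, -e$score), , drop = FALSE]
    e <- e[!duplicated(paste(e$protein_id, e$ec, sep = "\r")), , drop = FALSE]
    e <- e[order(e$protein_id, e$ec), , drop = FALSE]
    rownames(e) <- NULL
  }
  new("PredictionTable", modelName = modelName, entries = e)
}

#' @rdname accessors
#' @export
setMethod("proteins", "PredictionTable",
          function(x) unique(x@entries$protein_id))

#' @rdname accessors
#' @export
setMethod("tableEntries", "PredictionTable", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("modelName", "PredictionTable", function(x) x@modelName)

setMethod("show", "PredictionTable", function(object) {
  e <- object@entries
  cat("PredictionTable '", object@modelName, "': ",
      length(unique(e$protein_id)), " proteins, ", nrow(e),
      " scored predictions\n", sep = "")
})

#' Top-scoring prediction per protein
#'
#' Returns each requested protein's highest-scoring EC label; score ties are
#' broken by the lexicographically smallest canonical EC string. Proteins
#' absent from the table get \code{NA} (no prediction).
#'
#' @param preds a [PredictionTable-class].
#' @param proteinIds character vector of proteins to look up; default all
#'   proteins in the table.
#' @return named character vector (NA where the model abstains).
#' @examples
#' pt <- PredictionTable(data.frame(protein_id = "P1",
#'                                  ec = c("1.1.1.1", "2.1.1.1"),
#'                                  score = c(0.8, 0.6)), "toy")
#' topPrediction(pt)
#' @export
topPrediction <- function(preds, proteinIds = proteins(preds)) {
  stopifnot(is(preds, "PredictionTable"))
  e <- preds@entries
  out <- setNames(rep(NA_character_, length(proteinIds)), proteinIds)
  if (nrow(e)) {
    e <- e[order(e$protein_id, -e$score, e$ec), , drop = FALSE]
    top <- e[!duplicated(e$protein_id), , drop = FALSE]
    hit <- match(proteinIds, top$protein_id)
    out[!is.na(hit)] <- top$ec[hit[!is.na(hit)]]
  }
  out
}
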