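#' Export per-class metrics as a sunburst hierarchy
#'
#' Converts the per-class table from [perClassTable()] into the nested JSON
#' tree a sunburst renderer consumes: each node carries \code{label} (the
#' truncated EC string), \code{support}, \code{f1}, and \code{children};
#' the root's children are the top-level EC classes present.
#'
#' @param perClass data.frame as returned by [perClassTable()] (columns
#'   \code{level, ec, support, f1}, one row per EC node per level).
#' @param path output JSON path.
#' @return invisibly, the tree as a nested list.
#' @export
writeSunburst <- function(perClass, path) {
  tree <- .sunburstTree(perClass)
  jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA)
  invisible(tree)
}

#' @rdname writeSunburst
#' @param perClassA,perClassB per-class tables for the two models being
#'   compared; the difference tree carries \code{f1 = f1_A - f1_B} per node,
#'   treating a node absent in one model as F1 = 0 there, and
#'   \code{support} = the maximum of the two supports.
#' @export
writeSunburstDiff <- function(perClassA, perClassB, path) {
  key <- function(df) paste(df$level, df$ec)
  all <- unique(rbind(perClassA[c("level", "ec")], perClassB[c("level", "ec")]))
  ia <- match(key(all), key(perClassA))
  ib <- match(key(all), key(perClassB))
  diff <- data.frame(
    level = all$level, ec = all$ec,
    support = pmax(ifelse(is.na(ia), 0, perClassA$support[ia]),
                   ifelse(is.na(ib), 0, perClassB$support[ib])),
    f1 = ifelse(is.na(ia), 0, perClassA$f1[ia]) -
         ifelse(is.na(ib), 0, perClassB$f1[ib]),
    stringsAsFactors = FALSE)
  tree <- .sunburstTree(diff)
  jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA)
  invisible(tree)
}

.sunburstTree <- function(perClass) {
  stopifnot(all(c("level", "ec", "support", "f1") %in% names(perClass)))
  build <- function(prefixEc, level) {
    if (level > 4L) return(list())
    rows <- perClass[perClass$level == level, , drop = FALSE]
    if (level > 1L)
      rows <- rows[ecTruncate(rows$ec, level - 1L) == prefixEc, , drop = FALSE]
    rows <- rows[order(rows$ec), , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) list(
      label = rows$ec[i],
      support = rows$support[i],
      f1 = rows$f1[i],
      children = build(rows$ec[i], level + 1L)))
  }
  list(label = "EC", children = build(NULL, 1L))
}
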