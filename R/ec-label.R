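#' EC label parsing and hierarchy operations
#'
#' Enzyme Commission (EC) numbers are four-level hierarchical identifiers
#' (class.subclass.sub-subclass.serial, e.g. \code{"1.1.1.1"}). Partially
#' annotated enzymes carry trailing undefined levels written as dashes
#' (\code{"1.1.-.-"}). \code{ecParse} validates and canonicalizes label text;
#' labels are represented throughout the package by their canonical string
#' form, so ordinary character vectors are EC label sets.
#'
#' A level token is either a positive integer, a preliminary identifier
#' (\code{"n"} followed by a positive integer, as assigned by curators before
#' official classification, e.g. \code{"1.1.1.n5"}), or \code{"-"} for
#' undefined. Defined tokens must form a contiguous prefix: \code{"1.-.1.1"}
#' is rejected. Inputs with fewer than four dot-separated fields are
#' right-padded with \code{"-"} (some sources write \code{"1.1.1"} for
#' \code{"1.1.1.-"}).
#'
#' @param x character vector of EC label strings.
#' @return \code{ecParse}: a character vector of canonical labels
#'   (\code{"a.b.c.d"}, undefined levels as \code{"-"}).
#' @examples
#' ecParse(c("1.1.1.1", " 1.1 ", "2.7.7.n3"))
#' ecDepth(c("1.1.1.1", "1.1.-.-"))
#' ecTruncate("1.2.3.4", 2)
#' ecCompletes("1.1.1.1", "1.1.-.-")
#' @export
ecParse <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (!is.character(x)) stop("EC labels must be character")
  x <- trimws(x)
  if (any(is.na(x) | x == ""))
    stop("empty EC label")
  parts <- strsplit(x, ".", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld > 4L))
    stop("malformed EC label (more than 4 levels): ", x[nfld > 4L][1L])
  tok <- matrix("-", nrow = length(x), ncol = 4L)
  for (i in seq_along(parts)) tok[i, seq_len(nfld[i])] <- parts[[i]]
  tok <- trimws(tok)
  ok <- grepl("^([1-9][0-9]*|n[1-9][0-9]*|-)$", tok)
  if (!all(ok)) {
    bad <- ((which(!ok)[1L] - 1L) %% length(x)) + 1L   # column-major matrix
    stop("malformed EC token in label: ", x[bad])
  }
  defined <- tok != "-"
  # defined tokens must be a contiguous prefix
  for (j in 1:3) {
    gap <- !defined[, j] & apply(defined[, (j + 1L):4L, drop = FALSE], 1L, any)
    if (any(gap))
      stop("non-contiguous EC label (defined level after '-'): ", x[gap][1L])
  }
  paste(tok[, 1L], tok[, 2L], tok[, 3L], tok[, 4L], sep = ".")
}

#' @rdname ecParse
#' @return \code{ecDepth}: integer vector, the number of leading defined
#'   levels (0-4).
#' @export
ecDepth <- function(x) {
  if (length(x) == 0L) return(integer(0))
  # canonical labels have a contiguous defined prefix, so depth is the count
  as.integer(rowSums(.ecTokens(x) != "-"))
}

# token matrix for already-canonical labels (no re-validation)
.ecTokens <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  matrix(unlist(parts), ncol = 4L, byrow = TRUE,
         dimnames = list(NULL, paste0("L", 1:4)))
}

#' @rdname ecParse
#' @param level integer in 1..4, the hierarchy level to keep.
#' @return \code{ecTruncate}: character vector of labels keeping at most
#'   \code{level} defined levels, the rest undefined. Idempotent; a label
#'   shallower than \code{level} is returned unchanged.
#' @export
ecTruncate <- function(x, level) {
  stopifnot(length(level) == 1L, level >= 1, level <= 4)
  level <- as.integer(level)
  if (length(x) == 0L) return(character(0))
  tok <- .ecTokens(x)
  if (level < 4L) tok[, (level + 1L):4L] <- "-"
  paste(tok[, 1L], tok[, 2L], tok[, 3L], tok[, 4L], sep = ".")
}

#' @rdname ecParse
#' @param candidate,partial canonical EC labels (recycled to common length).
#' @return \code{ecCompletes}: logical; \code{TRUE} where \code{candidate} is
#'   a complete (depth-4) label whose defined prefix extends \code{partial}'s
#'   defined levels.
#' @export
ecCompletes <- function(candidate, partial) {
  n <- max(length(candidate), length(partial))
  candidate <- rep_len(candidate, n)
  partial <- rep_len(partial, n)
  dp <- ecDepth(partial)
  ecDepth(candidate) == 4L &
    mapply(function(cand, part, d) {
      d == 0L || identical(ecTruncate(cand, max(d, 1L)), part)
    }, candidate, partial, dp, USE.NAMES = FALSE)
}
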