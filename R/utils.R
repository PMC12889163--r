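# internal helpers

#' @importFrom stats setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a distinct sub-seed (< 2^31) from a base seed and a string salt
.deriveSeed <- function(seed, salt) {
  h <- 0
  for (code in utf8ToInt(salt)) h <- (h * 31 + code) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# shuffle ids and split into nBatches contiguous batches whose sizes differ
# by at most one (first batches take the remainder): 468/5 -> 94,94,94,93,93
.seededBatches <- function(ids, nBatches, seed) {
  n <- length(ids)
  if (n < nBatches) stop("fewer items (", n, ") than batches (", nBatches, ")")
  ids <- .withSeed(seed, sample(ids))
  base <- n %/% nBatches
  extra <- n %% nBatches
  sizes <- rep(base, nBatches) + c(rep(1L, extra), rep(0L, nBatches - extra))
  split(ids, rep(seq_len(nBatches), sizes))
}

# named-list mapping protein -> character set; drops empty elements
.dropEmptySets <- function(x) x[lengths(x) > 0L]

.assertLabelSets <- function(predicted) {
  if (is(predicted, "AnnotationTable")) return(labelSets(predicted))
  if (!is.list(predicted) ||
      (length(predicted) > 0L && is.null(names(predicted))))
    stop("predicted label sets must be a named list of character vectors")
  predicted
}
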