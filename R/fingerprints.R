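#' Reaction fingerprints and Tanimoto similarity
#'
#' The package compares enzymatic reactions through fixed-length bit-set
#' fingerprints under Tanimoto (intersection over union) similarity. The
#' backend is pluggable: any function mapping a reaction string
#' (\code{"reactants>>products"}, molecules \code{.}-separated) to a sorted
#' integer vector of set-bit indices can be used wherever a
#' \code{fingerprinter} argument is accepted.
#'
#' The default backend, \code{fingerprintTokenHash}, is fully deterministic
#' and dependency-free: each molecule string is decomposed into overlapping
#' character trigrams tagged with its reaction side (reactant/product), plus
#' one whole-molecule token, and each token is hashed onto \code{nbits}
#' buckets with a 31-ary polynomial rolling hash. Reactions sharing most of
#' their text share most bits; the side tagging makes the fingerprint a
#' difference-style descriptor (the same molecule contributes different bits
#' as a reactant than as a product).
#'
#' @param reaction single reaction string.
#' @param nbits fingerprint length in bits (default 1024).
#' @return integer vector of sorted set-bit indices in \code{[0, nbits)}.
#' @examples
#' fp <- fingerprintTokenHash("CCO.O>>CC=O")
#' tanimoto(fp, fp)
#' @export
fingerprintTokenHash <- function(reaction, nbits = 1024L) {
  stopifnot(is.character(reaction), length(reaction) == 1L)
  sides <- strsplit(reaction, ">>", fixed = TRUE)[[1L]]
  if (length(sides) > 2L) stop("malformed reaction (multiple '>>'): ", reaction)
  sides <- c(sides, rep("", 2L - length(sides)))
  toks <- character(0)
  for (s in 1:2) {
    tag <- c("r:", "p:")[s]
    mols <- strsplit(sides[s], ".", fixed = TRUE)[[1L]]
    mols <- mols[nzchar(mols)]
    for (m in mols) {
      n <- nchar(m)
      grams <- if (n <= 3L) m else
        substring(m, seq_len(n - 2L), seq_len(n - 2L) + 2L)
      toks <- c(toks, paste0(tag, m), paste0(tag, grams))
    }
  }
  if (length(toks) == 0L) return(integer(0))
  sort(unique(vapply(toks, .hashBucket, integer(1L),
                     nbits = as.integer(nbits), USE.NAMES = FALSE)))
}

# deterministic 31-ary polynomial rolling hash onto nbits buckets
.hashBucket <- function(token, nbits) {
  h <- 0
  for (code in utf8ToInt(token)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% nbits)
}

#' @rdname fingerprintTokenHash
#' @param a,b fingerprints (integer vectors of set-bit indices).
#' @return \code{tanimoto}: similarity in [0,1]; two empty fingerprints
#'   compare as 1 (identical).
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
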