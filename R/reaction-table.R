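#' Build a ReactionTable
#'
#' Associates complete (depth-4) EC numbers with the reactions they catalyze
#' and caches one fingerprint per reaction record. Modeled on unified
#' EC-to-reaction datasets such as ECReact; at desk scale the table is
#' usually a synthetic stand-in from [generateReactionTable()].
#'
#' @param entries data.frame with columns \code{ec} (complete EC labels) and
#'   \code{reaction} (\code{"reactants>>products"} strings).
#' @param fingerprinter function reaction string -> sorted integer vector of
#'   set-bit indices; default [fingerprintTokenHash()].
#' @param backend name recorded for provenance.
#' @return a [ReactionTable-class].
#' @export
ReactionTable <- function(entries, fingerprinter = fingerprintTokenHash,
                          backend = "token-hash") {
  stopifnot(is.data.frame(entries), is.function(fingerprinter))
  e <- data.frame(ec = if (nrow(entries)) ecParse(entries$ec) else character(0),
                  reaction = as.character(entries$reaction),
                  stringsAsFactors = FALSE)
  rownames(e) <- NULL
  fps <- lapply(e$reaction, fingerprinter)
  new("ReactionTable", entries = e, fingerprints = fps, backend = backend)
}

#' @rdname accessors
#' @export
setMethod("tableEntries", "ReactionTable", function(x) x@entries)

#' EC labels present in a ReactionTable
#' @param x a [ReactionTable-class]
#' @return character vector of distinct complete EC labels.
#' @export
reactionECs <- function(x) {
  stopifnot(is(x, "ReactionTable"))
  unique(x@entries$ec)
}

setMethod("show", "ReactionTable", function(object) {
  cat("ReactionTable:", nrow(object@entries), "reaction records for",
      length(unique(object@entries$ec)), "EC numbers (backend:",
      object@backend, ")\n")
})
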