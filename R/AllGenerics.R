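#' Accessors for enzEval containers
#'
#' \code{proteins} returns the protein identifiers covered by a table;
#' \code{tableEntries} the underlying long-form data.frame; \code{labelSets}
#' the per-protein sets of EC labels as a named list of character vectors;
#' \code{modelName} the model a prediction table belongs to.
#'
#' @param x an [AnnotationTable-class] or [PredictionTable-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("tableEntries", function(x) standardGeneric("tableEntries"))

#' @rdname accessors
#' @export
setGeneric("labelSets", function(x) standardGeneric("labelSets"))

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
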