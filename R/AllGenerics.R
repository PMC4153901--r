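#' @rdname MitoGenome-class
#' @param object,x a `MitoGenome` or `GeneOrder` object.
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname MitoGenome-class
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))

#' @rdname MitoGenome-class
#' @export
setGeneric("genomeLength", function(object) standardGeneric("genomeLength"))

#' @rdname MitoGenome-class
#' @export
setGeneric("genomeSequence",
           function(object) standardGeneric("genomeSequence"))

#' @rdname GeneOrder-class
#' @param object a `GeneOrder` object.
#' @export
setGeneric("orderTokens", function(object) standardGeneric("orderTokens"))
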