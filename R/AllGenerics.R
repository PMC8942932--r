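#' @rdname GenotypePanel-accessors
#' @export
setGeneric("dosageMatrix", function(x, ...) standardGeneric("dosageMatrix"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("snpInfo", function(x, ...) standardGeneric("snpInfo"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("maf", function(x, ...) standardGeneric("maf"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("missingRate", function(x, ...) standardGeneric("missingRate"))

#' @rdname KinshipMatrix-accessors
#' @export
setGeneric("excludedChromosome",
           function(x, ...) standardGeneric("excludedChromosome"))

#' @rdname KinshipMatrix-accessors
#' @export
setGeneric("nSnpsUsed", function(x, ...) standardGeneric("nSnpsUsed"))

#' @rdname SplitPlotFit-accessors
#' @export
setGeneric("varianceComponents",
           function(object, ...) standardGeneric("varianceComponents"))

#' @rdname SplitPlotFit-accessors
#' @export
setGeneric("fixedEffects", function(object, ...) standardGeneric("fixedEffects"))

#' @rdname SplitPlotFit-accessors
#' @export
setGeneric("blups", function(object, ...) standardGeneric("blups"))

#' @rdname GwasResult-accessors
#' @export
setGeneric("gwasTable", function(object, ...) standardGeneric("gwasTable"))
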