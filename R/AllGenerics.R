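#' @rdname GenotypeMatrix-class
#' @param x,object a \code{GenotypeMatrix}, \code{Pedigree},
#'   \code{KinshipMatrix}, \code{LDMatrix} or \code{PValueSet}.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleKeys", function(x) standardGeneric("sampleKeys"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname KinshipMatrix-class
#' @export
setGeneric("estimator", function(x) standardGeneric("estimator"))

#' @rdname SetTestResult-class
#' @export
setGeneric("overallP", function(x) standardGeneric("overallP"))
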