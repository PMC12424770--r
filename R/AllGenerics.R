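#' @rdname SpeciesCohort-class
#' @param x,object a \code{SpeciesCohort}
#' @export
setGeneric("cohortRecords", function(x) standardGeneric("cohortRecords"))

#' @rdname SpeciesCohort-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname SpeciesCohort-class
#' @export
setGeneric("samplingWeights", function(x) standardGeneric("samplingWeights"))

#' @rdname PglsFit-class
#' @export
setGeneric("lambdaHat", function(x) standardGeneric("lambdaHat"))

#' @rdname PglsFit-class
#' @export
setGeneric("sigma2Hat", function(x) standardGeneric("sigma2Hat"))

#' @rdname PglsFit-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname PglsFit-class
#' @export
setGeneric("rSquared", function(x, adjusted = FALSE) standardGeneric("rSquared"))

#' @rdname PglsFit-class
#' @export
setGeneric("aicValue", function(x) standardGeneric("aicValue"))

#' @rdname PglsFit-class
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))

#' @rdname ProximityStats-class
#' @export
setGeneric("iqrMean", function(x) standardGeneric("iqrMean"))
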