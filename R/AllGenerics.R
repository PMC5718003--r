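#' @export
setGeneric("nFractions", function(x) standardGeneric("nFractions"))

#' @export
setGeneric("peaks", function(x, ...) standardGeneric("peaks"))

#' @export
setGeneric("fractionSpectrum", function(x, k) standardGeneric("fractionSpectrum"))

#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @export
setGeneric("normalizeActivity", function(x) standardGeneric("normalizeActivity"))

#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @export
setGeneric("binWidthPpm", function(x) standardGeneric("binWidthPpm"))

#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @export
setGeneric("binNormalization", function(x) standardGeneric("binNormalization"))

#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

#' @export
setGeneric("enrichmentAUC", function(x, ...) standardGeneric("enrichmentAUC"))
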