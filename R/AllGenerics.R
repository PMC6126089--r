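#' @rdname FluorImage-class
#' @param object,x an object.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FluorImage-class
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname FrameStack-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname IntensityProfile-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname IntensityProfile-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname MultiPeakFit-class
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname MultiPeakFit-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname SpacingResult-class
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname SpacingResult-class
#' @export
setGeneric("spacingMean", function(x) standardGeneric("spacingMean"))

#' @rdname SpacingResult-class
#' @export
setGeneric("spacingSD", function(x) standardGeneric("spacingSD"))

#' @rdname SpacingResult-class
#' @export
setGeneric("nSpacings", function(x) standardGeneric("nSpacings"))

#' @rdname GroundTruth-class
#' @export
setGeneric("apparentSpacing", function(x) standardGeneric("apparentSpacing"))

#' @rdname GroundTruth-class
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname PairwiseComparison-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
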