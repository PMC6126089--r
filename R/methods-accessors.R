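#' @rdname FluorImage-class
#' @export
setMethod("pixelSize", "FluorImage", function(x) x@pixelSize)

#' @rdname FrameStack-class
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixelSize)

#' @rdname FluorImage-class
#' @export
setMethod("pixels", "FluorImage", function(x) x@pixels)

#' @rdname FrameStack-class
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) length(x@frames))

#' @rdname FrameStack-class
#' @param i frame index.
#' @export
setMethod("[[", "FrameStack", function(x, i) {
  fluorImage(x@frames[[i]], x@pixelSize)
})

#' @rdname IntensityProfile-class
#' @export
setMethod("positions", "IntensityProfile", function(x) x@positions)

#' @rdname IntensityProfile-class
#' @export
setMethod("intensities", "IntensityProfile", function(x) x@intensities)

#' @rdname IntensityProfile-class
#' @export
setMethod("length", "IntensityProfile", function(x) length(x@positions))

#' @rdname MultiPeakFit-class
#' @export
setMethod("peaks", "MultiPeakFit", function(x) x@peaks)

#' @rdname MultiPeakFit-class
#' @export
setMethod("converged", "MultiPeakFit", function(x) x@converged)

#' @rdname MultiPeakFit-class
#' @param object a MultiPeakFit.
#' @export
setMethod("coef", "MultiPeakFit", function(object) {
  c(slopeA = object@slopeA, interceptB = object@interceptB)
})

#' @rdname SpacingResult-class
#' @export
setMethod("distances", "SpacingResult", function(x) x@distances)

#' @rdname SpacingResult-class
#' @export
setMethod("spacingMean", "SpacingResult", function(x) x@mean)

#' @rdname SpacingResult-class
#' @export
setMethod("spacingSD", "SpacingResult", function(x) x@sd)

#' @rdname SpacingResult-class
#' @export
setMethod("nSpacings", "SpacingResult", function(x) x@n)

#' @rdname GroundTruth-class
#' @export
setMethod("apparentSpacing", "GroundTruth", function(x) x@apparentSpacing)

#' @rdname GroundTruth-class
#' @export
setMethod("bandCenters", "GroundTruth", function(x) x@bandCentersOnAxis)

#' @rdname PairwiseComparison-class
#' @export
setMethod("pValues", "PairwiseComparison", function(x) x@pValues)

setMethod("show", "FluorImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FluorImage: %d x %d px at %.4g um/px (%.3g x %.3g um)\n",
              d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize))
  cat(sprintf("  intensity range [%.4g, %.4g] AU\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("FrameStack: %d frame(s) of %d x %d px at %.4g um/px\n",
              length(object@frames), d[1], d[2], object@pixelSize))
})

setMethod("show", "LineROI", function(object) {
  cat(sprintf("LineROI: (%.2f, %.2f) -> (%.2f, %.2f), width %d px, length %.2f px\n",
              object@p0[1], object@p0[2], object@p1[1], object@p1[2],
              object@width, sqrt(sum((object@p1 - object@p0)^2))))
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d samples, 0 to %.3f um (step %.4f um) [%s]\n",
              length(object@positions), max(object@positions),
              object@positions[2] - object@positions[1], object@source))
})

setMethod("show", "MultiPeakFit", function(object) {
  cat(sprintf("MultiPeakFit: %d peak(s) + linear offset (a = %.4g AU/um, b = %.4g AU)\n",
              nrow(object@peaks), object@slopeA, object@interceptB))
  cat(sprintf("  RSS %.4g, R^2 %.5f, converged: %s (%d iterations)\n",
              object@rss, object@rSquared, object@converged,
              object@nIterations))
  if (any(!object@peaks$kept))
    cat(sprintf("  %d peak(s) excluded for insufficient intensity\n",
                sum(!object@peaks$kept)))
  print(object@peaks, digits = 4)
})

setMethod("show", "SpacingResult", function(object) {
  cat(sprintf("SpacingResult: %.3f +/- %.3f um (n = %d kept of %d distances) [%s]\n",
              object@mean, object@sd, object@n, nrow(object@distances),
              object@source))
})

setMethod("show", "TiltGeometry", function(object) {
  cat(sprintf("TiltGeometry: Lmin = %.3g um, t = %.3g um, theta = %.3f deg\n",
              object@lMin, object@sectionThickness, object@theta))
})

setMethod("show", "StriationScene", function(object) {
  cat(sprintf("StriationScene: %d bands, spacing %.3f um, sigma %.3f um\n",
              object@nBands, object@trueSpacing, object@bandSigma))
  cat(sprintf("  tilt %.2f deg, in-plane %.2f deg, noise sd %.3g AU, %d x %d px at %.3g um/px, seed %d\n",
              object@tiltAngle, object@inPlaneAngle, object@noiseSd,
              object@imageShape[1], object@imageShape[2], object@pixelSize,
              object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d bands, true spacing %.4f um, apparent %.4f um\n",
              length(object@bandCentersOnAxis), object@scene@trueSpacing,
              object@apparentSpacing))
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %.4g +/- %.4g (n = %d)\n",
              object@mean, object@sd, object@n))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: %s vs %s\n", object@method,
              object@groups[1], object@groups[2]))
  cat(sprintf("  statistic = %.4g, df = %.4g, p = %.4g\n",
              object@statistic, object@df, object@pValue))
})

setMethod("show", "PairwiseComparison", function(object) {
  cat(sprintf("%s (%d groups)\n", object@method, nrow(object@pValues)))
  cat("p-values:\n")
  print(signif(object@pValues, 4))
})
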