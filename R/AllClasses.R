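#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Single-channel fluorescence image
#'
#' A 2-D intensity raster in arbitrary fluorescence units (AU) with a known
#' pixel size. Pixel coordinates are continuous, x to the right and y down,
#' with the origin at the center of the top-left pixel, so pixel
#' \code{pixels[r, c]} sits at \code{(x, y) = (c - 1, r - 1)}.
#'
#' @slot pixels numeric matrix of intensities (rows = y, columns = x).
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @exportClass FluorImage
setClass("FluorImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single finite value > 0")
    if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
      return("pixel raster must be non-empty")
    if (!is.numeric(object@pixels))
      return("pixels must be numeric")
    TRUE
  }
)

#' Ordered stack of frames of one field of view
#'
#' All frames share the same raster geometry and pixel size; intended for
#' repeated exposures of the same (arrested) field so frames can be averaged.
#'
#' @slot frames list of numeric matrices, all of identical dimensions.
#' @slot pixelSize micrometres per pixel, shared by all frames.
#' @exportClass FrameStack
setClass("FrameStack",
  representation(frames = "list", pixelSize = "numeric"),
  validity = function(object) {
    if (length(object@frames) < 1L) return("stack must contain >= 1 frame")
    dims <- vapply(object@frames, dim, integer(2))
    if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
      return("all frames must have identical dimensions")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a single value > 0")
    TRUE
  }
)

#' Straight-line region of interest
#'
#' Two continuous endpoints in pixel coordinates plus an odd integer width.
#' Profiles are sampled along the p0 -> p1 axis and averaged across
#' \code{width} parallel lines at unit-pixel perpendicular offsets; the odd
#' width keeps the averaging band symmetric about the line.
#'
#' @slot p0,p1 numeric length-2 endpoint coordinates (x, y) in pixels.
#' @slot width odd integer band width in pixels.
#' @exportClass LineROI
setClass("LineROI",
  representation(p0 = "numeric", p1 = "numeric", width = "integer"),
  validity = function(object) {
    if (length(object@p0) != 2L || length(object@p1) != 2L)
      return("p0 and p1 must each have two coordinates")
    if (!all(is.finite(c(object@p0, object@p1))))
      return("endpoints must be finite")
    if (all(object@p0 == object@p1)) return("p0 and p1 must differ")
    if (length(object@width) != 1L || object@width < 1L)
      return("width must be a positive integer")
    if (object@width %% 2L == 0L)
      return("width must be odd so the band is symmetric about the line")
    TRUE
  }
)

#' Intensity profile along a line ROI
#'
#' Positions in micrometres from the ROI start (uniform step) and the
#' width-averaged fluorescence intensity at each position. This is the input
#' to multipeak fitting.
#'
#' @slot positions micrometres from the ROI start, strictly increasing,
#'   uniform step.
#' @slot intensities fluorescence intensities (AU), same length.
#' @slot source character label recording the ROI and image provenance.
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(positions = "numeric", intensities = "numeric",
                 source = "character"),
  validity = function(object) {
    n <- length(object@positions)
    if (n < 8L) return("profile must have at least 8 samples")
    if (length(object@intensities) != n)
      return("positions and intensities must have equal length")
    if (!all(is.finite(object@positions)) ||
        !all(is.finite(object@intensities)))
      return("profile values must be finite")
    steps <- diff(object@positions)
    if (any(steps <= 0)) return("positions must be strictly increasing")
    if (diff(range(steps)) > 1e-9 * max(steps))
      return("positions must be uniformly spaced")
    TRUE
  }
)

#' Configuration of the multipeak fit
#'
#' Controls peak initialization, the Levenberg-Marquardt optimisation and the
#' insufficient-intensity peak filter. All lengths are micrometres.
#'
#' @slot smoothingSigma Gaussian smoothing sigma used only to locate initial
#'   peak candidates.
#' @slot minProminenceFrac candidate peaks must rise above the baseline by at
#'   least this fraction of the tallest baseline-subtracted signal.
#' @slot sigmaBounds allowed (min, max) Gaussian peak sigma.
#' @slot minSeparation minimum center-to-center separation between candidate
#'   peaks; also sets the initial sigma (minSeparation / 4) and the
#'   collapsed-peak diagnostic threshold (minSeparation / 2).
#' @slot maxIterations Levenberg-Marquardt iteration cap.
#' @slot tolerance relative residual-sum-of-squares change declaring
#'   convergence.
#' @slot minAmplitudeFrac peaks with fitted amplitude below this fraction of
#'   the median fitted amplitude are excluded as having insufficient
#'   fluorescence intensity.
#' @exportClass FitConfig
setClass("FitConfig",
  representation(smoothingSigma = "numeric", minProminenceFrac = "numeric",
                 sigmaBounds = "numeric", minSeparation = "numeric",
                 maxIterations = "integer", tolerance = "numeric",
                 minAmplitudeFrac = "numeric"),
  validity = function(object) {
    if (object@smoothingSigma <= 0) return("smoothingSigma must be > 0")
    if (object@minProminenceFrac <= 0 || object@minProminenceFrac >= 1)
      return("minProminenceFrac must be in (0, 1)")
    if (length(object@sigmaBounds) != 2L ||
        object@sigmaBounds[1] <= 0 ||
        object@sigmaBounds[2] <= object@sigmaBounds[1])
      return("sigmaBounds must be an increasing positive pair")
    if (object@minSeparation <= 0) return("minSeparation must be > 0")
    if (object@maxIterations < 1L) return("maxIterations must be >= 1")
    if (object@tolerance <= 0) return("tolerance must be > 0")
    if (object@minAmplitudeFrac <= 0 || object@minAmplitudeFrac >= 1)
      return("minAmplitudeFrac must be in (0, 1)")
    TRUE
  }
)

#' Multipeak Gaussian fit with linear offset
#'
#' The fitted model is \eqn{Y = aX + b + \sum_i A_i \exp(-(X - \mu_i)^2 /
#' (2\sigma_i^2))}. Peaks are kept in order of increasing center; the
#' \code{kept} column of \code{peaks} records the insufficient-intensity
#' filter.
#'
#' @slot slopeA,interceptB linear offset parameters (AU/um and AU).
#' @slot peaks data.frame with columns center, amplitude, sigma (um / AU /
#'   um) and logical kept, ordered by center.
#' @slot rss residual sum of squares (AU^2).
#' @slot rSquared coefficient of determination.
#' @slot converged TRUE if the relative RSS change fell below the configured
#'   tolerance within the iteration cap.
#' @slot nIterations Levenberg-Marquardt iterations used.
#' @slot diagnostics list: rssTrace (accepted-iteration RSS values),
#'   collapsed flag and collapsedPairs, removedPeaks indices, info string.
#' @exportClass MultiPeakFit
setClass("MultiPeakFit",
  representation(slopeA = "numeric", interceptB = "numeric",
                 peaks = "data.frame", rss = "numeric", rSquared = "numeric",
                 converged = "logical", nIterations = "integer",
                 diagnostics = "list"),
  validity = function(object) {
    p <- object@peaks
    need <- c("center", "amplitude", "sigma", "kept")
    if (!all(need %in% names(p)))
      return("peaks must have columns center, amplitude, sigma, kept")
    if (nrow(p) > 1L && any(diff(p$center) < 0))
      return("peaks must be ordered by center")
    if (any(p$amplitude < 0)) return("amplitudes must be >= 0")
    if (any(p$sigma <= 0)) return("sigmas must be > 0")
    if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
      return("rSquared cannot exceed 1")
    TRUE
  }
)

#' Adjacent-peak spacing statistics
#'
#' Consecutive center-to-center distances of the fitted peaks. A distance is
#' kept only when both flanking peaks passed the intensity filter; distances
#' adjacent to a removed peak are excluded, never bridged. Mean, sample SD
#' and n summarise the kept distances only.
#'
#' @slot distances data.frame with columns index, leftCenter, rightCenter,
#'   distance (um) and logical kept.
#' @slot mean,sd mean and sample (n-1) standard deviation of kept distances.
#' @slot n number of kept distances.
#' @slot source character label of the originating fit.
#' @exportClass SpacingResult
setClass("SpacingResult",
  representation(distances = "data.frame", mean = "numeric", sd = "numeric",
                 n = "integer", source = "character"),
  validity = function(object) {
    need <- c("index", "leftCenter", "rightCenter", "distance", "kept")
    if (!all(need %in% names(object@distances)))
      return("distances must have columns index, leftCenter, rightCenter, distance, kept")
    if (any(object@distances$distance <= 0))
      return("all distances must be > 0")
    if (object@n != sum(object@distances$kept))
      return("n must equal the number of kept distances")
    TRUE
  }
)

#' Out-of-plane tilt geometry of a myocyte
#'
#' A myocyte whose long axis leaves the confocal image plane shows its
#' striation planes at an in-plane spacing larger than the true spacing. With
#' optical section thickness t and in-focus in-plane length Lmin, the tilt is
#' theta = arcsin(t / Lmin) and the overestimation factor is 1 / cos(theta).
#'
#' @slot lMin in-focus length in the image plane (um).
#' @slot sectionThickness optical slice thickness t (um).
#' @slot theta derived tilt angle in degrees.
#' @exportClass TiltGeometry
setClass("TiltGeometry",
  representation(lMin = "numeric", sectionThickness = "numeric",
                 theta = "numeric"),
  validity = function(object) {
    if (object@lMin <= 0) return("lMin must be > 0")
    if (object@sectionThickness < 0) return("sectionThickness must be >= 0")
    if (object@sectionThickness >= object@lMin)
      return("sectionThickness must be smaller than lMin (no real tilt solution otherwise)")
    TRUE
  }
)

#' Parameters of a synthetic striated scene
#'
#' Describes a confocal-like image of a striated myocyte: periodic bright
#' bands (Z-disks or T-tubules) with Gaussian cross-section, per-band
#' amplitudes, a linear background gradient along the myocyte axis, additive
#' Gaussian noise, an in-plane rotation and an optional out-of-plane tilt.
#' The scene (including its seed) fully determines the generated image.
#'
#' @slot trueSpacing band period along the myocyte axis (um).
#' @slot nBands number of bands.
#' @slot bandSigma Gaussian band half-width after PSF blur (um).
#' @slot bandAmplitudes per-band peak intensity above background (AU).
#' @slot baselineIntercept,baselineSlope linear background along the
#'   projected axis (AU and AU/um).
#' @slot inPlaneAngle myocyte axis vs image x-axis (degrees).
#' @slot tiltAngle axis vs image plane (degrees, 0 <= tilt < 90); the
#'   in-plane apparent spacing is trueSpacing / cos(tiltAngle).
#' @slot noiseSd additive Gaussian noise SD (AU).
#' @slot pixelSize um per pixel.
#' @slot imageShape integer (rows, cols) in pixels.
#' @slot seed integer RNG seed.
#' @exportClass StriationScene
setClass("StriationScene",
  representation(trueSpacing = "numeric", nBands = "integer",
                 bandSigma = "numeric", bandAmplitudes = "numeric",
                 baselineIntercept = "numeric", baselineSlope = "numeric",
                 inPlaneAngle = "numeric", tiltAngle = "numeric",
                 noiseSd = "numeric", pixelSize = "numeric",
                 imageShape = "integer", seed = "integer"),
  validity = function(object) {
    if (object@trueSpacing <= 0) return("trueSpacing must be > 0")
    if (object@nBands < 2L) return("nBands must be >= 2")
    if (object@bandSigma <= 0) return("bandSigma must be > 0")
    if (length(object@bandAmplitudes) != object@nBands)
      return("bandAmplitudes must have one value per band")
    if (any(object@bandAmplitudes < 0))
      return("bandAmplitudes must be >= 0")
    if (object@tiltAngle < 0 || object@tiltAngle >= 90)
      return("tiltAngle must satisfy 0 <= tilt < 90 degrees")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
      return("imageShape must be positive (rows, cols)")
    TRUE
  }
)

#' Ground truth attached to a synthetic image
#'
#' @slot bandCentersOnAxis band positions along the (possibly tilted)
#'   myocyte axis, um, consecutive positions differing by trueSpacing.
#' @slot apparentSpacing in-plane spacing, trueSpacing / cos(tiltAngle) (um).
#' @slot scene the generating [StriationScene-class].
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(bandCentersOnAxis = "numeric", apparentSpacing = "numeric",
                 scene = "StriationScene"),
  validity = function(object) {
    if (object@apparentSpacing < object@scene@trueSpacing - 1e-12)
      return("apparentSpacing cannot be smaller than trueSpacing")
    d <- diff(object@bandCentersOnAxis)
    if (any(abs(d - object@scene@trueSpacing) > 1e-9))
      return("consecutive band centers must differ by trueSpacing")
    TRUE
  }
)

#' Mean / SD / n summary of a group of distances
#'
#' @slot mean group mean (um).
#' @slot sd sample standard deviation (um).
#' @slot n number of observations.
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(mean = "numeric", sd = "numeric", n = "integer"),
  validity = function(object) {
    if (object@n < 2L) return("n must be >= 2")
    if (object@sd < 0) return("sd must be >= 0")
    TRUE
  }
)

#' Result of a two-group hypothesis test
#'
#' @slot statistic test statistic.
#' @slot df degrees of freedom (possibly fractional; NA when not applicable).
#' @slot pValue two-sided p-value.
#' @slot method test label.
#' @slot groups labels of the two compared groups.
#' @exportClass TestResult
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character", groups = "character"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      return("pValue must be in [0, 1]")
    TRUE
  }
)

#' All-pairs comparison result
#'
#' Symmetric matrices of standardized statistics and p-values over k groups,
#' with 1 on the p-value diagonal by convention.
#'
#' @slot statistics k x k matrix of standardized pairwise statistics.
#' @slot pValues k x k symmetric p-value matrix, unit diagonal.
#' @slot method test label.
#' @slot groupSizes integer vector of group sizes.
#' @exportClass PairwiseComparison
setClass("PairwiseComparison",
  representation(statistics = "matrix", pValues = "matrix",
                 method = "character", groupSizes = "integer"),
  validity = function(object) {
    p <- object@pValues
    if (nrow(p) != ncol(p)) return("pValues must be square")
    if (max(abs(p - t(p)), na.rm = TRUE) > 1e-12)
      return("pValues must be symmetric")
    offdiag <- p[row(p) != col(p)]
    if (any(offdiag < -1e-12 | offdiag > 1 + 1e-12, na.rm = TRUE))
      return("p-values must lie in [0, 1]")
    TRUE
  }
)
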