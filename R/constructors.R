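#' Create a FluorImage
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixelSize micrometres per pixel.
#' @return A [FluorImage-class].
#' @examples
#' img <- fluorImage(matrix(runif(100), 10), pixelSize = 0.27)
#' dim(pixels(img))
#' @export
fluorImage <- function(pixels, pixelSize) {
  new("FluorImage", pixels = as.matrix(pixels),
      pixelSize = as.numeric(pixelSize))
}

#' Create a FrameStack
#'
#' @param frames list of numeric matrices or of [FluorImage-class] objects
#'   with identical geometry.
#' @param pixelSize micrometres per pixel (taken from the first FluorImage
#'   when omitted).
#' @return A [FrameStack-class].
#' @export
frameStack <- function(frames, pixelSize = NULL) {
  if (length(frames) && methods::is(frames[[1]], "FluorImage")) {
    if (is.null(pixelSize)) pixelSize <- pixelSize(frames[[1]])
    frames <- lapply(frames, pixels)
  }
  if (is.null(pixelSize))
    stop("pixelSize must be given when frames are plain matrices")
  new("FrameStack", frames = frames, pixelSize = as.numeric(pixelSize))
}

#' Create a line ROI
#'
#' @param p0,p1 numeric (x, y) endpoints in continuous pixel coordinates
#'   (origin at the center of the top-left pixel, x right, y down).
#' @param width odd integer band width in pixels (the classic profiling
#'   width for striation analysis is 5).
#' @return A [LineROI-class].
#' @examples
#' roi <- lineROI(c(10, 10), c(110, 10), width = 5)
#' @export
lineROI <- function(p0, p1, width = 5L) {
  if (length(width) != 1L || is.na(width) || width != as.integer(width))
    stop("width must be a single integer")
  new("LineROI", p0 = as.numeric(p0), p1 = as.numeric(p1),
      width = as.integer(width))
}

#' Create an intensity profile directly
#'
#' Mostly used internally by [extractProfile()] and by simulation helpers;
#' positions must be uniformly spaced.
#'
#' @param positions micrometres from the profile start.
#' @param intensities fluorescence intensities (AU).
#' @param source provenance label.
#' @return An [IntensityProfile-class].
#' @export
intensityProfile <- function(positions, intensities, source = "manual") {
  new("IntensityProfile", positions = as.numeric(positions),
      intensities = as.numeric(intensities), source = source)
}

#' Fit configuration with field-standard defaults
#'
#' Defaults suit confocal striation profiles sampled near 0.27 um/px:
#' initialization smoothing of 0.2 um, candidate prominence at 10% of the
#' strongest baseline-subtracted signal, candidate separation of at least
#' 1 um (below the physiological striation range of 1.2-2.4 um), peak sigma
#' bounded in [0.1, 1] um, and the insufficient-intensity filter at 20% of
#' the median fitted amplitude.
#'
#' @param smoothingSigma um, Gaussian smoothing for initialization only.
#' @param minProminenceFrac fraction of the max baseline-subtracted signal a
#'   candidate peak must reach.
#' @param sigmaBounds um, allowed peak sigma interval.
#' @param minSeparation um, minimum candidate separation.
#' @param maxIterations Levenberg-Marquardt iteration cap.
#' @param tolerance relative RSS change declaring convergence.
#' @param minAmplitudeFrac insufficient-intensity threshold as a fraction of
#'   the median fitted amplitude.
#' @return A [FitConfig-class].
#' @export
fitConfig <- function(smoothingSigma = 0.2, minProminenceFrac = 0.1,
                      sigmaBounds = c(0.1, 1.0), minSeparation = 1.0,
                      maxIterations = 200L, tolerance = 1e-8,
                      minAmplitudeFrac = 0.2) {
  new("FitConfig", smoothingSigma = smoothingSigma,
      minProminenceFrac = minProminenceFrac, sigmaBounds = sigmaBounds,
      minSeparation = minSeparation,
      maxIterations = as.integer(maxIterations), tolerance = tolerance,
      minAmplitudeFrac = minAmplitudeFrac)
}

#' Summary statistics of a group of distances
#'
#' @param mean group mean (um).
#' @param sd sample standard deviation (um).
#' @param n number of observations.
#' @return A [SummaryStats-class].
#' @examples
#' summaryStats(2.18, 0.13, 9)
#' @export
summaryStats <- function(mean, sd, n) {
  new("SummaryStats", mean = as.numeric(mean), sd = as.numeric(sd),
      n = as.integer(n))
}
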