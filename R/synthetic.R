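# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Define a synthetic striated-myocyte scene
#'
#' Constructs the full parameter set of a confocal-like image of a striated
#' myocyte: \code{nBands} bright bands of Gaussian cross-section (half-width
#' \code{bandSigma}, the point-spread-function-blurred band profile) spaced
#' \code{trueSpacing} um along the myocyte axis, a linear background gradient
#' along that axis, additive Gaussian noise and an optional out-of-plane
#' tilt. The in-plane (apparent) band spacing is
#' \code{trueSpacing / cos(tiltAngle)}.
#'
#' Per-band amplitudes default to independent draws from
#' \code{[0.5, 1] * amplitudeMax}, reproducing the band-to-band intensity
#' variation seen along real myocytes; pass an explicit
#' \code{bandAmplitudes} vector for deterministic control (e.g. to plant a
#' low-intensity band for filter tests). The draw is seeded from \code{seed},
#' so a scene is fully reproducible.
#'
#' @param trueSpacing band period along the myocyte axis, um.
#' @param nBands number of bands (>= 2).
#' @param bandSigma Gaussian band half-width, um.
#' @param bandAmplitudes optional numeric vector of per-band amplitudes (AU);
#'   when NULL they are drawn uniformly in [0.5, 1] * amplitudeMax.
#' @param amplitudeMax amplitude scale used for the default draw, AU.
#' @param snr when given, sets \code{noiseSd = mean(bandAmplitudes) / snr}.
#' @param noiseSd additive Gaussian noise SD, AU (ignored when \code{snr} is
#'   given).
#' @param baselineIntercept,baselineSlope linear background (AU, AU/um).
#' @param inPlaneAngle myocyte axis vs image x-axis, degrees.
#' @param tiltAngle myocyte axis vs image plane, degrees in [0, 90).
#' @param pixelSize um per pixel; 0.27 matches a 512-px field of ~138 um with
#'   a 60x objective.
#' @param imageShape integer (rows, cols) of the raster.
#' @param seed integer RNG seed; with the other fields it fully determines
#'   the generated image.
#' @return A [StriationScene-class].
#' @examples
#' sc <- striationScene(trueSpacing = 1.92, nBands = 10, snr = 10, seed = 1)
#' sim <- generateStriationImage(sc)
#' apparentSpacing(sim$truth)
#' @export
striationScene <- function(trueSpacing = 2.0, nBands = 10L, bandSigma = 0.3,
                           bandAmplitudes = NULL, amplitudeMax = 100,
                           snr = NULL, noiseSd = 0,
                           baselineIntercept = 20, baselineSlope = 0.5,
                           inPlaneAngle = 0, tiltAngle = 0,
                           pixelSize = 0.27, imageShape = c(40L, 128L),
                           seed = 1L) {
  nBands <- as.integer(nBands)
  seed <- as.integer(seed)
  if (is.null(bandAmplitudes)) {
    if (nBands < 1L) stop("nBands must be >= 2")
    # amplitude draw uses its own stream so image noise is not entangled
    bandAmplitudes <- withSeed(seed, stats::runif(nBands, 0.5, 1)) *
      amplitudeMax
  }
  if (!is.null(snr)) {
    if (snr <= 0) stop("snr must be > 0")
    noiseSd <- mean(bandAmplitudes) / snr
  }
  new("StriationScene", trueSpacing = trueSpacing, nBands = nBands,
      bandSigma = bandSigma, bandAmplitudes = as.numeric(bandAmplitudes),
      baselineIntercept = baselineIntercept, baselineSlope = baselineSlope,
      inPlaneAngle = inPlaneAngle, tiltAngle = tiltAngle, noiseSd = noiseSd,
      pixelSize = pixelSize, imageShape = as.integer(imageShape),
      seed = seed)
}

# Projected-axis coordinate (um) of every pixel center, plus the apparent
# band centers (um) on that coordinate, centered in the image.
sceneGeometry <- function(scene) {
  rows <- scene@imageShape[1]; cols <- scene@imageShape[2]
  a <- scene@inPlaneAngle * pi / 180
  ca <- cos(a); sa <- sin(a)
  x <- matrix(rep(0:(cols - 1L), each = rows), rows, cols)
  y <- matrix(rep(0:(rows - 1L), times = cols), rows, cols)
  s <- (x * ca + y * sa) * scene@pixelSize
  apparent <- scene@trueSpacing / cos(scene@tiltAngle * pi / 180)
  cx <- (cols - 1) / 2; cy <- (rows - 1) / 2
  s0 <- (cx * ca + cy * sa) * scene@pixelSize
  idx <- seq_len(scene@nBands)
  mu <- s0 + (idx - (scene@nBands + 1) / 2) * apparent
  extent <- (abs(ca) * (cols - 1) + abs(sa) * (rows - 1)) * scene@pixelSize
  list(s = s, mu = mu, apparent = apparent, extent = extent)
}

# Noiseless intensity at projected-axis coordinates s (um): linear baseline
# plus the sum of Gaussian bands.
bandModel <- function(s, mu, amplitudes, bandSigma, intercept, slope) {
  out <- intercept + slope * s
  for (i in seq_along(mu))
    out <- out + amplitudes[i] * exp(-(s - mu[i])^2 / (2 * bandSigma^2))
  out
}

#' Render a synthetic striated image with its ground truth
#'
#' The noiseless pixel value at projected-axis coordinate s is
#' \code{baselineIntercept + baselineSlope * s + sum_i A_i *
#' exp(-(s - mu_i)^2 / (2 bandSigma^2))}, with band centers mu_i spaced by
#' the apparent (tilt-projected) spacing and rotated in-plane by
#' \code{inPlaneAngle}. Gaussian noise of SD \code{noiseSd} is added when
#' positive. The same scene always renders the identical image.
#'
#' @param scene a [StriationScene-class].
#' @return A list with elements \code{image} ([FluorImage-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @export
generateStriationImage <- function(scene) {
  sim <- renderFrame(scene, frame = 1L)
  list(image = sim$image, truth = sim$truth)
}

renderFrame <- function(scene, frame) {
  g <- sceneGeometry(scene)
  span <- (scene@nBands - 1) * g$apparent + 6 * scene@bandSigma
  if (span > g$extent)
    stop(sprintf(paste0("image too small: %d bands at apparent spacing ",
                        "%.3f um need %.2f um along the axis but the image ",
                        "provides %.2f um"),
                 scene@nBands, g$apparent, span, g$extent))
  px <- bandModel(g$s, g$mu, scene@bandAmplitudes, scene@bandSigma,
                  scene@baselineIntercept, scene@baselineSlope)
  if (scene@noiseSd > 0) {
    noise <- withSeed(frameSeed(scene@seed, frame),
                      stats::rnorm(length(px), 0, scene@noiseSd))
    px <- px + matrix(noise, nrow(px), ncol(px))
  }
  truth <- new("GroundTruth",
               bandCentersOnAxis = (seq_len(scene@nBands) -
                                    (scene@nBands + 1) / 2) *
                                   scene@trueSpacing,
               apparentSpacing = g$apparent, scene = scene)
  list(image = fluorImage(px, scene@pixelSize), truth = truth)
}

# Deterministic per-frame noise sub-seed, kept inside 32-bit integer range.
frameSeed <- function(seed, frame) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(frame)
}

#' Render a multi-frame stack sharing one noiseless signal
#'
#' All frames render the same noiseless scene; noise is drawn independently
#' per frame from sub-seeds derived deterministically from \code{scene@seed},
#' so frame 1 is identical to [generateStriationImage()] of the same scene.
#'
#' @param scene a [StriationScene-class].
#' @param nFrames number of frames (>= 1).
#' @return A list with elements \code{stack} ([FrameStack-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @export
generateFrameStack <- function(scene, nFrames) {
  nFrames <- as.integer(nFrames)
  if (is.na(nFrames) || nFrames < 1L) stop("nFrames must be >= 1")
  sims <- lapply(seq_len(nFrames), function(f) renderFrame(scene, f))
  list(stack = frameStack(lapply(sims, function(s) pixels(s$image)),
                          pixelSize = scene@pixelSize),
       truth = sims[[1]]$truth)
}

#' Noiseless model intensity along the myocyte axis of a scene
#'
#' Evaluates the analytic band model at given projected-axis coordinates;
#' useful as an oracle when validating rendered images and extracted
#' profiles.
#'
#' @param scene a [StriationScene-class].
#' @param s projected-axis coordinates, um.
#' @return Numeric vector of noiseless intensities (AU).
#' @export
sceneModel <- function(scene, s) {
  g <- sceneGeometry(scene)
  bandModel(s, g$mu, scene@bandAmplitudes, scene@bandSigma,
            scene@baselineIntercept, scene@baselineSlope)
}

#' Line ROI along the myocyte axis of a synthetic scene
#'
#' Builds the straight ROI a user would draw along the striation axis:
#' centered on the band train, long enough to cover all bands plus a margin,
#' oriented at the scene's in-plane angle.
#'
#' @param scene a [StriationScene-class].
#' @param width odd ROI width in pixels.
#' @param marginUm extra length beyond the outer bands at each end, um.
#' @return A [LineROI-class].
#' @export
axisROI <- function(scene, width = 5L, marginUm = 1.5) {
  g <- sceneGeometry(scene)
  a <- scene@inPlaneAngle * pi / 180
  u <- c(cos(a), sin(a))
  ctr <- c((scene@imageShape[2] - 1) / 2, (scene@imageShape[1] - 1) / 2)
  halfLenPx <- ((scene@nBands - 1) * g$apparent / 2 + marginUm) /
    scene@pixelSize
  lineROI(ctr - u * halfLenPx, ctr + u * halfLenPx, width = width)
}
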