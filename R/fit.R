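# Gaussian smoothing with edge renormalization; sigma in samples.
gaussSmooth <- function(y, sigmaSamples) {
  if (sigmaSamples <= 0) return(y)
  half <- max(1L, ceiling(4 * sigmaSamples))
  k <- exp(-((-half):half)^2 / (2 * sigmaSamples^2))
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(w * y[lo:hi]) / sum(w)
  }
  out
}

# Sum-of-Gaussians + linear offset model. par = c(a, b, A1, mu1, s1, ...).
evalMultiPeak <- function(par, x) {
  out <- par[1] * x + par[2]
  n <- (length(par) - 2L) %/% 3L
  for (i in seq_len(n)) {
    A <- par[3 * i]; mu <- par[3 * i + 1]; s <- par[3 * i + 2]
    out <- out + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  out
}

# Baseline guess: least-squares line through the profile's lower envelope
# (the samples at or below the median intensity).
baselineGuess <- function(x, y) {
  low <- y <= stats::median(y)
  fit <- stats::lm.fit(cbind(1, x[low]), y[low])
  c(a = unname(fit$coefficients[2]), b = unname(fit$coefficients[1]))
}

# Candidate peaks: local maxima of the smoothed, baseline-subtracted profile
# above the prominence threshold, thinned to the minimum separation
# (tallest first). Returns a data.frame ordered by position.
findCandidates <- function(profile, cfg) {
  x <- profile@positions; y <- profile@intensities
  step <- x[2] - x[1]
  bl <- baselineGuess(x, y)
  g <- gaussSmooth(y - (bl["a"] * x + bl["b"]), cfg@smoothingSigma / step)
  top <- max(g)
  n <- length(g)
  if (top <= 1e-8 * max(abs(y), 1e-300))
    return(list(baseline = bl,
                candidates = data.frame(center = numeric(0),
                                        amplitude = numeric(0))))
  i <- 2:(n - 1)
  isMax <- g[i] >= g[i - 1] & g[i] > g[i + 1] &
    g[i] >= cfg@minProminenceFrac * top
  cand <- i[isMax]
  cand <- cand[order(g[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (ci in cand)
    if (!length(kept) || all(abs(x[ci] - x[kept]) >= cfg@minSeparation))
      kept <- c(kept, ci)
  kept <- sort(kept)
  list(baseline = bl,
       candidates = data.frame(center = x[kept], amplitude = g[kept]))
}

newMultiPeakFit <- function(a, b, peaksDF, x, y, converged = FALSE,
                            nIterations = 0L, diagnostics = list()) {
  par <- c(a, b, as.vector(rbind(peaksDF$amplitude, peaksDF$center,
                                 peaksDF$sigma)))
  a <- unname(a); b <- unname(b)
  resid <- y - evalMultiPeak(par, x)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  new("MultiPeakFit", slopeA = a, interceptB = b, peaks = peaksDF,
      rss = rss, rSquared = if (tss > 0) 1 - rss / tss else NA_real_,
      converged = converged, nIterations = as.integer(nIterations),
      diagnostics = diagnostics)
}

#' Initial guess for the multipeak fit
#'
#' Builds the starting point of the Levenberg-Marquardt optimisation: the
#' baseline from a least-squares line through the profile's lower envelope
#' (samples at or below the median), and one candidate peak per local
#' maximum of the Gaussian-smoothed, baseline-subtracted profile whose
#' height reaches \code{minProminenceFrac} of the strongest signal, with
#' mutual separation of at least \code{minSeparation}. Initial sigma is
#' \code{minSeparation / 4}.
#'
#' @param profile an [IntensityProfile-class].
#' @param cfg a [FitConfig-class].
#' @return A [MultiPeakFit-class] holding the initial guess
#'   (\code{converged = FALSE}).
#' @export
initializePeaks <- function(profile, cfg = fitConfig()) {
  fc <- findCandidates(profile, cfg)
  if (nrow(fc$candidates) < 2L)
    stop("insufficient striations: fewer than 2 candidate peaks found")
  sigma0 <- clampSigma(cfg@minSeparation / 4, cfg)
  peaksDF <- data.frame(center = fc$candidates$center,
                        amplitude = fc$candidates$amplitude,
                        sigma = sigma0, kept = TRUE)
  newMultiPeakFit(fc$baseline["a"], fc$baseline["b"], peaksDF,
                  profile@positions, profile@intensities,
                  diagnostics = list(info = "initial guess"))
}

clampSigma <- function(s, cfg) {
  min(max(s, cfg@sigmaBounds[1]), cfg@sigmaBounds[2])
}

# Extend or truncate the candidate list to exactly nPeaks entries.
adjustCandidates <- function(cand, nPeaks, profile, cfg) {
  if (nrow(cand) > nPeaks) {
    cand <- cand[order(cand$amplitude, decreasing = TRUE), ][seq_len(nPeaks), ]
    return(cand[order(cand$center), ])
  }
  span <- range(profile@positions)
  defaultAmp <- if (nrow(cand)) stats::median(cand$amplitude) else
    max(profile@intensities) - min(profile@intensities)
  side <- 1
  while (nrow(cand) < nPeaks) {
    base <- if (nrow(cand)) cand$center[which.max(cand$amplitude)] else
      mean(span)
    pos <- min(max(base + side * cfg@minSeparation / 2, span[1]), span[2])
    cand <- rbind(cand, data.frame(center = pos, amplitude = defaultAmp))
    side <- -side * 1.5
  }
  cand[order(cand$center), ]
}

#' Fit a sum of Gaussians plus a linear offset by Levenberg-Marquardt
#'
#' Minimizes \eqn{\sum_j (Y_j - [aX_j + b + \sum_i A_i \exp(-(X_j -
#' \mu_i)^2 / (2\sigma_i^2))])^2} by damped least squares starting from
#' [initializePeaks()]. Parameters are box-bounded: centers within the
#' profile span, sigma within \code{sigmaBounds}, amplitudes non-negative.
#' The fit is deterministic. Non-convergence is reported via
#' \code{converged = FALSE}, never an error. Overfitting is flagged in the
#' diagnostics as \code{collapsed}: peaks whose centers end up closer than
#' \code{minSeparation / 2} (\code{collapsedPairs}) or whose amplitude fell
#' to zero (\code{degeneratePeaks}).
#'
#' @param profile an [IntensityProfile-class].
#' @param cfg a [FitConfig-class].
#' @param nPeaks optional forced number of peaks (>= 2); by default the
#'   number of initialization candidates is used.
#' @return A [MultiPeakFit-class] with peaks ordered by center.
#' @export
fitMultiPeak <- function(profile, cfg = fitConfig(), nPeaks = NULL) {
  x <- profile@positions; y <- profile@intensities
  if (is.null(nPeaks)) {
    init <- initializePeaks(profile, cfg)
    cand <- init@peaks[, c("center", "amplitude")]
    baseline <- c(a = init@slopeA, b = init@interceptB)
  } else {
    nPeaks <- as.integer(nPeaks)
    if (nPeaks < 2L) stop("nPeaks must be >= 2")
    fc <- findCandidates(profile, cfg)
    cand <- adjustCandidates(fc$candidates, nPeaks, profile, cfg)
    baseline <- fc$baseline
  }
  n <- nrow(cand)
  sigma0 <- clampSigma(cfg@minSeparation / 4, cfg)
  par0 <- c(unname(baseline["a"]), unname(baseline["b"]),
            as.vector(rbind(pmax(cand$amplitude, 1e-12), cand$center,
                            rep(sigma0, n))))
  span <- range(x)
  lower <- c(-Inf, -Inf, rep(c(0, span[1], cfg@sigmaBounds[1]), n))
  upper <- c(Inf, Inf, rep(c(Inf, span[2], cfg@sigmaBounds[2]), n))

  lm <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) y - evalMultiPeak(p, x),
    control = minpack.lm::nls.lm.control(
      maxiter = cfg@maxIterations, ftol = cfg@tolerance, ptol = 1e-12))

  p <- lm$par
  peaksDF <- data.frame(center = p[3 * seq_len(n) + 1],
                        amplitude = p[3 * seq_len(n)],
                        sigma = p[3 * seq_len(n) + 2], kept = TRUE)
  peaksDF <- peaksDF[order(peaksDF$center), ]
  rownames(peaksDF) <- NULL

  trace <- lm$rsstrace
  relChange <- if (length(trace) >= 2L) {
    last <- trace[length(trace) - 1:0]
    abs(diff(last)) / max(last[1], 1e-300)
  } else 0
  conv <- (lm$info %in% 1:3 || relChange < cfg@tolerance) &&
    lm$niter <= cfg@maxIterations
  gaps <- diff(peaksDF$center)
  collapsedPairs <- which(gaps < cfg@minSeparation / 2)
  degenerate <- which(peaksDF$amplitude < 1e-6 * max(peaksDF$amplitude))
  newMultiPeakFit(p[1], p[2], peaksDF, x, y, converged = conv,
                  nIterations = lm$niter,
                  diagnostics = list(
                    rssTrace = trace, info = lm$message,
                    collapsed = length(collapsedPairs) > 0L ||
                      length(degenerate) > 0L,
                    collapsedPairs = collapsedPairs,
                    degeneratePeaks = degenerate,
                    removedPeaks = integer(0)))
}

#' Exclude peaks with insufficient fluorescence intensity
#'
#' Striations whose fitted amplitude falls below \code{minAmplitudeFrac}
#' times the median fitted amplitude are excluded from spacing computation.
#' Excluded peaks keep their fitted centers and remain listed with
#' \code{kept = FALSE}; [computeSpacings()] drops the distances adjacent to
#' an excluded peak rather than bridging across it (a bridged distance would
#' be roughly twice the spacing and corrupt the mean).
#'
#' @param fit a [MultiPeakFit-class] with at least two peaks.
#' @param cfg a [FitConfig-class]; \code{minAmplitudeFrac} sets the
#'   threshold.
#' @return The fit with the \code{kept} column updated and removed indices
#'   recorded in \code{diagnostics$removedPeaks}.
#' @export
filterPeaks <- function(fit, cfg = fitConfig()) {
  p <- fit@peaks
  if (nrow(p) < 2L) stop("filterPeaks needs a fit with >= 2 peaks")
  thr <- cfg@minAmplitudeFrac * stats::median(p$amplitude)
  keep <- p$amplitude >= thr
  if (sum(keep) < 2L)
    stop("insufficient striations after filtering: fewer than 2 peaks ",
         "meet the intensity threshold")
  fit@peaks$kept <- keep
  fit@diagnostics$removedPeaks <- which(!keep)
  fit@diagnostics$amplitudeThreshold <- thr
  fit
}
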