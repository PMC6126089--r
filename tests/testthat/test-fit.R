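# Build a profile directly from the analytic model.
modelProfile <- function(a, b, A, mu, sigma, from, to, step = 0.27) {
  x <- seq(from, to, by = step)
  intensityProfile(x, oracleModel(a, b, A, mu, sigma, x), source = "model")
}

test_that("initialization finds every band of a noiseless profile", {
  sc <- striationScene(trueSpacing = 2, nBands = 10, noiseSd = 0, seed = 6)
  roi <- sceneROI(sc)
  prof <- extractProfile(generateStriationImage(sc)$image, roi)
  init <- initializePeaks(prof)
  expect_equal(nrow(peaks(init)), 10L)
  expected <- expectedProfileCenters(sc, roi)
  expect_true(all(abs(peaks(init)$center - expected) <= sc@pixelSize))
})

test_that("a pure linear ramp has insufficient striations", {
  x <- seq(0, 30, by = 0.27)
  prof <- intensityProfile(x, 5 + 2 * x)
  expect_error(initializePeaks(prof), "insufficient striations")
})

test_that("candidates below the prominence threshold are dropped", {
  amps <- rep(100, 10); amps[4] <- 5
  sc <- striationScene(trueSpacing = 2, nBands = 10, bandAmplitudes = amps,
                       noiseSd = 0, baselineSlope = 0, seed = 2)
  prof <- extractProfile(generateStriationImage(sc)$image, sceneROI(sc))
  init <- initializePeaks(prof, fitConfig(minProminenceFrac = 0.1))
  expect_equal(nrow(peaks(init)), 9L)
})

test_that("noiseless profiles are recovered to high relative accuracy", {
  a <- 0.8; b <- 15
  A <- c(60, 90, 75, 82, 66)
  mu <- c(3, 5.1, 7.0, 9.2, 11.1)
  sigma <- c(0.28, 0.33, 0.30, 0.26, 0.31)
  prof <- modelProfile(a, b, A, mu, sigma, 0, 14.3)
  fit <- fitMultiPeak(prof, fitConfig(tolerance = 1e-14))
  expect_true(converged(fit))
  p <- peaks(fit)
  expect_equal(nrow(p), 5L)
  expect_lt(max(abs(p$center - mu) / mu), 1e-6)
  expect_lt(max(abs(p$amplitude - A) / A), 1e-6)
  expect_lt(max(abs(p$sigma - sigma) / sigma), 1e-6)
  expect_lt(abs(fit@slopeA - a) / a, 1e-6)
  expect_lt(abs(fit@interceptB - b) / b, 1e-6)
  expect_gt(fit@rSquared, 1 - 1e-10)
})

test_that("accepted Levenberg-Marquardt iterations never increase the RSS", {
  sc <- striationScene(trueSpacing = 1.9, snr = 8, seed = 13)
  prof <- extractProfile(generateStriationImage(sc)$image, sceneROI(sc))
  fit <- fitMultiPeak(prof)
  trace <- fit@diagnostics$rssTrace
  expect_gte(length(trace), 2L)
  expect_true(all(diff(trace) <= 1e-9 * trace[-length(trace)]))
})

test_that("the fit is equivariant to position shifts and intensity scaling", {
  A <- c(70, 85, 60); mu <- c(2.5, 4.6, 6.5); sg <- c(0.3, 0.27, 0.35)
  prof <- modelProfile(0.5, 10, A, mu, sg, 0, 9)
  fit <- fitMultiPeak(prof, fitConfig(tolerance = 1e-12))

  shifted <- intensityProfile(positions(prof) + 3.2, intensities(prof))
  fitS <- fitMultiPeak(shifted, fitConfig(tolerance = 1e-12))
  expect_equal(peaks(fitS)$center, peaks(fit)$center + 3.2,
               tolerance = 1e-6)
  expect_equal(peaks(fitS)$sigma, peaks(fit)$sigma, tolerance = 1e-6)
  expect_equal(peaks(fitS)$amplitude, peaks(fit)$amplitude,
               tolerance = 1e-6)

  scaled <- intensityProfile(positions(prof), intensities(prof) * 7.3)
  fitC <- fitMultiPeak(scaled, fitConfig(tolerance = 1e-12))
  expect_equal(peaks(fitC)$center, peaks(fit)$center, tolerance = 1e-6)
  expect_equal(peaks(fitC)$sigma, peaks(fit)$sigma, tolerance = 1e-6)
  expect_equal(peaks(fitC)$amplitude, peaks(fit)$amplitude * 7.3,
               tolerance = 1e-6)
  expect_equal(fitC@slopeA, fit@slopeA * 7.3, tolerance = 1e-6)
  expect_equal(fitC@interceptB, fit@interceptB * 7.3, tolerance = 1e-6)
})

test_that("forcing two peaks onto one Gaussian raises the collapse flag", {
  prof <- modelProfile(0, 5, A = 80, mu = 5, sigma = 0.4, 0, 10)
  fit <- fitMultiPeak(prof, nPeaks = 2)
  expect_true(fit@diagnostics$collapsed)
  expect_error(fitMultiPeak(prof, nPeaks = 1), "nPeaks")
})

test_that("non-convergence is reported, not thrown", {
  sc <- striationScene(trueSpacing = 2, snr = 6, seed = 17)
  prof <- extractProfile(generateStriationImage(sc)$image, sceneROI(sc))
  fit <- suppressWarnings(
    fitMultiPeak(prof, fitConfig(maxIterations = 1L, tolerance = 1e-15)))
  expect_s4_class(fit, "MultiPeakFit")
  expect_false(converged(fit))
})

test_that("intensity filter removes only insufficient peaks", {
  even <- new("MultiPeakFit", slopeA = 0, interceptB = 0,
              peaks = data.frame(center = 1:5, amplitude = 50, sigma = 0.3,
                                 kept = TRUE),
              rss = 0, rSquared = 1, converged = TRUE, nIterations = 1L,
              diagnostics = list())
  expect_true(all(peaks(filterPeaks(even))$kept))

  amps <- rep(100, 10); amps[4] <- 10 # 10% of the median
  weak <- new("MultiPeakFit", slopeA = 0, interceptB = 0,
              peaks = data.frame(center = 1:10 * 2, amplitude = amps,
                                 sigma = 0.3, kept = TRUE),
              rss = 0, rSquared = 1, converged = TRUE, nIterations = 1L,
              diagnostics = list())
  filtered <- filterPeaks(weak, fitConfig(minAmplitudeFrac = 0.2))
  expect_equal(sum(peaks(filtered)$kept), 9L)
  expect_identical(filtered@diagnostics$removedPeaks, 4L)
  expect_equal(peaks(filtered)$center, peaks(weak)$center)

  allWeak <- new("MultiPeakFit", slopeA = 0, interceptB = 0,
                 peaks = data.frame(center = c(1, 2), amplitude = c(100, 1),
                                    sigma = 0.3, kept = TRUE),
                 rss = 0, rSquared = 1, converged = TRUE, nIterations = 1L,
                 diagnostics = list())
  expect_error(filterPeaks(allWeak, fitConfig(minAmplitudeFrac = 0.5)),
               "insufficient striations after filtering")
})
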