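peakFit <- function(centers, amplitudes = rep(50, length(centers)),
                    kept = rep(TRUE, length(centers))) {
  new("MultiPeakFit", slopeA = 0, interceptB = 0,
      peaks = data.frame(center = centers, amplitude = amplitudes,
                         sigma = 0.3, kept = kept),
      rss = 0, rSquared = 1, converged = TRUE, nIterations = 1L,
      diagnostics = list())
}

test_that("adjacent-peak distances and their summary are exact", {
  sp <- computeSpacings(peakFit(c(0, 2, 4)))
  expect_equal(distances(sp)$distance, c(2, 2))
  expect_equal(spacingMean(sp), 2.0)
  expect_equal(spacingSD(sp), 0.0)
  expect_equal(nSpacings(sp), 2L)

  sp2 <- computeSpacings(peakFit(c(0, 1.9, 3.9, 6.0)))
  expect_equal(distances(sp2)$distance, c(1.9, 2.0, 2.1))
  expect_equal(spacingMean(sp2), 2.0)
  expect_equal(spacingSD(sp2), 0.1) # sample (n-1) SD
  expect_equal(nSpacings(sp2), 3L)

  # ten kept striation peaks yield nine spacings
  sp3 <- computeSpacings(peakFit(seq(0, 19.8, by = 2.2)))
  expect_equal(nSpacings(sp3), 9L)
})

test_that("distances adjacent to a removed peak are dropped, not bridged", {
  centers <- c(0, 2, 4, 6, 8)
  kept <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  sp <- computeSpacings(peakFit(centers, kept = kept))
  d <- distances(sp)
  expect_equal(nrow(d), 4L)
  expect_equal(d$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(nSpacings(sp), 2L)
  expect_false(any(d$distance > 3.9)) # no synthesized 2x distance
  # kept + excluded distances still tile the full span
  expect_equal(sum(d$distance), max(centers) - min(centers))
  expect_error(computeSpacings(peakFit(c(0, 2, 4), kept = c(TRUE, FALSE,
                                                            FALSE))),
               "kept peaks")
})

test_that("spacing statistics are invariant to profile direction", {
  sc <- striationScene(trueSpacing = 1.9, snr = 10, seed = 23)
  img <- generateStriationImage(sc)$image
  roi0 <- sceneROI(sc)
  # integer-length ROI so both directions sample identical points
  u <- (roi0@p1 - roi0@p0) / sqrt(sum((roi0@p1 - roi0@p0)^2))
  p1 <- roi0@p0 + u * floor(sqrt(sum((roi0@p1 - roi0@p0)^2)))
  fwd <- analyzeImage(img, lineROI(roi0@p0, p1, 5))$spacing
  bwd <- analyzeImage(img, lineROI(p1, roi0@p0, 5))$spacing
  expect_equal(spacingMean(bwd), spacingMean(fwd), tolerance = 1e-6)
  expect_equal(spacingSD(bwd), spacingSD(fwd), tolerance = 1e-5)
})

test_that("tilt overestimation follows 1/cos(arcsin(t/Lmin))", {
  expect_identical(tiltOverestimation(tiltGeometry(70, 0)), 1.0)
  g30 <- tiltGeometry(10, 5) # t/Lmin = 0.5 -> theta = 30 deg
  expect_equal(g30@theta, 30, tolerance = 1e-12)
  expect_equal(tiltOverestimation(g30), 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(tiltOverestimation(g30), 1.1547, tolerance = 1e-4)

  # the default section thickness keeps the bias at ~2% for Lmin = 70 um
  f70 <- tiltOverestimation(tiltGeometry(70))
  expect_equal(f70, 1.02, tolerance = 5e-4)
  # and inverting the closed form reproduces the implied thickness
  tImplied <- 70 * sin(acos(1 / 1.02))
  expect_equal(tImplied, 13.8, tolerance = 0.01)
  expect_equal(correctSpacing(2.04, tiltGeometry(70, tImplied)), 2.0,
               tolerance = 1e-3)

  expect_error(tiltGeometry(10, 10), "smaller than lMin")
})

test_that("the tilt factor is monotone in t and Lmin and never below 1", {
  ts <- seq(1, 60, by = 5)
  f <- vapply(ts, function(t) tiltOverestimation(tiltGeometry(70, t)),
              numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 1))
  ls <- seq(20, 120, by = 10)
  g <- vapply(ls, function(L) tiltOverestimation(tiltGeometry(L, 13.8)),
              numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("labeled fraction counts above-threshold area", {
  checker <- matrix(c(0, 100), 20, 20)
  expect_equal(labeledFraction(fluorImage(checker, 1), threshold = 50)$fraction,
               0.5)
  bright <- fluorImage(matrix(10, 5, 5), 1)
  expect_equal(labeledFraction(bright, threshold = 5)$fraction, 1.0)
  expect_error(labeledFraction(bright, "auto"), "constant")

  # a field with ~10% labeled myocyte area, auto-thresholded
  set.seed(42)
  field <- matrix(rnorm(200 * 200, 10, 2), 200, 200)
  lab <- matrix(FALSE, 200, 200)
  lab[60:100, 52:148] <- TRUE # 41 x 97 block ~ 9.9% of the field
  field[lab] <- rnorm(sum(lab), 100, 5)
  res <- labeledFraction(fluorImage(field, 0.27), "auto")
  expect_equal(res$method, "otsu")
  expect_equal(res$fraction, mean(lab), tolerance = 0.02)
  expect_gt(res$threshold, 20)
  expect_lt(res$threshold, 90)
})
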