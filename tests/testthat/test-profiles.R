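test_that("a constant image yields a constant profile", {
  img <- fluorImage(matrix(7.5, 50, 120), 0.27)
  prof <- extractProfile(img, lineROI(c(5, 20.3), c(100, 35.7), width = 5))
  expect_true(all(abs(intensities(prof) - 7.5) < 1e-12))
})

test_that("sampling runs at 1-pixel steps with positions in micrometres", {
  img <- fluorImage(matrix(runif(50 * 120), 50, 120), 0.27)
  prof <- extractProfile(img, lineROI(c(10, 10), c(110, 10), width = 5))
  expect_equal(length(prof), 101L)
  expect_equal(positions(prof)[1], 0)
  expect_equal(diff(positions(prof)), rep(0.27, 100))
  expect_equal(max(positions(prof)), 27.0)
})

test_that("profiles of noiseless striations match the analytic model", {
  # grid-aligned axis ROI: every sample falls on pixel x-coordinates and
  # the band model does not vary with y, so bilinear sampling is exact
  sc <- striationScene(trueSpacing = 2, nBands = 9, noiseSd = 0, seed = 5)
  img <- generateStriationImage(sc)$image
  roi <- lineROI(c(4, 19.5), c(123, 19.5), width = 5)
  prof <- extractProfile(img, roi)
  s0 <- roi@p0[1] * sc@pixelSize
  expect_lt(max(abs(intensities(prof) -
                    sceneModel(sc, s0 + positions(prof)))), 1e-10)

  # rotated ROI samples off-grid: bilinear interpolation of a band of
  # sigma ~ 1.1 px stays within a few percent of the band amplitude
  scR <- striationScene(trueSpacing = 2, nBands = 8, noiseSd = 0,
                        inPlaneAngle = 20, imageShape = c(90L, 120L),
                        seed = 5)
  imgR <- generateStriationImage(scR)$image
  roiR <- sceneROI(scR)
  profR <- extractProfile(imgR, roiR)
  a <- 20 * pi / 180
  sP0 <- (roiR@p0[1] * cos(a) + roiR@p0[2] * sin(a)) * scR@pixelSize
  model <- sceneModel(scR, sP0 + positions(profR))
  expect_lt(max(abs(intensities(profR) - model)),
            0.08 * max(scR@bandAmplitudes))
})

test_that("reversing the ROI reverses the intensity sequence exactly", {
  set.seed(4)
  img <- fluorImage(matrix(runif(110 * 120), 110, 120), 0.27)
  # integer length (|d| = 100) so forward and reverse sample the same points
  fwd <- extractProfile(img, lineROI(c(10, 12), c(70, 92), width = 5))
  rev_ <- extractProfile(img, lineROI(c(70, 92), c(10, 12), width = 5))
  expect_equal(intensities(rev_), rev(intensities(fwd)), tolerance = 1e-12)
})

test_that("extraction is equivariant to whole-pixel translations", {
  set.seed(8)
  big <- matrix(runif(80 * 150), 80, 150)
  winA <- fluorImage(big[1:60, 1:120], 0.27)
  winB <- fluorImage(big[4:63, 6:125], 0.27) # content shifted by (-3, -5)
  roiA <- lineROI(c(20, 30), c(100, 42), width = 5)
  roiB <- lineROI(c(20 - 5, 30 - 3), c(100 - 5, 42 - 3), width = 5)
  expect_equal(intensities(extractProfile(winA, roiA)),
               intensities(extractProfile(winB, roiB)), tolerance = 1e-12)
})

test_that("an ROI band leaving the image is an error, not clamped", {
  img <- fluorImage(matrix(0, 40, 100), 0.27)
  expect_error(extractProfile(img, lineROI(c(-2, 10), c(50, 10), 5)),
               "bounds")
  # line inside but the width band pokes past the top edge
  expect_error(extractProfile(img, lineROI(c(5, 1), c(95, 1), 5)), "bounds")
  expect_silent(extractProfile(img, lineROI(c(5, 2), c(95, 2), 5)))
})

test_that("widening the ROI reduces profile noise on average", {
  deltas <- replicate(10, {
    seed <- sample.int(1e6, 1)
    sc <- striationScene(trueSpacing = 2, snr = 3, seed = seed,
                         imageShape = c(40L, 128L))
    img <- generateStriationImage(sc)$image
    roi1 <- axisROI(sc, width = 1L)
    roi5 <- axisROI(sc, width = 5L)
    noiseless <- generateStriationImage(
      striationScene(trueSpacing = 2, seed = seed, noiseSd = 0,
                     bandAmplitudes = sc@bandAmplitudes,
                     imageShape = c(40L, 128L)))$image
    n1 <- intensities(extractProfile(img, roi1)) -
      intensities(extractProfile(noiseless, roi1))
    n5 <- intensities(extractProfile(img, roi5)) -
      intensities(extractProfile(noiseless, roi5))
    var(n5) - var(n1)
  })
  expect_lt(mean(deltas), 0)
  expect_gt(mean(deltas < 0), 0.8)
})

test_that("superposing identical frames returns the frame", {
  m <- matrix(runif(30 * 40), 30, 40)
  st <- frameStack(list(m, m, m), pixelSize = 0.27)
  expect_equal(pixels(superpose(st)), m, tolerance = 1e-14)
})

test_that("averaging 25 frames cuts the noise about five-fold", {
  sc <- striationScene(trueSpacing = 2, snr = 4, seed = 31)
  st <- generateFrameStack(sc, 25)$stack
  noiseless <- pixels(generateStriationImage(
    striationScene(trueSpacing = 2, seed = 31, noiseSd = 0,
                   bandAmplitudes = sc@bandAmplitudes))$image)
  sdSingle <- sd(as.vector(frames(st)[[1]] - noiseless))
  sdAvg <- sd(as.vector(pixels(superpose(st)) - noiseless))
  expect_gt(sdSingle / sdAvg, 3.5)
  expect_lt(sdSingle / sdAvg, 6.5)
})

test_that("registration recovers known integer jitter", {
  set.seed(12)
  big <- matrix(runif(80 * 150), 80, 150) # textured in both directions
  jitter <- rbind(c(0, 0), c(2, -1), c(-2, 2), c(1, 2), c(-1, -2))
  # frame f shows what frame 1 shows at (r - sh1, c - sh2)
  frs <- apply(jitter, 1, function(sh) {
    big[(21:50) - sh[1], (21:120) - sh[2]]
  }, simplify = FALSE)
  st <- frameStack(frs, pixelSize = 0.27)
  est <- estimateShifts(st, maxShift = 4L)
  expect_equal(unname(est), -jitter)
  reg <- superpose(st, register = TRUE, maxShift = 4L)
  expect_equal(dim(pixels(reg)), c(30L, 100L))
  # registered average reproduces the common content at the overlap center
  expect_equal(pixels(reg)[10:20, 10:80], frs[[1]][10:20, 10:80],
               tolerance = 1e-12)
})

test_that("empty stacks are rejected", {
  expect_error(frameStack(list(), pixelSize = 0.27), "frame")
})
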