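#' Extract the width-averaged intensity profile along a line ROI
#'
#' Samples the image at 1-pixel steps along the p0 -> p1 axis. At each step
#' the intensity is the mean of \code{width} bilinear samples taken at unit
#' perpendicular offsets, symmetric about the line, mirroring the de facto
#' plot-profile convention of interactive striation analysis (ROI width 5).
#' Positions are returned in micrometres from the ROI start.
#'
#' The whole sampling band, including the perpendicular offsets, must lie
#' inside the image; an out-of-bounds band is an error, never silently
#' clamped.
#'
#' @param image a [FluorImage-class].
#' @param roi a [LineROI-class].
#' @return An [IntensityProfile-class] with samples at
#'   \code{t = 0, 1, ..., floor(|p1 - p0|)} pixels along the axis.
#' @export
extractProfile <- function(image, roi) {
  px <- image@pixels
  d <- roi@p1 - roi@p0
  len <- sqrt(sum(d^2))
  u <- d / len
  v <- c(-u[2], u[1])
  t <- 0:floor(len + 1e-9)
  off <- seq(-(roi@width - 1) / 2, (roi@width - 1) / 2)

  sx <- outer(t * u[1], off * v[1], "+") + roi@p0[1]
  sy <- outer(t * u[2], off * v[2], "+") + roi@p0[2]
  eps <- 1e-9
  if (min(sx) < -eps || max(sx) > ncol(px) - 1 + eps ||
      min(sy) < -eps || max(sy) > nrow(px) - 1 + eps)
    stop("ROI band exits the image bounds; shrink the ROI or its width")

  vals <- pracma::interp2(x = 0:(ncol(px) - 1L), y = 0:(nrow(px) - 1L),
                          Z = px,
                          xp = pmin(pmax(as.vector(sx), 0), ncol(px) - 1),
                          yp = pmin(pmax(as.vector(sy), 0), nrow(px) - 1),
                          method = "linear")
  vals <- matrix(vals, nrow = length(t))
  intensityProfile(t * image@pixelSize, rowMeans(vals),
                   source = sprintf("ROI (%.1f,%.1f)->(%.1f,%.1f) w%d",
                                    roi@p0[1], roi@p0[2], roi@p1[1],
                                    roi@p1[2], roi@width))
}

#' Estimate integer inter-frame shifts by cross-correlation
#'
#' For each frame, finds the integer (dy, dx) translation within
#' \code{maxShift} pixels that maximizes the Pearson correlation with the
#' first frame over the overlapping region; frame 1 has shift (0, 0).
#'
#' @param stack a [FrameStack-class].
#' @param maxShift largest shift searched in each direction, pixels.
#' @return Integer matrix with one row per frame and columns dy, dx.
#' @export
estimateShifts <- function(stack, maxShift = 10L) {
  ref <- stack@frames[[1]]
  shifts <- matrix(0L, nFrames(stack), 2,
                   dimnames = list(NULL, c("dy", "dx")))
  grid <- -maxShift:maxShift
  for (f in seq_along(stack@frames)[-1]) {
    fr <- stack@frames[[f]]
    best <- -Inf; bestShift <- c(0L, 0L)
    for (dy in grid) for (dx in grid) {
      r1 <- max(1, 1 + dy):min(nrow(ref), nrow(ref) + dy)
      c1 <- max(1, 1 + dx):min(ncol(ref), ncol(ref) + dx)
      a <- ref[r1, c1]
      b <- fr[r1 - dy, c1 - dx]
      cc <- stats::cor(as.vector(a), as.vector(b))
      if (is.finite(cc) && cc > best) {
        best <- cc
        bestShift <- c(dy, dx)
      }
    }
    shifts[f, ] <- as.integer(bestShift)
  }
  shifts
}

#' Superpose (pixelwise-average) the frames of a stack
#'
#' Averaging n frames of the same arrested field reduces additive noise by
#' sqrt(n), sharpening the striation signal before profile fitting. With
#' \code{register = TRUE}, each frame is first shifted by the integer
#' translation best aligning it to frame 1 ([estimateShifts()]); border
#' pixels are averaged over the frames that cover them. Registration is off
#' by default because frames of an arrested heart are nominally aligned.
#'
#' @param stack a [FrameStack-class].
#' @param register align frames to frame 1 before averaging.
#' @param maxShift registration search radius, pixels.
#' @return A [FluorImage-class] with the stack's pixel size.
#' @export
superpose <- function(stack, register = FALSE, maxShift = 10L) {
  frs <- stack@frames
  if (!register)
    return(fluorImage(Reduce(`+`, frs) / length(frs), stack@pixelSize))
  shifts <- estimateShifts(stack, maxShift)
  nr <- nrow(frs[[1]]); nc <- ncol(frs[[1]])
  total <- matrix(0, nr, nc)
  count <- matrix(0, nr, nc)
  for (f in seq_along(frs)) {
    dy <- shifts[f, 1]; dx <- shifts[f, 2]
    r1 <- max(1, 1 + dy):min(nr, nr + dy)
    c1 <- max(1, 1 + dx):min(nc, nc + dx)
    total[r1, c1] <- total[r1, c1] + frs[[f]][r1 - dy, c1 - dx]
    count[r1, c1] <- count[r1, c1] + 1
  }
  if (any(count == 0))
    stop("registration shifts leave pixels uncovered; reduce maxShift")
  fluorImage(total / count, stack@pixelSize)
}
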