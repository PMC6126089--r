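sidecarPath <- function(path) paste0(path, ".json")

#' Read a single-channel grayscale TIFF as a FluorImage
#'
#' Accepts 8/16-bit integer or float grayscale TIFFs. Integer data are
#' returned on their native scale (e.g. 0..65535 for 16-bit), so integer
#' rasters round-trip losslessly through [writeFluorImage()]. Multi-channel
#' (RGB) input is rejected. The pixel size must come from the
#' \code{pixelSize} argument or from a JSON sidecar written by
#' [writeFluorImage()]; it is never silently assumed.
#'
#' @param path TIFF file path.
#' @param pixelSize um per pixel; when NULL, read from the sidecar
#'   \code{<path>.json}.
#' @return A [FluorImage-class].
#' @export
readFluorImage <- function(path, pixelSize = NULL) {
  frames <- readGrayFrames(path)
  if (length(frames) > 1L)
    stop("file contains ", length(frames),
         " pages; use readFrameStack() for multi-frame TIFFs")
  fluorImage(frames[[1]], resolvePixelSize(path, pixelSize))
}

#' Read a multipage grayscale TIFF as a FrameStack
#'
#' @inheritParams readFluorImage
#' @return A [FrameStack-class] with one frame per TIFF page, in stored
#'   order.
#' @export
readFrameStack <- function(path, pixelSize = NULL) {
  frameStack(readGrayFrames(path),
             pixelSize = resolvePixelSize(path, pixelSize))
}

readGrayFrames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] > 1L)
        stop("multi-channel (RGB) TIFF is not supported; ",
             "supply a single-channel grayscale image")
      p <- p[, , 1L]
    }
    p * 1.0
  })
}

resolvePixelSize <- function(path, pixelSize) {
  if (!is.null(pixelSize)) return(as.numeric(pixelSize))
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$pixel_size_um)) return(as.numeric(meta$pixel_size_um))
  }
  stop("pixel size unknown for ", path,
       ": pass pixelSize= or provide a sidecar JSON with pixel_size_um")
}

#' Write a FluorImage or FrameStack as 16-bit grayscale TIFF
#'
#' Intensities must lie in [0, 65535]; non-integer values are rounded to the
#' nearest integer AU (the 16-bit container), so integer rasters round-trip
#' exactly. A JSON sidecar \code{<path>.json} recording \code{pixel_size_um}
#' is written alongside so the image can be re-read without external
#' metadata.
#'
#' @param x a [FluorImage-class] or [FrameStack-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeFluorImage <- function(x, path) {
  mats <- if (methods::is(x, "FrameStack")) x@frames else list(x@pixels)
  mats <- lapply(mats, function(m) {
    if (min(m) < 0 || max(m) > 65535)
      stop("intensities outside [0, 65535] cannot be stored as 16-bit TIFF")
    round(m) / 65535
  })
  tiff::writeTIFF(if (length(mats) == 1L) mats[[1]] else mats, path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(pixel_size_um = pixelSize(x)),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFluorImage
#' @export
writeFrameStack <- writeFluorImage

#' Read a line ROI from JSON
#'
#' Expected layout: \code{\{"p0": [x, y], "p1": [x, y], "width": w\}} with
#' continuous pixel coordinates and an odd integer width.
#'
#' @param path JSON file path.
#' @return A [LineROI-class].
#' @export
readLineROI <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("p0", "p1", "width")) {
    if (is.null(j[[field]]))
      stop("ROI JSON is missing required field '", field, "'")
    if (!is.numeric(j[[field]]))
      stop("ROI JSON field '", field, "' must be numeric")
  }
  if (length(j$p0) != 2L || length(j$p1) != 2L)
    stop("ROI JSON fields 'p0' and 'p1' must each hold two coordinates")
  if (j$width %% 2 == 0)
    stop("ROI JSON field 'width' must be odd (got ", j$width, ")")
  lineROI(j$p0, j$p1, j$width)
}

#' @rdname readLineROI
#' @param roi a [LineROI-class] to serialize.
#' @export
writeLineROI <- function(roi, path) {
  jsonlite::write_json(list(p0 = roi@p0, p1 = roi@p1, width = roi@width),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write spacing results as CSV and JSON reports
#'
#' The CSV holds one row per adjacent-peak distance (index, left and right
#' peak centers in um, the distance, and whether it was kept after the
#' intensity filter). The JSON summary echoes mean/sd/n and, when a fit is
#' supplied, its parameters and diagnostics.
#'
#' @param result a [SpacingResult-class].
#' @param csvPath output CSV path (NULL to skip).
#' @param jsonPath output JSON path (NULL to skip).
#' @param fit optional [MultiPeakFit-class] included in the JSON summary.
#' @return Invisible list of the written paths.
#' @export
writeSpacingResult <- function(result, csvPath = NULL, jsonPath = NULL,
                               fit = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(result@distances, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    summary <- list(mean_um = result@mean, sd_um = result@sd, n = result@n,
                    source = result@source)
    if (!is.null(fit))
      summary$fit <- list(
        slope_a = fit@slopeA, intercept_b = fit@interceptB,
        peaks = fit@peaks, rss = fit@rss, r_squared = fit@rSquared,
        converged = fit@converged, n_iterations = fit@nIterations,
        removed_peaks = fit@diagnostics$removedPeaks,
        collapsed = isTRUE(fit@diagnostics$collapsed))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(csv = csvPath, json = jsonPath))
}

#' Read kept distances back from a spacing CSV
#'
#' @param path CSV written by [writeSpacingResult()].
#' @param keptOnly drop distances excluded by the intensity filter
#'   (default TRUE).
#' @return Numeric vector of distances (um).
#' @export
readSpacingDistances <- function(path, keptOnly = TRUE) {
  d <- utils::read.csv(path)
  for (field in c("distance", "kept"))
    if (is.null(d[[field]]))
      stop("spacing CSV is missing required column '", field, "'")
  if (keptOnly) d <- d[as.logical(d$kept), ]
  d$distance
}

#' Serialize / restore ground truth of a synthetic scene
#'
#' Writes the full scene parameter set plus the derived band centers and
#' apparent spacing as JSON (the sidecar format accompanying synthetic
#' TIFFs), and reads it back into a [GroundTruth-class].
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return \code{path} invisibly (write); a [GroundTruth-class] (read).
#' @export
writeGroundTruth <- function(truth, path) {
  sc <- truth@scene
  jsonlite::write_json(list(
    scene = list(
      true_spacing_um = sc@trueSpacing, n_bands = sc@nBands,
      band_sigma_um = sc@bandSigma, band_amplitudes = sc@bandAmplitudes,
      baseline_intercept = sc@baselineIntercept,
      baseline_slope = sc@baselineSlope,
      in_plane_angle_deg = sc@inPlaneAngle, tilt_angle_deg = sc@tiltAngle,
      noise_sd = sc@noiseSd, pixel_size_um = sc@pixelSize,
      image_shape = sc@imageShape, seed = sc@seed),
    band_centers_on_axis_um = truth@bandCentersOnAxis,
    apparent_spacing_um = truth@apparentSpacing),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- j$scene
  scene <- striationScene(
    trueSpacing = s$true_spacing_um, nBands = s$n_bands,
    bandSigma = s$band_sigma_um, bandAmplitudes = s$band_amplitudes,
    baselineIntercept = s$baseline_intercept,
    baselineSlope = s$baseline_slope, inPlaneAngle = s$in_plane_angle_deg,
    tiltAngle = s$tilt_angle_deg, noiseSd = s$noise_sd,
    pixelSize = s$pixel_size_um, imageShape = s$image_shape, seed = s$seed)
  new("GroundTruth", bandCentersOnAxis = j$band_centers_on_axis_um,
      apparentSpacing = j$apparent_spacing_um, scene = scene)
}
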