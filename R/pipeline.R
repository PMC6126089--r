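#' Full striation-spacing analysis of an image or frame stack
#'
#' Runs the complete measurement chain: optional superposition of a frame
#' stack, profile extraction along the line ROI, multipeak Gaussian fitting
#' with linear offset, exclusion of insufficient-intensity peaks, and
#' adjacent-peak spacing statistics. The run is fully deterministic given
#' its inputs. When \code{outPrefix} is given, \code{<outPrefix>.csv} (one
#' row per distance) and \code{<outPrefix>.json} (summary plus fit
#' diagnostics) are written.
#'
#' @param x a [FluorImage-class] or [FrameStack-class].
#' @param roi a [LineROI-class], or path to an ROI JSON.
#' @param cfg a [FitConfig-class].
#' @param nPeaks optional forced peak count passed to [fitMultiPeak()].
#' @param superposeFrames average a stack before analysis (default TRUE;
#'   ignored for single images).
#' @param register align frames before averaging (see [superpose()]).
#' @param outPrefix path prefix for CSV/JSON reports, or NULL for none.
#' @return A list with elements \code{profile}, \code{fit} (filtered) and
#'   \code{spacing}.
#' @examples
#' sim <- generateStriationImage(striationScene(trueSpacing = 2, seed = 1))
#' roi <- lineROI(c(4, 19.5), c(123, 19.5), width = 5)
#' res <- analyzeImage(sim$image, roi)
#' spacingMean(res$spacing)
#' @export
analyzeImage <- function(x, roi, cfg = fitConfig(), nPeaks = NULL,
                         superposeFrames = TRUE, register = FALSE,
                         outPrefix = NULL) {
  if (is.character(roi)) roi <- readLineROI(roi)
  if (methods::is(x, "FrameStack")) {
    x <- if (superposeFrames) superpose(x, register = register) else x[[1L]]
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
  }
  profile <- stage("extractProfile", extractProfile(x, roi))
  fit <- stage("fitMultiPeak", fitMultiPeak(profile, cfg, nPeaks = nPeaks))
  fit <- stage("filterPeaks", filterPeaks(fit, cfg))
  spacing <- stage("computeSpacings",
                   computeSpacings(fit, source = profile@source))
  if (!is.null(outPrefix))
    writeSpacingResult(spacing, csvPath = paste0(outPrefix, ".csv"),
                       jsonPath = paste0(outPrefix, ".json"), fit = fit)
  list(profile = profile, fit = fit, spacing = spacing)
}

#' Compare spacing distributions between groups
#'
#' Two groups are compared by Welch's t-test; three or more are compared by
#' the Steel-Dwass all-pairs test (the convention for multi-condition
#' spacing tables). \code{method} overrides the automatic choice; pairwise
#' Welch p-values for k > 2 carry no multiplicity adjustment and are flagged
#' as such in the method label.
#'
#' @param groups named list of numeric distance vectors or
#'   [SpacingResult-class] objects (>= 2 groups).
#' @param method "auto", "welch" or "steel_dwass".
#' @return A [TestResult-class] (Welch, 2 groups) or
#'   [PairwiseComparison-class].
#' @examples
#' set.seed(1)
#' compareGroups(list(a = rnorm(9, 2.18, 0.13), b = rnorm(9, 1.80, 0.08)))
#' @export
compareGroups <- function(groups, method = c("auto", "welch",
                                             "steel_dwass")) {
  method <- match.arg(method)
  groups <- lapply(groups, asDistances)
  k <- length(groups)
  if (k < 2L) stop("compareGroups needs at least 2 groups")
  if (method == "auto") method <- if (k == 2L) "welch" else "steel_dwass"
  if (method == "steel_dwass") return(steelDwass(groups))
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  if (k == 2L) return(welchT(groups[[1]], groups[[2]], labels = nm))
  z <- matrix(0, k, k, dimnames = list(nm, nm))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- welchT(groups[[i]], groups[[j]], labels = nm[c(i, j)])
    z[i, j] <- z[j, i] <- r@statistic
    p[i, j] <- p[j, i] <- r@pValue
  }
  new("PairwiseComparison", statistics = z, pValues = p,
      method = "pairwise Welch t-tests (unadjusted)",
      groupSizes = as.integer(lengths(groups)))
}
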