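#' Summarize a group of distances
#'
#' @param x numeric vector of distances, or a [SpacingResult-class] (kept
#'   distances are used).
#' @return A [SummaryStats-class] with mean, sample SD and n.
#' @examples
#' summarizeDistances(c(1.9, 2.0, 2.1))
#' @export
summarizeDistances <- function(x) {
  x <- asDistances(x)
  if (length(x) < 2L) stop("need at least 2 observations to summarize")
  summaryStats(mean(x), stats::sd(x), length(x))
}

asDistances <- function(x) {
  if (methods::is(x, "SpacingResult"))
    return(x@distances$distance[x@distances$kept])
  as.numeric(x)
}

asSummary <- function(x) {
  if (methods::is(x, "SummaryStats")) return(x)
  summarizeDistances(x)
}

#' Welch's two-sample t-test from raw data or summary statistics
#'
#' Computes \eqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student t distribution. Raw inputs are reduced to their summary
#' statistics first, so raw-data and summary-based calls agree exactly;
#' reported group comparisons can therefore be recomputed from printed
#' mean +/- SD and n alone.
#'
#' @param g1,g2 numeric vectors of distances, [SpacingResult-class] objects,
#'   or [SummaryStats-class] objects.
#' @param labels character labels of the two groups.
#' @return A [TestResult-class].
#' @examples
#' welchT(summaryStats(2.18, 0.13, 9), summaryStats(1.80, 0.08, 9))
#' @export
welchT <- function(g1, g2, labels = c("group1", "group2")) {
  s1 <- asSummary(g1); s2 <- asSummary(g2)
  se2 <- s1@sd^2 / s1@n + s2@sd^2 / s2@n
  if (se2 == 0) {
    if (s1@mean == s2@mean)
      stop("degenerate comparison: both groups have zero variance ",
           "and equal means")
    return(new("TestResult", statistic = Inf * sign(s1@mean - s2@mean),
               df = NA_real_, pValue = 0,
               method = "Welch two-sample t-test", groups = labels))
  }
  t <- (s1@mean - s2@mean) / sqrt(se2)
  df <- se2^2 / ((s1@sd^2 / s1@n)^2 / (s1@n - 1) +
                 (s2@sd^2 / s2@n)^2 / (s2@n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  new("TestResult", statistic = t, df = df, pValue = p,
      method = "Welch two-sample t-test", groups = labels)
}

# Standardized pairwise rank statistic with tie correction: the two groups
# are jointly ranked (mid-ranks for ties) and the rank sum of the first
# group is centered and scaled by the tie-corrected null variance.
pairwiseRankZ <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  R <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(list(z = 0, R = R, E = E, V = V))
  list(z = (R - E) / sqrt(V), R = R, E = E, V = V)
}

# Exact two-sided permutation p of the rank-sum statistic: enumerate every
# assignment of n1 of the joint mid-ranks to group 1.
exactRankP <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (N + 1) / 2)
  idx <- utils::combn(N, n1)
  E <- n1 * (N + 1) / 2
  sums <- colSums(matrix(r[idx], nrow = n1))
  mean(abs(sums - E) >= obs - 1e-9)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, the two samples are jointly ranked (average
#' ranks for ties) and the rank sum is standardized with the tie-corrected
#' null variance; the two-sided p-value refers \eqn{q = |z|\sqrt{2}} to the
#' studentized range distribution with k groups and infinite degrees of
#' freedom, which controls the familywise error over all k(k-1)/2
#' comparisons. With k = 2 this reduces exactly to the two-sided
#' normal-approximation rank-sum test.
#'
#' \code{exact = TRUE} replaces each pair's asymptotic p with the exhaustive
#' permutation p of the rank statistic (feasible for group sizes up to ~8);
#' for k = 2 that is the exact test, while for k > 2 the exact pairwise
#' p-values carry no studentized-range multiplicity adjustment and are
#' intended for validation rather than inference.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2);
#'   [SpacingResult-class] elements are reduced to their kept distances.
#' @param exact use the exhaustive permutation null per pair.
#' @return A [PairwiseComparison-class] with k x k statistic and p-value
#'   matrices (unit diagonal).
#' @examples
#' set.seed(1)
#' steelDwass(list(a = rnorm(8, 2.0, 0.1), b = rnorm(8, 2.2, 0.1)))
#' @export
steelDwass <- function(groups, exact = FALSE) {
  groups <- lapply(groups, asDistances)
  k <- length(groups)
  if (k < 2L) stop("steelDwass needs at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group must have n >= 2")
  if (exact && any(sizes > 10L))
    stop("exact mode is limited to groups of size <= 10")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  z <- matrix(0, k, k, dimnames = list(nm, nm))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    st <- pairwiseRankZ(groups[[i]], groups[[j]])
    z[i, j] <- z[j, i] <- st$z
    p[i, j] <- p[j, i] <- if (exact)
      exactRankP(groups[[i]], groups[[j]])
    else
      stats::ptukey(abs(st$z) * sqrt(2), nmeans = k, df = Inf,
                    lower.tail = FALSE)
  }
  new("PairwiseComparison", statistics = z, pValues = p,
      method = if (exact) "Steel-Dwass (exact pairwise permutation)"
               else "Steel-Dwass all-pairs test",
      groupSizes = as.integer(sizes))
}
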