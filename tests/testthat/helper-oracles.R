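# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they validate.

# Sum-of-Gaussians + line, written independently of the package model.
oracleModel <- function(a, b, A, mu, sigma, x) {
  y <- a * x + b
  for (i in seq_along(A))
    y <- y + A[i] * exp(-0.5 * ((x - mu[i]) / sigma[i])^2)
  y
}

# Greedy grid search over (center, sigma) with baseline and amplitudes
# solved linearly at each step, followed by a joint quasi-Newton polish.
# An independent route to the least-squares optimum of the same model.
gridPolishFit <- function(x, y, nPeaks, sigmaGrid = seq(0.1, 1, by = 0.05)) {
  resid <- y
  centers <- numeric(0); sigmas <- numeric(0)
  design <- function(mu, sg) {
    cols <- cbind(1, x)
    for (i in seq_along(mu))
      cols <- cbind(cols, exp(-0.5 * ((x - mu[i]) / sg[i])^2))
    cols
  }
  for (p in seq_len(nPeaks)) {
    best <- list(rss = Inf)
    for (mu in x) for (sg in sigmaGrid) {
      X <- design(c(centers, mu), c(sigmas, sg))
      f <- stats::lm.fit(X, y)
      rss <- sum(f$residuals^2)
      if (rss < best$rss) best <- list(rss = rss, mu = mu, sg = sg)
    }
    centers <- c(centers, best$mu); sigmas <- c(sigmas, best$sg)
  }
  X <- design(centers, sigmas)
  beta <- stats::lm.fit(X, y)$coefficients
  par0 <- c(beta[1:2], as.vector(rbind(pmax(beta[-(1:2)], 1e-9), centers,
                                       sigmas)))
  obj <- function(p) {
    A <- p[3 * seq_len(nPeaks)]
    mu <- p[3 * seq_len(nPeaks) + 1]
    sg <- p[3 * seq_len(nPeaks) + 2]
    sum((y - oracleModel(p[1], p[2], A, mu, sg, x))^2)
  }
  lo <- c(-Inf, -Inf, rep(c(0, min(x), 0.05), nPeaks))
  hi <- c(Inf, Inf, rep(c(Inf, max(x), 1.5), nPeaks))
  sc <- pmax(abs(par0), 0.05)
  opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 5000, factr = 10,
                                     parscale = sc))
  # second-stage polish with a different optimizer to escape L-BFGS-B stalls
  opt2 <- stats::nlminb(opt$par, obj, lower = lo, upper = hi,
                        scale = 1 / pmax(abs(opt$par), 0.05),
                        control = list(iter.max = 5000, eval.max = 10000,
                                       rel.tol = 1e-15, x.tol = 1e-14))
  p <- if (opt2$objective < opt$value) opt2$par else opt$par
  best <- min(opt2$objective, opt$value)
  ord <- order(p[3 * seq_len(nPeaks) + 1])
  list(a = p[1], b = p[2],
       A = p[3 * seq_len(nPeaks)][ord],
       mu = p[3 * seq_len(nPeaks) + 1][ord],
       sigma = p[3 * seq_len(nPeaks) + 2][ord],
       rss = best)
}

# Exhaustive permutation p-value of the two-sided rank-sum statistic:
# every assignment of n1 of the joint mid-ranks to group 1 is enumerated.
permutationRankP <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  E <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - E)
  sums <- colSums(matrix(r[utils::combn(N, n1)], nrow = n1))
  mean(abs(sums - E) >= obs - 1e-9)
}

# Default straight ROI along the striation axis of a synthetic scene.
sceneROI <- function(scene, width = 5L) axisROI(scene, width = width)

# Expected peak centers, in profile coordinates, of a scene analyzed along
# sceneROI(): the band train is centered on the ROI midpoint.
expectedProfileCenters <- function(scene, roi) {
  apparent <- scene@trueSpacing / cos(scene@tiltAngle * pi / 180)
  mid <- sqrt(sum((roi@p1 - roi@p0)^2)) * scene@pixelSize / 2
  mid + (seq_len(scene@nBands) - (scene@nBands + 1) / 2) * apparent
}
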