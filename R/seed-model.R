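# Per-seed bivariate Gaussian feature model and fused liver probability map.
#
# Each voxel q carries the feature vector F_q = (mu_q, sigma_q): mean and
# sample standard deviation of intensity over the in-plane N x N window
# centred at q (edge replication at slice borders). For each user seed p a
# bivariate Gaussian is fitted to the features of the (2N-1) x (2N-1) patch
# around p, so (N + N - 1)^2 pixels contribute per seed. Per-voxel densities
# are fused across seeds by the maximum and min-max normalized to [0, 1].

# windowed sums over an N x N box with edge replication, via integral images
boxSums <- function(mat, N) {
  h <- (N - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  padded <- mat[c(rep(1L, h), seq_len(nr), rep(nr, h)),
                c(rep(1L, h), seq_len(nc), rep(nc, h)), drop = FALSE]
  ii <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  ii[r1 + N, c1 + N, drop = FALSE] - ii[r1, c1 + N, drop = FALSE] -
    ii[r1 + N, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

#' Compute per-voxel local statistical features
#'
#' For every voxel, the mean and sample standard deviation of intensity over
#' the in-plane `N x N` window centred at it (2D window within each slice;
#' borders use edge replication).
#'
#' @param volume a [CtVolume-class].
#' @param N odd window width, >= 3 (default 9).
#' @return a [FeatureVolume-class].
#' @export
computeLocalFeatures <- function(volume, N = 9L) {
  N <- as.integer(N)
  if (N %% 2L != 1L || N < 3L) stop("window width N must be odd and >= 3")
  d <- dim(volume)
  mu <- array(0, d); sg <- array(0, d)
  n <- as.numeric(N)^2
  for (s in seq_len(d[1])) {
    sl <- volume@intensities[s, , ]
    s1 <- boxSums(sl, N)
    s2 <- boxSums(sl * sl, N)
    m <- s1 / n
    v <- pmax((s2 - n * m^2) / (n - 1), 0)
    mu[s, , ] <- m
    sg[s, , ] <- sqrt(v)
  }
  new("FeatureVolume", mu = mu, sigma = sg, windowWidth = N,
      pixelSpacing = volume@pixelSpacing,
      sliceDistance = volume@sliceDistance, origin = volume@origin)
}

regularizeCovariance <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- S[1, 1] + S[2, 2]
  if (min(ev) <= 1e-8 * max(abs(ev), 1e-30)) {
    eps <- 1e-6 * tr / 2 + 1e-12
    S <- S + diag(eps, 2)
  }
  S
}

#' Fit the per-seed bivariate Gaussian models
#'
#' For each seed p, the mean feature vector and its 2x2 covariance are
#' estimated from the feature vectors of all voxels in the in-plane
#' `(2N-1) x (2N-1)` patch centred at p. Near-singular covariances (e.g. a
#' seed in a perfectly constant region) are regularized by adding
#' `eps * I` with `eps = 1e-6 * trace / 2 + 1e-12`.
#'
#' @param features a [FeatureVolume-class].
#' @param seeds k-by-3 matrix (or length-3 vector) of 1-based seed voxel
#'   coordinates (slice, row, col); each patch must fit inside its slice.
#' @param N patch base width; defaults to the feature window width.
#' @return a [SeedModel-class].
#' @export
fitSeedModels <- function(features, seeds, N = features@windowWidth) {
  seeds <- matrix(as.integer(round(seeds)), ncol = 3)
  d <- dim(features@mu)
  half <- N - 1L  # patch half-width of the (2N-1) x (2N-1) patch
  means <- matrix(0, nrow(seeds), 2)
  covs <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, 1]; r <- seeds[i, 2]; c <- seeds[i, 3]
    if (s < 1 || s > d[1] || r < 1 || r > d[2] || c < 1 || c > d[3])
      stop(sprintf("seed %d at (%d, %d, %d) lies outside the volume",
                   i, s, r, c))
    if (r - half < 1 || r + half > d[2] || c - half < 1 || c + half > d[3])
      stop(sprintf("seed %d lacks full (2N-1)x(2N-1) patch support", i))
    rows <- (r - half):(r + half); cols <- (c - half):(c + half)
    F <- cbind(as.vector(features@mu[s, rows, cols]),
               as.vector(features@sigma[s, rows, cols]))
    means[i, ] <- colMeans(F)
    covs[[i]] <- regularizeCovariance(stats::cov(F))
  }
  new("SeedModel", means = means, covariances = covs, seeds = seeds,
      windowWidth = as.integer(N))
}

#' Number of feature samples behind a seed model
#'
#' `k * (2N - 1)^2`: every seed contributes the (2N-1) x (2N-1) patch around
#' it (578 for the default N = 9, k = 2).
#'
#' @param model a [SeedModel-class].
#' @export
seedSampleCount <- function(model) {
  w <- 2L * model@windowWidth - 1L
  nrow(model@means) * w * w
}

#' Fused per-voxel liver probability map
#'
#' Evaluates each seed's bivariate Gaussian density at every voxel's feature
#' vector, fuses across seeds by the maximum, and maps the result to
#' `[0, 1]`.
#'
#' The default `"reference"` normalization clips each seed's density at its
#' own in-model median level: `P_i = min(1, exp((m - q_i)/2))` with `q_i` the
#' squared Mahalanobis distance and `m = qchisq(0.5, 2)` the chi-squared
#' median. A voxel whose features are typical of the seed's patch scores ~1
#' while mismatched tissue decays exponentially; the best-matching voxel
#' always scores exactly 1. The `"max"` option instead divides the fused
#' density by its global maximum (a min-max map to `[0, 1]`); it preserves
#' the same ordering but centres in-distribution voxels near 0.5, which
#' leaves the downstream region term indifferent.
#'
#' @param features a [FeatureVolume-class].
#' @param model a [SeedModel-class].
#' @param normalize `"reference"` (default), `"max"`, or `"none"` for the raw
#'   fused densities (plain array, not a probability volume).
#' @return a [ProbabilityVolume-class], or the raw fused density array for
#'   `normalize = "none"`.
#' @export
liverProbability <- function(features, model,
                             normalize = c("reference", "max", "none")) {
  normalize <- match.arg(normalize)
  d <- dim(features@mu)
  x1 <- as.vector(features@mu); x2 <- as.vector(features@sigma)
  m <- stats::qchisq(0.5, df = 2)
  fused <- rep(0, length(x1))
  for (i in seq_len(nrow(model@means))) {
    S <- model@covariances[[i]]
    dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / dt
    e1 <- x1 - model@means[i, 1]; e2 <- x2 - model@means[i, 2]
    q <- inv[1, 1] * e1^2 + 2 * inv[1, 2] * e1 * e2 + inv[2, 2] * e2^2
    v <- switch(normalize,
                reference = pmin(1, exp((m - q) / 2)),
                exp(-q / 2) / (2 * pi * sqrt(dt)))
    fused <- pmax(fused, v)
  }
  if (normalize == "none") return(array(fused, d))
  if (normalize == "max") {
    mx <- max(fused)
    if (mx > 0) fused <- fused / mx
  }
  probabilityVolume(array(fused, d), pixelSpacing = features@pixelSpacing,
                    sliceDistance = features@sliceDistance,
                    origin = features@origin)
}
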