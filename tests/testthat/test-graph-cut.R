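test_that("region terms follow R(liver) = 1 - Pr, R(background) = Pr", {
  expect_equal(regionTerm(1, "liver"), 0)
  expect_equal(regionTerm(0, "liver"), 1)
  expect_equal(regionTerm(0.25, "background"), 0.25)
  expect_error(regionTerm(1.2, "liver"), "\\[0, 1\\]")
})

test_that("boundary terms reduce to inverse distance without contrast", {
  expect_equal(boundaryTerm(100, 100, 1, 0.7, 5), 1 / 0.7)
  expect_equal(boundaryTerm(0, 500, 0, 2, 5), 1 / 2)   # F = 0
  d <- 3
  expect_equal(boundaryTerm(0, d * sqrt(2), 1, 1.5, d), exp(-1) / 1.5)
  expect_error(boundaryTerm(1, 2, 0.5, 0, 1), "distance")
})

test_that("the noise estimate is the floored median neighbour difference", {
  arr <- array(0, c(1, 1, 5)); arr[1, 1, ] <- c(0, 10, 20, 30, 40)
  expect_equal(estimateNoiseSd(ctVolume(arr)), 10)
  expect_equal(estimateNoiseSd(ctVolume(array(5, c(2, 3, 3)))), 1)  # floor
})

# independent enumeration oracle over every labeling of a tiny volume
enumerateMin <- function(v, pv, g, cfg) {
  d <- dim(v); n <- prod(d)
  P <- as.vector(probArray(pv)); I <- as.vector(intensities(v))
  G <- as.vector(g)
  delta <- if (is.null(cfg$delta)) estimateNoiseSd(v) else cfg$delta
  sp <- c(pixelSpacing(v), sliceDistance(v))
  idx <- arrayInd(seq_len(n), d)
  pairs <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- idx[j, ] - idx[i, ]
    if (all(abs(dv) <= 1)) {
      if (cfg$neighborhood == "in-plane-8" && dv[1] != 0) next
      dist <- sqrt((dv[3] * sp[1])^2 + (dv[2] * sp[2])^2 + (dv[1] * sp[3])^2)
      F <- if (dv[1] == 0) max(G[i], G[j]) else 0
      B <- exp(-F * (I[i] - I[j])^2 / (2 * delta^2)) / dist
      pairs <- rbind(pairs, c(i, j, B))
    }
  }
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(mask)[1:n])
    e <- cfg$alpha * sum(ifelse(lab == 1, 1 - P, P)) +
      (1 - cfg$alpha) * sum(pairs[lab[pairs[, 1]] != lab[pairs[, 2]], 3])
    if (e < best) best <- e
  }
  best
}

test_that("the solver attains the exhaustive minimum on random fixtures", {
  set.seed(77)
  for (trial in 1:20) {
    d <- if (trial %% 2 == 0) c(2, 2, 3) else c(1, 3, 4)
    n <- prod(d)
    v <- ctVolume(array(rnorm(n, 100, 30), d),
                  pixelSpacing = c(0.8, 0.8), sliceDistance = 1.5)
    pv <- probabilityVolume(array(runif(n), d), pixelSpacing = c(0.8, 0.8),
                            sliceDistance = 1.5)
    g <- array(runif(n), d)
    cfg <- gcConfig(alpha = runif(1, 0.3, 0.8), delta = runif(1, 5, 30),
                    neighborhood = ifelse(trial %% 3 == 0, "in-plane-8",
                                          "volumetric-26"))
    res <- segmentMincut(v, pv, g, cfg)
    expect_equal(res$energy, enumerateMin(v, pv, g, cfg), tolerance = 1e-9)
    expect_equal(res$flow, res$energy, tolerance = 1e-9)
  }
})

test_that("the compiled solver agrees with an independent max-flow", {
  set.seed(31)
  d <- c(3, 5, 5); n <- prod(d)
  v <- ctVolume(array(rnorm(n, 100, 25), d))
  pv <- probabilityVolume(array(runif(n), d))
  g <- array(runif(n), d)
  cfg <- gcConfig(delta = 15)
  a <- segmentMincut(v, pv, g, cfg)
  b <- segmentMincut(v, pv, g, modifyList(cfg, list(solver = "igraph")))
  expect_equal(a$flow, b$flow, tolerance = 1e-9)
  expect_equal(a$energy, b$energy, tolerance = 1e-9)
})

test_that("certain probability maps label every voxel liver", {
  d <- c(2, 4, 4)
  v <- ctVolume(array(rnorm(prod(d), 100, 5), d))
  pv <- probabilityVolume(array(1, d))
  res <- segmentMincut(v, pv, array(0, d), gcConfig(delta = 5))
  expect_true(all(labelArray(res$labels) == 1L))
})

test_that("seeded 1D strips cut at the intensity jump", {
  arr <- array(0, c(1, 1, 6)); arr[1, 1, 4:6] <- 100
  v <- ctVolume(arr)
  pv <- probabilityVolume(array(0.5, c(1, 1, 6)))
  g <- array(1, c(1, 1, 6))
  res <- segmentMincut(v, pv, g, gcConfig(delta = 5),
                       seeds = matrix(c(1, 1, 1), 1),
                       bgSeeds = matrix(c(1, 1, 6), 1))
  expect_equal(labelArray(res$labels)[1, 1, ], c(1L, 1L, 1L, 0L, 0L, 0L))
})

test_that("raising alpha moves solutions toward the region optimum", {
  set.seed(55)
  d <- c(1, 3, 4); n <- prod(d)
  v <- ctVolume(array(rnorm(n, 100, 30), d))
  pv <- probabilityVolume(array(runif(n), d))
  g <- array(runif(n), d)
  P <- as.vector(probArray(pv))
  regionCost <- function(alpha) {
    lab <- as.vector(labelArray(segmentMincut(
      v, pv, g, gcConfig(alpha = alpha, delta = 10))$labels))
    sum(ifelse(lab == 1, 1 - P, P))
  }
  costs <- vapply(c(0.2, 0.5, 0.8, 0.95), regionCost, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("empty probability maps without seeds are rejected", {
  d <- c(1, 2, 2)
  expect_error(segmentMincut(ctVolume(array(0, d)),
                             probabilityVolume(array(0, d)),
                             array(0, d), gcConfig(delta = 1)),
               "empty")
})
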