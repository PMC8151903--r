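test_that("local features of a constant slice are exact", {
  v <- ctVolume(array(100, c(2, 20, 20)))
  f <- computeLocalFeatures(v, 9)
  expect_true(all(f@mu == 100))
  expect_true(all(f@sigma == 0))
})

test_that("window statistics match direct computation", {
  img <- outer(1:20, 1:20, function(r, c) (r + c + 1) %% 2)  # centre = 1
  arr <- array(0, c(1, 20, 20)); arr[1, , ] <- img
  f <- computeLocalFeatures(ctVolume(arr), 9)
  w <- img[6:14, 6:14]
  expect_equal(f@mu[1, 10, 10], mean(w))
  expect_equal(f@mu[1, 10, 10], 41 / 81)  # 41 ones among the 81
  expect_equal(f@sigma[1, 10, 10], sd(w))
  # interior voxel of a linear ramp: mean equals the centre value
  ramp <- array(0, c(1, 20, 20)); ramp[1, , ] <- outer(1:20, 1:20,
                                                       function(r, c) 3 * c)
  fr <- computeLocalFeatures(ctVolume(ramp), 9)
  expect_equal(fr@mu[1, 10, 10], ramp[1, 10, 10])
})

test_that("even window widths are rejected", {
  expect_error(computeLocalFeatures(ctVolume(array(0, c(1, 10, 10))), 8),
               "odd")
})

test_that("each seed contributes a (2N-1)^2 patch: 578 samples for N=9, k=2", {
  v <- ctVolume(array(rnorm(2 * 40 * 40), c(2, 40, 40)))
  f <- computeLocalFeatures(v, 9)
  m <- fitSeedModels(f, rbind(c(1, 20, 20), c(2, 20, 20)), 9)
  expect_identical(seedSampleCount(m), 578L)
})

test_that("seeds outside the volume or without patch support are rejected", {
  v <- ctVolume(array(0, c(2, 30, 30)))
  f <- computeLocalFeatures(v, 9)
  expect_error(fitSeedModels(f, c(5, 10, 10), 9), "outside")
  expect_error(fitSeedModels(f, c(1, 3, 15), 9), "support")
})

test_that("a seed in a constant region yields a regularized PD covariance", {
  v <- ctVolume(array(50, c(1, 40, 40)))
  f <- computeLocalFeatures(v, 9)
  m <- fitSeedModels(f, c(1, 20, 20), 9)
  S <- m@covariances[[1]]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(S, diag(1e-12, 2), tolerance = 1e-10)
})

test_that("two seeds with identical patches give identical records", {
  arr <- array(rnorm(1 * 60 * 30), c(1, 60, 30))
  arr[1, 31:60, ] <- arr[1, 1:30, ]
  f <- computeLocalFeatures(ctVolume(arr), 5)
  m <- fitSeedModels(f, rbind(c(1, 15, 15), c(1, 45, 15)), 5)
  expect_equal(m@means[1, ], m@means[2, ])
  expect_equal(m@covariances[[1]], m@covariances[[2]])
})

test_that("unnormalized density at a seed mean is the Gaussian peak", {
  set.seed(3)
  v <- ctVolume(array(rnorm(1 * 40 * 40, 100, 10), c(1, 40, 40)))
  f <- computeLocalFeatures(v, 9)
  m <- fitSeedModels(f, c(1, 20, 20), 9)
  # plant a voxel whose features equal the model mean
  f@mu[1, 2, 2] <- m@means[1, 1]; f@sigma[1, 2, 2] <- m@means[1, 2]
  dens <- liverProbability(f, m, normalize = "none")
  S <- m@covariances[[1]]
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  expect_equal(dens[1, 2, 2], 1 / (2 * pi * sqrt(detS)), tolerance = 1e-12)
})

test_that("maximum fusion takes the best-matching seed and ignores order", {
  set.seed(4)
  arr <- array(rnorm(1 * 60 * 40, 100, 10), c(1, 60, 40))
  arr[1, 31:60, ] <- arr[1, 31:60, ] + 300  # second tissue class
  f <- computeLocalFeatures(ctVolume(arr), 5)
  m12 <- fitSeedModels(f, rbind(c(1, 15, 20), c(1, 45, 20)), 5)
  m21 <- fitSeedModels(f, rbind(c(1, 45, 20), c(1, 15, 20)), 5)
  p12 <- liverProbability(f, m12)
  p21 <- liverProbability(f, m21)
  expect_equal(probArray(p12), probArray(p21))
  # a voxel matching only the second class is scored by that model
  m2 <- fitSeedModels(f, c(1, 45, 20), 5)
  p2 <- liverProbability(f, m2)
  expect_equal(probArray(p12)[1, 50, 20], probArray(p2)[1, 50, 20])
})

test_that("normalized map attains 1 and stays within [0, 1]", {
  b <- biasedPhantom()
  p <- probArray(b$p0)
  expect_equal(max(p), 1)
  expect_gte(min(p), 0)
  pm <- liverProbability(b$feats, b$model, normalize = "max")
  expect_equal(max(probArray(pm)), 1)
})

test_that("mean probability inside the truth mask exceeds outside", {
  r <- noiseFreeRun()
  feats <- computeLocalFeatures(r$volume, 9)
  model <- fitSeedModels(feats, r$seeds, 9)
  p <- probArray(liverProbability(feats, model))
  t <- labelArray(r$truth) == 1L
  expect_gt(mean(p[t]), mean(p[!t]))
})
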