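test_that("the weight table holds the inverse-distance values", {
  expect_equal(mrlWeight(c(1, 0, 0), 2), 1)
  expect_equal(mrlWeight(c(1, 1, 0), 2), 1 / sqrt(2))
  expect_equal(mrlWeight(c(0, 0, 1), 2), 1 / 2)
  w <- mrlWeightTable(2)
  expect_identical(nrow(w@offsets), 26L)
  expect_equal(sum(w@weights), 1, tolerance = 1e-12)
  expect_true(all(w@weights > 0))
  expect_error(mrlWeightTable(-1), "positive")
})

test_that("support reflects neighbour certainty with renormalized borders", {
  w <- mrlWeightTable(2)
  ones <- array(1, c(3, 6, 6))
  expect_equal(mrlSupport(ones, w, c(2, 3, 3), "liver"), 1)
  expect_equal(mrlSupport(ones, w, c(2, 3, 3), "background"), -1)
  half <- array(0.5, c(3, 6, 6))
  expect_equal(mrlSupport(half, w, c(2, 3, 3), "liver"), 0)
  # corner voxel: weights renormalize over available neighbours
  expect_equal(mrlSupport(ones, w, c(1, 1, 1), "liver"), 1)
})

test_that("fully certain and uniform fields are fixed points", {
  w <- mrlWeightTable(1.5)
  certain <- array(1, c(3, 8, 8))
  expect_equal(relaxProbability(certain, w, 1), certain)
  half <- array(0.5, c(3, 8, 8))
  expect_equal(relaxProbability(half, w, 5), half)
})

test_that("class probabilities stay complementary across iterations", {
  set.seed(9)
  p <- array(runif(4 * 10 * 10), c(4, 10, 10))
  w <- mrlWeightTable(2)
  for (it in 1:3) {
    a <- relaxProbability(p, w, it)
    b <- relaxProbability(1 - p, w, it)
    expect_equal(a + b, array(1, dim(p)), tolerance = 1e-9)
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("a single-slice volume reduces MRL to in-plane relaxation", {
  set.seed(10)
  p <- array(runif(1 * 12 * 12), c(1, 12, 12))
  full <- relaxProbability(p, mrlWeightTable(2), 3)
  # same update driven only by the 8 in-plane offsets
  w8 <- mrlWeightTable(1000)   # slice offsets get negligible weight
  inPlane <- relaxProbability(p, w8, 3)
  expect_equal(full, inPlane, tolerance = 1e-6)
})

test_that("five iterations homogenize the phantom interior beyond the
           feature rim", {
  b <- biasedPhantom()
  t <- labelArray(b$truth) == 1L
  # erode in-plane past the feature-window rim: the region whose features
  # are pure liver
  er <- t
  d <- dim(er)
  for (k in 1:5) {
    er[, -1, ] <- er[, -1, ] & er[, -d[2], ]
    er[, -d[2], ] <- er[, -d[2], ] & er[, -1, ]
    er[, , -1] <- er[, , -1] & er[, , -d[3]]
    er[, , -d[3]] <- er[, , -d[3]] & er[, , -1]
  }
  p0 <- probArray(b$p0)
  p5 <- probArray(relaxProbability(b$p0, iterations = 5))
  expect_lt(var(p5[er]), var(p0[er]))
  # the interior saturates toward full certainty
  expect_gt(mean(p5[er]), mean(p0[er]))
})

test_that("negative iteration counts are rejected", {
  expect_error(relaxProbability(array(0.5, c(1, 4, 4)), iterations = -1))
})
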