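mk <- function(arr) labelVolume(arr)

test_that("overlap metrics follow their set-algebra closed forms", {
  d <- c(2, 4, 4)
  full <- array(1L, d)
  expect_equal(unname(overlapMetrics(mk(full), mk(full))), c(0, 0))
  half <- array(0L, d); half[1, , ] <- 1L
  # A = half, B = full: |AnB| = |A| = |B|/2
  expect_equal(unname(overlapMetrics(mk(half), mk(full))), c(50, -50))
  other <- array(0L, d); other[2, , ] <- 1L
  expect_equal(unname(overlapMetrics(mk(half), mk(other))), c(100, 0))
  expect_error(overlapMetrics(mk(half), mk(array(0L, d))), "empty")
})

test_that("surface distances respect geometry and pooled symmetry", {
  d <- c(5, 7, 7)
  a <- array(0L, d); a[3, 4, 2] <- 1L
  b <- array(0L, d); b[3, 4, 7] <- 1L
  av <- labelVolume(a, pixelSpacing = c(1, 1), sliceDistance = 1)
  bv <- labelVolume(b, pixelSpacing = c(1, 1), sliceDistance = 1)
  expect_equal(unname(surfaceDistances(av, bv)), c(5, 5, 5))
  expect_equal(unname(surfaceDistances(av, av)), c(0, 0, 0))
  expect_error(surfaceDistances(av, labelVolume(array(0L, d))), "empty")
})

test_that("asd <= rmsd <= msd on random masks and metrics are symmetric", {
  set.seed(12)
  for (trial in 1:20) {
    d <- c(6, 10, 10)
    a <- array(as.integer(runif(prod(d)) > 0.6), d)
    b <- array(as.integer(runif(prod(d)) > 0.6), d)
    a[3, 5, 5] <- 1L; b[3, 5, 5] <- 1L
    av <- mk(a); bv <- mk(b)
    sAB <- surfaceDistances(av, bv)
    expect_lte(sAB[["asd"]], sAB[["rmsd"]] + 1e-12)
    expect_lte(sAB[["rmsd"]], sAB[["msd"]] + 1e-12)
    expect_equal(sAB, surfaceDistances(bv, av))
    oAB <- overlapMetrics(av, bv)
    expect_equal(oAB[["voe"]], overlapMetrics(bv, av)[["voe"]])
  }
})

test_that("the score maps errors to [0, 100] with the stated anchors", {
  expect_equal(metricScore(0, 6.4), 100)
  expect_equal(metricScore(6.4, 6.4), 75)
  expect_equal(metricScore(5 * 6.4, 6.4), 0)
  expect_equal(metricScore(10 * 6.4, 6.4), 0)   # clamped
  expect_error(metricScore(1, 0), "> 0")
  expect_error(metricScore(-1, 1), ">= 0")
  # non-increasing and continuous in the error
  e <- seq(0, 30, by = 0.5)
  s <- metricScore(e, 6.4)
  expect_true(all(diff(s) <= 0))
})

test_that("the report wires metrics, scores and the unweighted mean", {
  d <- c(3, 6, 6)
  a <- array(0L, d); a[2, 2:5, 2:5] <- 1L
  r <- metricReport(mk(a), mk(a),
                    refErrors = c(voe = 6.4, rvd = 4.7, asd = 1,
                                  rmsd = 1.8, msd = 19))
  expect_equal(unname(r$metrics), rep(0, 5))
  expect_equal(unname(r$scores), rep(100, 5))
  expect_equal(r$overall, 100)
  expect_error(metricReport(mk(a), mk(a), refErrors = c(voe = 1)),
               "refErrors")
})
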