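test_that("a single voxel reconstructs as a closed genus-0 surface", {
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  m <- reconstructSurface(labelVolume(one))
  expect_identical(eulerCharacteristic(m), 2L)
  expect_true(isWatertight(m))
})

test_that("a digital ball reconstructs watertight with near-analytic area", {
  ball <- digitalBall(10)
  m <- reconstructSurface(ball)
  expect_true(isWatertight(m))
  expect_identical(eulerCharacteristic(m), 2L)
  expect_lt(abs(meshArea(m) - 4 * pi * 100) / (4 * pi * 100), 0.10)
  expect_lt(abs(meshVolume(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.10)
})

test_that("anisotropic spacing carries into physical coordinates", {
  ball <- digitalBall(6)
  ball@pixelSpacing <- c(0.5, 0.5); ball@sliceDistance <- 2
  m <- reconstructSurface(ball)
  rng <- apply(m@vertices, 2, function(x) diff(range(x)))
  expect_equal(rng[3] / rng[1], 2 / 0.5 * 1, tolerance = 0.25)
})

test_that("empty masks are rejected", {
  expect_error(reconstructSurface(labelVolume(array(0L, c(3, 3, 3)))),
               "empty")
})

test_that("a clean mesh already at the target passes through", {
  m <- icosphere(4)   # 2562 vertices
  r <- cleanAndResample(m, nrow(m@vertices))
  expect_identical(nrow(r@vertices), nrow(m@vertices))
  expect_identical(eulerCharacteristic(r), 2L)
})

test_that("duplicate faces are removed and the result stays watertight", {
  m <- icosphere(3)
  m@faces <- rbind(m@faces, m@faces[1:5, ])
  r <- cleanAndResample(m, nrow(m@vertices))
  expect_identical(nrow(r@faces), 1280L)
  expect_true(isWatertight(r))
})

test_that("resampling hits the target within 2 % in both directions", {
  down <- cleanAndResample(icosphere(4), 1000)
  expect_lt(abs(nrow(down@vertices) - 1000) / 1000, 0.02)
  expect_true(isWatertight(down))
  expect_identical(eulerCharacteristic(down), 2L)
  up <- cleanAndResample(icosphere(3), 1500)
  expect_lt(abs(nrow(up@vertices) - 1500) / 1500, 0.02)
  expect_identical(eulerCharacteristic(up), 2L)
})

test_that("toroidal input is rejected as non-genus-0", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  ph <- seq(0, 2 * pi, length.out = 13)[-13]
  g <- expand.grid(a = th, b = ph)
  v <- cbind((2 + 0.5 * cos(g$b)) * cos(g$a),
             (2 + 0.5 * cos(g$b)) * sin(g$a), 0.5 * sin(g$b))
  idx <- function(i, j) ((i - 1) %% 24) * 12 + ((j - 1) %% 12) + 1
  f <- do.call(rbind, lapply(1:24, function(i)
    do.call(rbind, lapply(1:12, function(j)
      rbind(c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
            c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  torus <- triangleMesh(v, f)
  expect_identical(eulerCharacteristic(torus), 0L)
  expect_error(cleanAndResample(torus, nrow(v)), "genus-0")
})

test_that("multi-component input errors unless the largest is requested", {
  a <- icosphere(2)
  b <- icosphere(1)
  b@vertices <- b@vertices * 0.2 + 5
  both <- triangleMesh(rbind(a@vertices, b@vertices),
                       rbind(a@faces, b@faces + nrow(a@vertices)))
  expect_error(cleanAndResample(both, 162), "components")
  r <- cleanAndResample(both, 162, keepLargest = TRUE)
  expect_identical(nrow(r@vertices), 162L)
})

test_that("cleaning is idempotent on its own output", {
  r1 <- cleanAndResample(icosphere(4), 1200)
  r2 <- cleanAndResample(r1, 1200, smoothIterations = 0)
  expect_identical(nrow(r2@vertices), nrow(r1@vertices))
  expect_identical(eulerCharacteristic(r2), 2L)
})
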