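test_that("both generated meshes are watertight genus-0", {
  pr <- identicalPair()
  for (s in list(pr$S1, pr$S2)) {
    expect_identical(eulerCharacteristic(s$mesh), 2L)
    expect_true(isWatertight(s$mesh))
  }
})

test_that("zero deformation difference and unit scale give identical meshes", {
  pr <- identicalPair()
  expect_identical(pr$S1$mesh@vertices, pr$S2$mesh@vertices)
  expect_identical(pr$S1$landmarks, pr$S2$landmarks)
})

test_that("a scale ratio s scales the surface area by s^2", {
  pr <- generateLiverMeshPair(meshPairSpec(subdivision = 3,
                                           scaleRatio = 1.3,
                                           rotationS2 = 0, seed = 2))
  expect_equal(meshArea(pr$S2$mesh) / meshArea(pr$S1$mesh), 1.3^2,
               tolerance = 1e-6)
})

test_that("generation is deterministic in the seed", {
  a <- generateLiverMeshPair(meshPairSpec(subdivision = 2, seed = 9))
  b <- generateLiverMeshPair(meshPairSpec(subdivision = 2, seed = 9))
  expect_identical(a$S1$mesh@vertices, b$S1$mesh@vertices)
  expect_identical(a$S2$mesh@vertices, b$S2$mesh@vertices)
})

test_that("eleven landmarks share labels bijectively across the pair", {
  pr <- asymmetricPair()
  expect_identical(names(pr$S1$landmarks), as.character(1:11))
  expect_identical(names(pr$S2$landmarks), names(pr$S1$landmarks))
  expect_identical(anyDuplicated(pr$S1$landmarks), 0L)
  # corresponding landmarks are the same vertex index by construction
  expect_identical(pr$S1$landmarks, pr$S2$landmarks)
})

test_that("resection paths lie on their mesh surfaces", {
  pr <- asymmetricPair()
  for (side in list(pr$S1, pr$S2)) {
    v <- side$mesh@vertices; f <- side$mesh@faces
    for (p in side$paths) {
      pts <- pathPoints(p)
      expect_gte(nrow(pts), 2)
      # each point is a barycentric combination of one face: distance to
      # the surface is numerically zero
      d <- vapply(seq_len(nrow(pts)), function(i) {
        x <- pts[i, ]
        fd <- Inf
        ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
        for (k in order(rowSums(sweep(ctr, 2, x)^2))[1:8]) {
          a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c <- v[f[k, 3], ]
          M <- cbind(b - a, c - a)
          uv <- solve(crossprod(M), crossprod(M, x - a))
          uv <- pmax(pmin(uv, 1), 0)
          q <- a + M %*% uv
          fd <- min(fd, sqrt(sum((x - q)^2)))
        }
        fd
      }, numeric(1))
      expect_lt(max(d), 1e-6)
    }
  }
})

test_that("excessive deformation is rejected before self-intersection", {
  expect_error(generateLiverMeshPair(
    meshPairSpec(subdivision = 2, deformAmplitude = c(2.5, 0.1), seed = 1)),
    "self-intersect")
})
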