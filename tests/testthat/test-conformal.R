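test_that("cotangent weights reproduce closed-form angle sums", {
  # regular tetrahedron: all opposite angles are 60 degrees
  tet <- triangleMesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                            c(-1, -1, 1)),
                      rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3)))
  cw <- cotangentWeights(tet)
  expect_equal(unname(cw$weights), rep(2 / sqrt(3), 6), tolerance = 1e-12)
  # right-angle opposite corners cancel: near-zero weight on the shared
  # edge of two right-angled triangles
  rightTet <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.5, 0),
                                 c(0.5, -0.5, 1e-3)),
                           rbind(c(1, 2, 3), c(2, 1, 4), c(1, 3, 4),
                                 c(3, 2, 4)))
  cwr <- cotangentWeights(rightTet)
  sharedR <- which(cwr$edges[, 1] == 1 & cwr$edges[, 2] == 2)
  expect_equal(cwr$weights[sharedR], 0, tolerance = 1e-3)
  # obtuse opposite angles make a negative weight on the shared edge
  flatTet <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.12, 0),
                                c(0.5, -0.12, 0.02)),
                          rbind(c(1, 2, 3), c(2, 1, 4), c(1, 3, 4),
                                c(3, 2, 4)))
  cwf <- cotangentWeights(flatTet)
  shared <- which(cwf$edges[, 1] == 1 & cwf$edges[, 2] == 2)
  expect_lt(cwf$weights[shared], 0)
})

test_that("the harmonic energy matches its definition", {
  tet <- icosphere(0)
  cw <- cotangentWeights(tet)
  pos <- matrix(0, nrow(tet@vertices), 3)  # all vertices to one point
  expect_equal(harmonicEnergy(pos, cw), 0)
  # single-edge contribution: k ||d||^2
  cw1 <- list(edges = cbind(1L, 2L), weights = 2)
  p <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(harmonicEnergy(p, cw1), 2)
  # landmark term adds gamma * squared mismatch
  expect_equal(harmonicEnergy(p, cw1, landmarks = 1L,
                              targetPositions = rbind(c(0, 2, 0)),
                              gamma = 10), 2 + 10 * 4)
  expect_error(harmonicEnergy(p, cw1, landmarks = 1L), "mismatch")
})

test_that("Beltrami coefficients of canonical affine maps are exact", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(beltramiCoefficient(src, src), 0 + 0i)
  expect_equal(beltramiCoefficient(src, 2 * src), 0 + 0i)  # scaling
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- z + 0.5 * Conj(z)
  expect_equal(beltramiCoefficient(src, w), 0.5 + 0i)
  expect_error(beltramiCoefficient(rbind(c(0, 0), c(1, 0), c(2, 0)), src),
               "degenerate")
})

test_that("a unit sphere reparameterizes onto itself", {
  sp <- icosphere(3)
  mp <- sphericalParameterize(sp)
  expect_lt(max(abs(sqrt(rowSums(spherePositions(mp)^2)) - 1)), 1e-9)
  expect_lt(mean(mp@angleDistortion), 0.5)
  expect_true(all(Mod(beltrami(mp)) < 1, na.rm = TRUE))
  # positions equal the input up to a rotation (Moebius subgroup)
  X <- sp@vertices; Y <- spherePositions(mp)
  s <- svd(t(X) %*% Y)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  expect_lt(max(sqrt(rowSums((Y %*% R - X)^2))), 1e-3)
})

test_that("deformed liver meshes map without flipped faces", {
  am <- asymmetricMaps()
  for (mp in list(am$map2)) {
    expect_lt(max(abs(sqrt(rowSums(spherePositions(mp)^2)) - 1)), 1e-9)
    expect_true(all(Mod(beltrami(mp)) < 1, na.rm = TRUE))
  }
  pr <- am$pair
  m1 <- sphericalParameterize(pr$S1$mesh, landmarks = pr$S1$landmarks,
                              targetPositions = am$targets, gamma = 100)
  expect_true(all(Mod(beltrami(m1)) < 1, na.rm = TRUE))
  expect_true(all(diff(m1@energyTrace) <= 1e-9))
})

test_that("non-genus-0 meshes are rejected", {
  open <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_error(sphericalParameterize(open), "genus-0|watertight|closed")
})

test_that("landmark mismatch does not grow with gamma", {
  am <- asymmetricMaps()
  pr <- am$pair
  mism <- function(g) {
    m1 <- sphericalParameterize(pr$S1$mesh, landmarks = pr$S1$landmarks,
                                targetPositions = am$targets, gamma = g)
    sum(rowSums((spherePositions(m1)[pr$S1$landmarks, ] - am$targets)^2))
  }
  expect_lte(mism(100), mism(10) + 1e-9)
})

test_that("identical meshes register to the identity", {
  pr <- identicalPair()
  map2 <- sphericalParameterize(pr$S2$mesh)
  map1 <- sphericalParameterize(pr$S1$mesh, landmarks = pr$S1$landmarks,
                                targetPositions =
                                  spherePositions(map2)[pr$S2$landmarks, ],
                                gamma = 100)
  reg <- composeRegistration(map1, map2)
  expect_lt(max(sqrt(rowSums((reg - pr$S1$mesh@vertices)^2))), 1e-6)
  tp <- transferResection(pr$S2$paths[[1]], map1, map2)
  hd <- hausdorffStats(tp, pr$S1$paths[[1]])
  expect_lt(hd[["max"]], 1e-6)
  expect_identical(nrow(pathPoints(tp)), nrow(pathPoints(pr$S2$paths[[1]])))
})

test_that("the registered image lies on the target surface", {
  am <- asymmetricMaps()
  pr <- am$pair
  m1 <- sphericalParameterize(pr$S1$mesh, landmarks = pr$S1$landmarks,
                              targetPositions = am$targets, gamma = 100)
  reg <- composeRegistration(m1, am$map2)
  # every registered point is a barycentric point of some target face
  v <- pr$S2$mesh@vertices; f <- pr$S2$mesh@faces
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  idx <- sample(nrow(reg), 40)
  d <- vapply(idx, function(i) {
    x <- reg[i, ]
    fd <- Inf
    for (k in order(rowSums(sweep(ctr, 2, x)^2))[1:6]) {
      a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c <- v[f[k, 3], ]
      M <- cbind(b - a, c - a)
      uv <- pmax(pmin(solve(crossprod(M), crossprod(M, x - a)), 1), 0)
      q <- a + M %*% uv
      fd <- min(fd, sqrt(sum((x - q)^2)))
    }
    fd
  }, numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("path transfer round-trips within tolerance", {
  am <- asymmetricMaps()
  pr <- am$pair
  m1 <- sphericalParameterize(pr$S1$mesh, landmarks = pr$S1$landmarks,
                              targetPositions = am$targets, gamma = 100)
  p2 <- pr$S2$paths[[1]]
  onS1 <- transferResection(p2, m1, am$map2)
  back <- transferResection(onS1, am$map2, m1)
  expect_lt(max(sqrt(rowSums((pathPoints(back) - pathPoints(p2))^2))), 1e-3)
})

test_that("Hausdorff statistics follow their closed forms", {
  a <- cbind(0:5, 0, 0)
  expect_equal(unname(hausdorffStats(a, a)), c(0, 0, 0, 0))
  b <- cbind(0:5, 2, 0)  # parallel offset by 2
  expect_equal(unname(hausdorffStats(a, b)), c(2, 2, 2, 2))
  p1 <- matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  p2 <- matrix(c(3, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(unname(hausdorffStats(p1, p2)), c(3, 3, 3, 3))
  expect_error(hausdorffStats(matrix(0, 0, 3), a), "empty")
})
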