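squareLabels <- function() {
  arr <- array(0L, c(1, 30, 30)); arr[1, 6:25, 6:25] <- 1L
  labelVolume(arr)
}

test_that("a filled square yields one CCW contour with raster area 400", {
  cs <- extractSliceContours(squareLabels())
  expect_length(cs@contours[[1]], 1)
  expect_equal(cs@areas[[1]], 400)
  poly <- cs@contours[[1]][[1]]
  expect_gt(polygonSignedArea(poly), 0)  # counter-clockwise
  m <- rasterizePolygon(poly, 30, 30)
  expect_identical(m, labelArray(squareLabels())[1, , ] == 1L)
})

test_that("empty slices and disjoint blobs extract as expected", {
  arr <- array(0L, c(2, 20, 20))
  arr[2, 2:5, 2:5] <- 1L; arr[2, 10:15, 10:15] <- 1L
  cs <- extractSliceContours(labelVolume(arr))
  expect_length(cs@contours[[1]], 0)
  expect_length(cs@contours[[2]], 2)
})

test_that("probability volumes are Otsu-binarized before tracing", {
  vals <- array(0.1, c(1, 20, 20)); vals[1, 5:15, 5:15] <- 0.9
  cs <- extractSliceContours(probabilityVolume(vals))
  expect_length(cs@contours[[1]], 1)
  expect_equal(cs@areas[[1]], 121)
})

test_that("polygon simplification respects the tolerance contract", {
  cs <- extractSliceContours(squareLabels())
  poly <- cs@contours[[1]][[1]]
  expect_identical(approximatePolygon(poly, 0), poly)
  sq <- approximatePolygon(poly, 0.5)
  expect_identical(nrow(sq), 4L)
  # rasterized circle: vertex count drops, deviation bounded
  th <- seq(0, 2 * pi, length.out = 1441)[-1441]
  circ <- unique(round(cbind(60 + 50 * sin(th), 60 + 50 * cos(th))))
  simp <- approximatePolygon(circ, 2)
  expect_lt(nrow(simp), nrow(circ))
  rad <- sqrt(rowSums(sweep(simp, 2, c(60, 60))^2))
  expect_lt(max(abs(rad - 50)), 2 + 1)
  expect_error(approximatePolygon(poly, -1), ">= 0")
})

test_that("outer angles follow the exterior-angle convention", {
  sq <- ensureCcw(cbind(row = c(0, 0, 10, 10), col = c(0, 10, 10, 0)))
  expect_equal(outerAngles(sq), rep(270, 4))
  withMid <- ensureCcw(cbind(row = c(0, 0, 0, 10, 10),
                             col = c(0, 5, 10, 10, 0)))
  expect_equal(outerAngle(withMid, 2), 180)
  Lshape <- ensureCcw(cbind(row = c(0, 0, 10, 10, 20, 20),
                            col = c(0, 20, 20, 10, 10, 0)))
  ang <- outerAngles(Lshape)
  expect_equal(sort(unique(round(ang))), c(90, 270))
  expect_equal(sum(round(ang) == 90), 1)  # the single reflex notch
  dup <- rbind(sq, sq[4, ])
  expect_error(outerAngle(dup, 5), "duplicate")
})

test_that("a circle admits no bottleneck at Tb = 0.6 (minimal ratio 2/pi)", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(row = 150 + 100 * sin(th), col = 150 + 100 * cos(th))
  expect_identical(nrow(detectBottlenecks(circ)), 0L)
  # the minimal chord/arc ratio over admissible pairs approaches 2/pi
  relaxed <- detectBottlenecks(circ, Tb = 0.65)
  expect_gt(nrow(relaxed), 0)
  expect_equal(min(relaxed$epsilon), 2 / pi, tolerance = 1e-3)
})

test_that("a convex square has no bottlenecks", {
  big <- ensureCcw(cbind(row = c(0, 0, 100, 100), col = c(0, 100, 100, 0)))
  expect_identical(nrow(detectBottlenecks(big)), 0L)
})

dumbbellMask <- function() {
  mk <- matrix(0L, 200, 300)
  rr <- row(mk); cc <- col(mk)
  mk[(rr - 100)^2 + (cc - 80)^2 <= 1600] <- 1L
  mk[(rr - 100)^2 + (cc - 220)^2 <= 1600] <- 1L
  mk[abs(rr - 100) <= 3 & cc >= 80 & cc <= 220] <- 1L
  arr <- array(0L, c(1, 200, 300)); arr[1, , ] <- mk
  labelVolume(arr)
}

test_that("a thin-necked dumbbell is detected and split at the neck", {
  cs <- extractSliceContours(dumbbellMask())
  poly <- cs@contours[[1]][[1]]
  simp <- approximatePolygon(poly, 0.5)
  bn <- detectBottlenecks(simp)
  expect_gt(nrow(bn), 0)
  best <- bn[1, ]
  expect_lt(best$epsilon, 0.1)
  # the best chord crosses the neck (columns between the two discs)
  cols <- c(simp[best$i, 2], simp[best$j, 2])
  expect_true(all(cols > 80 & cols < 220))
  pieces <- removeBottleneck(simp, c(best$i, best$j))
  areas <- vapply(pieces, function(p) abs(polygonSignedArea(p)), numeric(1))
  expect_lt(abs(sum(areas) - abs(polygonSignedArea(simp))) /
              abs(polygonSignedArea(simp)), 0.02)
})

test_that("the bottleneck ratio is similarity-invariant", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  base <- cbind(row = 40 * sin(th) * (1 + 0.8 * cos(2 * th)),
                col = 60 * cos(th))
  bn0 <- detectBottlenecks(base, Tb = 0.9, minSeparation = 20)
  rot <- 0.7
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  moved <- 2.5 * base %*% R + matrix(c(500, 300), nrow(base), 2, byrow = TRUE)
  bn1 <- detectBottlenecks(moved, Tb = 0.9, minSeparation = 50)
  expect_gt(nrow(bn0), 0)
  expect_equal(bn0$epsilon[1], bn1$epsilon[1], tolerance = 1e-9)
})

test_that("degenerate pairs are rejected when splitting", {
  sq <- ensureCcw(cbind(row = c(0, 0, 10, 10), col = c(0, 10, 10, 0)))
  expect_error(removeBottleneck(sq, c(1, 2)), "degenerate|adjacent")
})

stackedContours <- function(masks, D = 1) {
  arr <- array(0L, c(length(masks), 40, 40))
  for (s in seq_along(masks)) arr[s, , ] <- masks[[s]]
  extractSliceContours(labelVolume(arr, sliceDistance = D))
}

sqMask <- function(r, c, half = 8) {
  m <- matrix(0L, 40, 40)
  m[(r - half):(r + half), (c - half):(c + half)] <- 1L
  m
}

test_that("interslice filtering keeps coherent stacks and drops orphans", {
  cs <- stackedContours(list(sqMask(20, 20), sqMask(20, 20), sqMask(20, 20)))
  kept <- intersliceFilter(cs)
  expect_equal(vapply(kept@contours, length, integer(1)), c(1L, 1L, 1L))
  # a contour disjoint from its neighbours disappears
  cs2 <- stackedContours(list(sqMask(10, 10), sqMask(30, 30), sqMask(10, 10)))
  kept2 <- intersliceFilter(cs2)
  expect_length(kept2@contours[[2]], 0)
})

test_that("half-overlapping equal squares fail T_s = 0.8 at D = 1", {
  cs <- stackedContours(list(sqMask(20, 12), sqMask(20, 21)), D = 1)
  # overlap ratio ~ 0.5 < 0.8
  kept <- intersliceFilter(cs)
  nKept <- sum(vapply(kept@contours, length, integer(1)))
  expect_identical(nKept, 1L)
})

test_that("interslice filtering is idempotent", {
  r <- organRun()
  cs <- extractSliceContours(r$res$gc$labels)
  once <- intersliceFilter(cs)
  twice <- intersliceFilter(once)
  expect_equal(once@contours, twice@contours)
})

test_that("post-processing never increases the labeled area per slice", {
  r <- organRun()
  before <- apply(labelArray(r$res$gc$labels), 1, sum)
  after <- apply(labelArray(r$res$labels), 1, sum)
  expect_true(all(after <= before + 1e-9))
})
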