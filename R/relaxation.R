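# Multi-slice relaxation labeling (MRL) over the two classes
# C = {liver, background}. Per-voxel class probabilities are updated
# synchronously:
#
#   Pr^{t+1}(a) = Pr^t(a) (1 + S(a)) / sum_b Pr^t(b) (1 + S(b))
#
# with the support S(a) a weighted sum of neighbour compatibilities
# (+1 same class, -1 different class) over the 26-neighbourhood, weighted by
# normalized inverse Euclidean distance in which the slice offset is scaled
# by the physical slice distance D.

#' Precompute the 26-neighbour MRL weight look-up table
#'
#' Unnormalized weights are `[(dx)^2 + (dy)^2 + D^2 (ds)^2]^(-1/2)` with
#' `dx, dy` in pixel units and `D` the slice distance in mm, then normalized
#' to sum to one over the 26 offsets. Setting `physicalUnits = TRUE` instead
#' measures `dx, dy` in mm using the pixel spacing.
#'
#' @param D slice distance in mm, > 0.
#' @param pixelSpacing in-plane spacing (dx, dy) in mm; used only when
#'   `physicalUnits = TRUE`.
#' @param physicalUnits measure in-plane offsets in mm instead of pixels.
#' @return a [NeighborWeights-class].
#' @export
mrlWeightTable <- function(D, pixelSpacing = c(1, 1), physicalUnits = FALSE) {
  if (length(D) != 1 || !is.finite(D) || D <= 0)
    stop("slice distance D must be a single positive number")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, ds = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  sc <- if (physicalUnits) pixelSpacing else c(1, 1)
  w <- 1 / sqrt((off[, 1] * sc[1])^2 + (off[, 2] * sc[2])^2 + D^2 * off[, 3]^2)
  new("NeighborWeights", offsets = unname(off), weights = unname(w / sum(w)),
      sliceDistance = D)
}

#' Unnormalized MRL weight of one offset
#'
#' @param offset integer(3) offset (dx, dy, ds).
#' @inheritParams mrlWeightTable
#' @export
mrlWeight <- function(offset, D, pixelSpacing = c(1, 1),
                      physicalUnits = FALSE) {
  sc <- if (physicalUnits) pixelSpacing else c(1, 1)
  1 / sqrt((offset[1] * sc[1])^2 + (offset[2] * sc[2])^2 + D^2 * offset[3]^2)
}

# shift a (slice, row, col) array by offset (dx, dy, ds); NA outside
shiftArray <- function(arr, dx, dy, ds) {
  d <- dim(arr)
  out <- array(NA_real_, d)
  sIdx <- seq_len(d[1]) + ds; rIdx <- seq_len(d[2]) + dy
  cIdx <- seq_len(d[3]) + dx
  sOk <- sIdx >= 1 & sIdx <= d[1]
  rOk <- rIdx >= 1 & rIdx <= d[2]
  cOk <- cIdx >= 1 & cIdx <= d[3]
  out[sOk, rOk, cOk] <- arr[sIdx[sOk], rIdx[rOk], cIdx[cOk]]
  out
}

# support field for the liver class; background support is its negation.
# Boundary voxels renormalize the weights over available neighbours.
supportField <- function(P, weights) {
  comp <- 2 * P - 1  # Pr(liver) - Pr(background)
  acc <- array(0, dim(P)); wacc <- array(0, dim(P))
  for (i in seq_len(nrow(weights@offsets))) {
    sh <- shiftArray(comp, weights@offsets[i, 1], weights@offsets[i, 2],
                     weights@offsets[i, 3])
    ok <- !is.na(sh)
    w <- weights@weights[i]
    acc[ok] <- acc[ok] + w * sh[ok]
    wacc <- wacc + w * ok
  }
  ifelse(wacc > 0, acc / wacc, 0)
}

#' Relaxation-labeling support for one voxel and class
#'
#' `S_p(a) = sum_q w_pq sum_b r_pq(a, b) Pr_q(b)` with compatibility +1 for
#' `a == b` and -1 otherwise; at volume borders the weights are renormalized
#' over the available neighbours. Always lies in `[-1, 1]`.
#'
#' @param liverProb 3D array of Pr(liver) per voxel (Pr(background) is its
#'   complement).
#' @param weights a [NeighborWeights-class].
#' @param voxel integer(3) 1-based (slice, row, col).
#' @param class "liver" or "background".
#' @export
mrlSupport <- function(liverProb, weights, voxel,
                       class = c("liver", "background")) {
  class <- match.arg(class)
  d <- dim(liverProb)
  acc <- 0; wacc <- 0
  for (i in seq_len(nrow(weights@offsets))) {
    q <- voxel + weights@offsets[i, c(3, 2, 1)]
    if (any(q < 1) || any(q > d)) next
    w <- weights@weights[i]
    acc <- acc + w * (2 * liverProb[q[1], q[2], q[3]] - 1)
    wacc <- wacc + w
  }
  s <- if (wacc > 0) acc / wacc else 0
  if (class == "liver") s else -s
}

#' Refine a probability map by multi-slice relaxation labeling
#'
#' Initializes `Pr(liver)` from the map and `Pr(background)` as its
#' complement, then applies the synchronous update for the stated number of
#' iterations (default 5) and returns the liver-class plane. Class
#' probabilities sum to one after every iteration.
#'
#' @param probmap a [ProbabilityVolume-class] (or 3D array in `[0, 1]`).
#' @param weights a [NeighborWeights-class]; defaults to the table for the
#'   map's slice distance.
#' @param iterations number of synchronous updates, >= 0.
#' @return a [ProbabilityVolume-class].
#' @export
relaxProbability <- function(probmap, weights = NULL, iterations = 5L) {
  if (iterations < 0) stop("iterations must be >= 0")
  isVol <- is(probmap, "ProbabilityVolume")
  P <- if (isVol) probmap@values else probmap
  if (is.null(weights))
    weights <- mrlWeightTable(if (isVol) probmap@sliceDistance else 1)
  for (t in seq_len(iterations)) {
    S <- supportField(P, weights)
    numA <- P * pmax(1 + S, 0)
    numB <- (1 - P) * pmax(1 - S, 0)
    den <- numA + numB
    P <- ifelse(den > 0, numA / den, P)
  }
  P <- pmin(pmax(P, 0), 1)
  if (isVol)
    probabilityVolume(P, pixelSpacing = probmap@pixelSpacing,
                      sliceDistance = probmap@sliceDistance,
                      origin = probmap@origin)
  else P
}
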