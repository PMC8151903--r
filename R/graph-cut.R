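# Binary segmentation energy
#
#   E(L) = alpha * sum_p R(l_p) + (1 - alpha) * sum_{p,q in N} B(p,q) [l_p != l_q]
#
# with region term R(liver) = 1 - Pr(liver | p), R(background) = Pr, and the
# structure-modulated boundary term
#
#   B(p,q) = exp(-F(p,q) |I(p) - I(q)|^2 / (2 delta^2)) / ||p - q||
#
# where F(p,q) = max(g(p), g(q)) is evaluated in-plane (F = 0 for cross-slice
# links, reducing B to pure distance weighting there) and ||p - q|| is the
# physical distance in mm. Solved exactly as a min s-t cut.

#' Graph-cut configuration
#'
#' @param alpha region/boundary balance in `[0, 1]` (default 0.6).
#' @param delta noise standard deviation; `NULL` auto-estimates the median
#'   absolute neighbour intensity difference (floored at 1).
#' @param neighborhood `"volumetric-26"` (default) or `"in-plane-8"`.
#' @param hardSeeds treat seed voxels as hard liver constraints.
#' @param solver `"bk"` (compiled Boykov-Kolmogorov max-flow, default) or
#'   `"igraph"` (push-relabel via [igraph::max_flow()]; exact but slow on
#'   large grids — retained as an independent cross-check).
#' @export
gcConfig <- function(alpha = 0.6, delta = NULL,
                     neighborhood = c("volumetric-26", "in-plane-8"),
                     hardSeeds = TRUE, solver = c("bk", "igraph")) {
  stopifnot(alpha >= 0, alpha <= 1, is.null(delta) || delta > 0)
  list(alpha = alpha, delta = delta,
       neighborhood = match.arg(neighborhood), hardSeeds = hardSeeds,
       solver = match.arg(solver))
}

#' Region term of the segmentation energy
#'
#' `R(liver) = 1 - prob`, `R(background) = prob`.
#'
#' @param prob liver probability in `[0, 1]` (vectorized).
#' @param label "liver" or "background".
#' @export
regionTerm <- function(prob, label = c("liver", "background")) {
  label <- match.arg(label)
  if (any(prob < 0 | prob > 1)) stop("probability outside [0, 1]")
  if (label == "liver") 1 - prob else prob
}

#' Boundary term of the segmentation energy
#'
#' Strictly positive and bounded by `1 / distance`; with `F = 0` (isotropic
#' pair) or equal intensities it reduces to pure inverse-distance weighting.
#'
#' @param Ip,Iq intensities of the two voxels.
#' @param F structural measure in `[0, 1]`.
#' @param distance physical distance in mm, > 0.
#' @param delta noise standard deviation, > 0.
#' @export
boundaryTerm <- function(Ip, Iq, F, distance, delta) {
  if (any(distance <= 0)) stop("distance must be > 0")
  if (any(delta <= 0)) stop("delta must be > 0")
  exp(-F * (Ip - Iq)^2 / (2 * delta^2)) / distance
}

#' Robust noise estimate: median absolute neighbour difference
#'
#' Median of |I(p) - I(q)| over the three axis-aligned neighbour pairs,
#' floored at 1.
#'
#' @param volume a [CtVolume-class] or 3D array.
#' @export
estimateNoiseSd <- function(volume) {
  arr <- if (is(volume, "CtVolume")) volume@intensities else volume
  d <- dim(arr)
  difs <- c(
    if (d[1] > 1) abs(arr[-1, , ] - arr[-d[1], , ]),
    if (d[2] > 1) abs(arr[, -1, ] - arr[, -d[2], ]),
    if (d[3] > 1) abs(arr[, , -1] - arr[, , -d[3]]))
  max(stats::median(difs), 1)
}

halfOffsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(ds = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  # keep one representative of each +/- pair (lexicographically positive)
  keep <- off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
    (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0)
  off <- off[keep, , drop = FALSE]
  if (neighborhood == "in-plane-8") off <- off[off[, 1] == 0, , drop = FALSE]
  off  # columns: ds, dy, dx
}

# linear voxel ids of every in-range (p, q = p + off) pair, plus slice flags
offsetPairs <- function(d, off) {
  sIdx <- seq_len(d[1] - abs(off[1])); if (off[1] < 0) sIdx <- sIdx + abs(off[1])
  rIdx <- seq_len(d[2] - abs(off[2])); if (off[2] < 0) rIdx <- rIdx + abs(off[2])
  cIdx <- seq_len(d[3] - abs(off[3])); if (off[3] < 0) cIdx <- cIdx + abs(off[3])
  lin <- function(s, r, c)
    as.vector(outer(outer(s, (r - 1) * d[1], `+`), (c - 1) * d[1] * d[2], `+`))
  list(p = lin(sIdx, rIdx, cIdx),
       q = lin(sIdx + off[1], rIdx + off[2], cIdx + off[3]))
}

#' Eq-style energy of a labeling
#'
#' Evaluates the full segmentation energy of an arbitrary labeling under the
#' same terms the solver uses; the enumeration oracle in the tests minimizes
#' this directly.
#'
#' @param volume a [CtVolume-class].
#' @param prob a [ProbabilityVolume-class].
#' @param gvol 3D array of the anisotropic measure (from
#'   [anisotropyVolume()]).
#' @param labels 3D 0/1 array (1 = liver).
#' @param cfg a [gcConfig()]; `delta` must be resolved or auto-estimable.
#' @export
gcEnergy <- function(volume, prob, gvol, labels, cfg = gcConfig()) {
  d <- dim(volume)
  delta <- if (is.null(cfg$delta)) estimateNoiseSd(volume) else cfg$delta
  P <- as.vector(prob@values); L <- as.vector(labels)
  I <- as.vector(volume@intensities); G <- as.vector(gvol)
  e <- cfg$alpha * sum(ifelse(L == 1, 1 - P, P))
  sp <- c(volume@pixelSpacing, volume@sliceDistance)
  for (i in seq_len(nrow(halfOffsets(cfg$neighborhood)))) {
    off <- halfOffsets(cfg$neighborhood)[i, ]
    pr <- offsetPairs(d, off)
    cut <- L[pr$p] != L[pr$q]
    if (!any(cut)) next
    dist <- sqrt((off[3] * sp[1])^2 + (off[2] * sp[2])^2 + (off[1] * sp[3])^2)
    F <- if (off[1] == 0) pmax(G[pr$p[cut]], G[pr$q[cut]]) else 0
    e <- e + (1 - cfg$alpha) *
      sum(boundaryTerm(I[pr$p[cut]], I[pr$q[cut]], F, dist, delta))
  }
  e
}

#' Segment a volume by exact min-cut
#'
#' Builds the s-t graph (t-links `alpha * R`, n-links `(1 - alpha) * B` over
#' the configured neighbourhood with physical mm distances) and solves it by
#' max-flow. Seed voxels receive an effectively infinite liver t-link when
#' `hardSeeds` is set.
#'
#' @param volume a [CtVolume-class].
#' @param prob a [ProbabilityVolume-class] co-registered with `volume`.
#' @param gvol 3D anisotropic-measure array; `NULL` computes it.
#' @param cfg a [gcConfig()].
#' @param seeds k-by-3 matrix of liver seed voxels (slice, row, col), or NULL.
#' @param bgSeeds optional background seed voxels, same layout.
#' @return list with `labels` (a [LabelVolume-class]), `energy` (energy of
#'   the returned labeling) and `flow` (max-flow value).
#' @export
segmentMincut <- function(volume, prob, gvol = NULL, cfg = gcConfig(),
                          seeds = NULL, bgSeeds = NULL) {
  d <- dim(volume)
  if (!identical(dim(prob), d)) stop("probability map and volume differ in shape")
  if (all(prob@values == 0) && is.null(seeds))
    stop("empty probability map and no seeds: nothing to segment")
  if (is.null(gvol)) gvol <- anisotropyVolume(volume)
  delta <- if (is.null(cfg$delta)) estimateNoiseSd(volume) else cfg$delta
  n <- prod(d)
  P <- as.vector(prob@values); I <- as.vector(volume@intensities)
  G <- as.vector(gvol)
  sp <- c(volume@pixelSpacing, volume@sliceDistance)

  from <- vector("list", 16); to <- vector("list", 16); cap <- vector("list", 16)
  k <- 0
  offs <- halfOffsets(cfg$neighborhood)
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    pr <- offsetPairs(d, off)
    dist <- sqrt((off[3] * sp[1])^2 + (off[2] * sp[2])^2 + (off[1] * sp[3])^2)
    F <- if (off[1] == 0) pmax(G[pr$p], G[pr$q]) else 0
    B <- (1 - cfg$alpha) * boundaryTerm(I[pr$p], I[pr$q], F, dist, delta)
    k <- k + 1; from[[k]] <- pr$p; to[[k]] <- pr$q; cap[[k]] <- B
  }
  eFrom <- unlist(from, use.names = FALSE)
  eTo <- unlist(to, use.names = FALSE)
  eCap <- unlist(cap, use.names = FALSE)
  # src cap = alpha * R(background) = alpha * P  (cut when p background)
  # snk cap = alpha * R(liver) = alpha * (1 - P) (cut when p liver)
  srcCap <- cfg$alpha * P
  snkCap <- cfg$alpha * (1 - P)
  big <- sum(eCap) + sum(srcCap) + sum(snkCap) + 1
  linId <- function(m) {
    m <- matrix(as.integer(m), ncol = 3)
    m[, 1] + (m[, 2] - 1L) * d[1] + (m[, 3] - 1L) * d[1] * d[2]
  }
  if (!is.null(seeds) && cfg$hardSeeds) srcCap[linId(seeds)] <- big
  if (!is.null(bgSeeds) && cfg$hardSeeds) snkCap[linId(bgSeeds)] <- big
  if (cfg$solver == "bk") {
    mf <- .bkMaxflow(n, eFrom - 1L, eTo - 1L, eCap, srcCap, snkCap)
    lab <- as.integer(mf$sourceSide)
    flow <- mf$flow
  } else {
    src <- n + 1L; snk <- n + 2L
    g <- igraph::make_graph(rbind(c(eFrom, rep(src, n), seq_len(n)),
                                  c(eTo, seq_len(n), rep(snk, n))),
                            n = n + 2L, directed = FALSE)
    mf <- igraph::max_flow(g, source = src, target = snk,
                           capacity = c(eCap, srcCap, snkCap))
    lab <- integer(n)
    p1 <- as.integer(mf$partition1)
    if (src %in% p1) lab[p1[p1 <= n]] <- 1L else {
      p2 <- as.integer(mf$partition2); lab[p2[p2 <= n]] <- 1L
    }
    flow <- mf$value
  }
  labels <- labelVolume(array(lab, d), pixelSpacing = volume@pixelSpacing,
                        sliceDistance = volume@sliceDistance,
                        origin = volume@origin)
  energy <- gcEnergy(volume, prob, gvol,
                     array(lab, d), modifyList(cfg, list(delta = delta)))
  list(labels = labels, energy = energy, flow = flow)
}
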