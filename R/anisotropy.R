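# Local orientation, anisotropic measure and corner strength of a 2D slice,
# from windowed products of first-order central differences (a structure
# tensor in integral form). Only the anisotropic measure g feeds the
# segmentation energy; theta, c, s1, s2 are exposed for completeness.

centralDiff <- function(img, along) {
  nr <- nrow(img); nc <- ncol(img)
  if (along == "x") { # columns
    (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
  } else {            # rows
    (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  }
}

#' Structure field of a 2D image
#'
#' First-order derivatives by central differences; windowed sums over a
#' `(2r+1) x (2r+1)` box replace the neighbourhood integrals. The local
#' orientation is
#' `theta = atan2(S_2fxfy, S_(fx^2 - fy^2)) / 2 + pi/2` (mapped to `[0, pi)`),
#' the anisotropic measure
#' `g = (S_(fx^2 - fy^2)^2 + S_2fxfy^2) / S_(fx^2 + fy^2)^2` (clamped to
#' `[0, 1]`, 0 where the denominator vanishes), the corner strength
#' `c = (1 - g) |grad f|^2`, and the adaptive kernel axes
#' `s1 = r / (1 + c / lambda)`, `s2 = (1 - g) s1`, so an isotropic region has
#' a circular kernel (`s1 = s2 = r`) and structure shrinks the minor axis.
#'
#' @param img 2D numeric matrix (one axial slice, rows = y, cols = x).
#' @param r support radius of the integration window (default 3).
#' @param lambda corner-strength weight (default 0.75).
#' @return a [StructureField-class].
#' @export
structureField <- function(img, r = 3L, lambda = 0.75) {
  img <- as.matrix(img)
  win <- 2L * as.integer(r) + 1L
  if (win > nrow(img) || win > ncol(img))
    stop("integration window larger than the image")
  fx <- centralDiff(img, "x")
  fy <- centralDiff(img, "y")
  A <- boxSums(fx * fx - fy * fy, win)
  B <- boxSums(2 * fx * fy, win)
  C <- boxSums(fx * fx + fy * fy, win)
  g <- ifelse(C > 0, (A^2 + B^2) / C^2, 0)
  g <- pmin(pmax(g, 0), 1)
  theta <- ifelse(C > 0, atan2(B, A) / 2 + pi / 2, 0)
  theta <- theta %% pi
  cc <- (1 - g) * (fx^2 + fy^2)
  s1 <- r / (1 + cc / lambda)
  s2 <- (1 - g) * s1
  new("StructureField", theta = theta, g = g, c = cc, s1 = s1, s2 = s2,
      r = as.numeric(r), lambda = lambda)
}

#' Pairwise structural measure
#'
#' `F(p, q) = max(g(p), g(q))`: the larger of the two pixels' anisotropic
#' measures. Symmetric, in `[0, 1]`, and 0 when both pixels lie in an
#' isotropic (e.g. constant) region.
#'
#' @param field a [StructureField-class].
#' @param p,q integer(2) pixel coordinates (row, col).
#' @export
pairwiseStructuralMeasure <- function(field, p, q) {
  max(field@g[p[1], p[2]], field@g[q[1], q[2]])
}

#' Per-slice anisotropy volumes for a CT volume
#'
#' Runs [structureField()] on every axial slice and returns the g-volume
#' consumed by the graph-cut boundary term.
#'
#' @param volume a [CtVolume-class].
#' @inheritParams structureField
#' @return 3D array of the anisotropic measure g, same dimensions as the
#'   volume.
#' @export
anisotropyVolume <- function(volume, r = 3L, lambda = 0.75) {
  d <- dim(volume)
  g <- array(0, d)
  for (s in seq_len(d[1]))
    g[s, , ] <- structureField(volume@intensities[s, , ], r, lambda)@g
  g
}
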