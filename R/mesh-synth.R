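# Synthetic genus-0 liver-like mesh pairs with 11 labelled landmarks and
# resection polylines, built as radial deformations of a common subdivided
# icosahedron. Because both meshes share the sphere parameterization (the
# same base topology and parametric landmark directions), landmark k on S1
# corresponds to landmark k on S2 by construction, and resection paths are
# constant-parameter curves through landmark directions, making transfer
# accuracy checkable by construction.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangleMesh(v, f)
}

#' Unit icosphere
#'
#' @param level subdivision level (0 = icosahedron; vertex count
#'   `10 * 4^level + 2`).
#' @return a [TriangleMesh-class] with unit-norm vertices.
#' @export
icosphere <- function(level = 3) {
  m <- icosahedron()
  for (i in seq_len(level)) {
    m <- midpointSubdivide(m)
    m@vertices <- m@vertices / sqrt(rowSums(m@vertices^2))
  }
  if (meshVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

# parametric landmark directions (unit vectors); labels 1-11.
# The left system (labels 1, 2, 3, 4, 10) occupies the x < 0 hemisphere,
# the right system the x > 0 hemisphere.
landmarkDirections <- function() {
  d <- rbind(
    c(-0.35, 0.80, 0.45),   # 1  gallbladder-fossa-like anterior point
    c(-0.65, 0.55, -0.25),  # 2  falciform-ligament-like point
    c(-0.80, 0.10, 0.55),   # 3  LHV path intersection
    c(-0.85, -0.30, -0.30), # 4  LHV/LPV intersection
    c(0.10, 0.95, 0.10),    # 5  MHV path point
    c(0.15, 0.70, -0.65),   # 6  falciform/fossa right point
    c(0.75, 0.45, 0.45),    # 7  RHV intersection
    c(0.85, 0.05, -0.45),   # 8  RHV/RPV intersection
    c(0.70, -0.55, 0.35),   # 9  RHV inferior point
    c(-0.55, -0.65, 0.45),  # 10 LPV virtual-path point
    c(0.45, -0.70, -0.50))  # 11 RPV virtual-path point
  d / sqrt(rowSums(d^2))
}

slerp <- function(a, b, t) {
  w <- acos(min(max(sum(a * b), -1), 1))
  if (w < 1e-12) return(matrix(rep(a, length(t)), ncol = 3, byrow = TRUE))
  (outer(sin((1 - t) * w), a) + outer(sin(t * w), b)) / sin(w)
}

# resection paths as geodesic arcs through landmark directions
resectionDirections <- function(nPer = 24) {
  lm <- landmarkDirections()
  arc <- function(idx) {
    pts <- lapply(seq_len(length(idx) - 1), function(i) {
      s <- slerp(lm[idx[i], ], lm[idx[i + 1], ],
                 seq(0, 1, length.out = nPer)[-nPer])
      s
    })
    p <- do.call(rbind, pts)
    rbind(p, lm[idx[length(idx)], ])
  }
  list(LHV = arc(c(2, 3, 4)), MHV = arc(c(6, 5, 1)), RHV = arc(c(7, 8, 9)),
       LPV = arc(c(4, 10)), RPV = arc(c(8, 11)))
}

#' Specify a synthetic liver-like mesh pair
#'
#' @param subdivision icosphere subdivision level (default 4: 2562
#'   vertices).
#' @param deformAmplitude numeric(2) smooth-bump amplitudes for S1 and S2.
#' @param scaleRatio global scale of S2 relative to S1.
#' @param asymmetry extra deformation applied to S2 on the right-hand
#'   (`x > 0`) side only; makes the pair's right hemi-livers genuinely less
#'   corresponding than the left.
#' @param rotationS2 rigid rotation (radians, about a fixed oblique axis)
#'   applied to S2 and its paths. It emulates the arbitrary patient
#'   orientation / Moebius freedom that landmark constraints must absorb;
#'   0 leaves the pair in a common frame.
#' @param seed integer seed controlling the bump phases.
#' @return a `MeshPairSpec` list.
#' @export
meshPairSpec <- function(subdivision = 4, deformAmplitude = c(0.12, 0.12),
                         scaleRatio = 1, asymmetry = 0, rotationS2 = 0.4,
                         seed = 1L) {
  stopifnot(subdivision >= 1, all(deformAmplitude >= 0), scaleRatio > 0,
            asymmetry >= 0)
  structure(list(subdivision = as.integer(subdivision),
                 deformAmplitude = deformAmplitude, scaleRatio = scaleRatio,
                 asymmetry = asymmetry, rotationS2 = rotationS2,
                 seed = as.integer(seed)),
            class = "MeshPairSpec")
}

liverRadialShape <- function(dirs, amplitude, phases, asym = 0) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  bumps <- sin(2 * x + phases[1]) * cos(1.5 * y + phases[2]) * 0.5 +
    sin(1.5 * y + phases[3]) * cos(2 * z + phases[4]) * 0.3 +
    sin(2 * z + phases[5]) * cos(1.5 * x + phases[6]) * 0.2
  r <- 1 + amplitude * bumps
  if (asym > 0)
    r <- r + asym * pmax(x, 0)^2 *
      (sin(3 * y + phases[7]) * cos(2 * z + phases[8]))
  if (any(r <= 0.1))
    stop("deformation amplitude large enough to self-intersect the surface")
  r
}

#' Generate a corresponding pair of liver-like meshes
#'
#' Both meshes are radial deformations (over an anisotropic liver-like base
#' ellipsoid) of the same subdivided icosahedron. Landmarks are the mesh
#' vertices nearest to 11 fixed parametric directions — the same vertex
#' indices on both meshes — and resection paths are geodesic arcs through
#' landmark directions, projected onto each surface.
#'
#' @param spec a [meshPairSpec()].
#' @return list with `S1` and `S2`, each containing `mesh`
#'   ([TriangleMesh-class]), `landmarks` (named vector, labels "1".."11")
#'   and `paths` (list of [ResectionPath-class]).
#' @export
generateLiverMeshPair <- function(spec) {
  stopifnot(inherits(spec, "MeshPairSpec"))
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(spec$seed)
  phases <- runif(8, 0, 2 * pi)

  base <- icosphere(spec$subdivision)
  dirs <- base@vertices
  ellip <- c(1.6, 1.15, 0.85)  # anterior-posterior / lateral / cranio-caudal

  buildMesh <- function(amplitude, scale, asym) {
    r <- liverRadialShape(dirs, amplitude, phases, asym)
    v <- (dirs * r) %*% diag(ellip) * scale * 50  # ~80-160 mm extent
    triangleMesh(v, base@faces)
  }
  onSurface <- function(mesh, d) {
    # point on the mesh along parametric direction d (barycentric on the
    # icosphere triangulation, applied to the deformed vertices)
    loc <- locateOnIcosphere(base, d)
    f <- base@faces[loc$face, ]
    loc$bary[1] * mesh@vertices[f[1], ] + loc$bary[2] * mesh@vertices[f[2], ] +
      loc$bary[3] * mesh@vertices[f[3], ]
  }
  build <- function(amplitude, scale, asym) {
    mesh <- buildMesh(amplitude, scale, asym)
    lmDir <- landmarkDirections()
    lmIdx <- apply(lmDir, 1, function(d) which.max(dirs %*% d))
    names(lmIdx) <- as.character(1:11)
    paths <- lapply(names(resectionDirections()), function(lbl) {
      dmat <- resectionDirections()[[lbl]]
      pts <- t(apply(dmat, 1, function(d) onSurface(mesh, d)))
      resectionPath(pts, lbl)
    })
    list(mesh = mesh, landmarks = lmIdx, paths = paths)
  }
  S1 <- build(spec$deformAmplitude[1], 1, 0)
  S2 <- build(spec$deformAmplitude[2], spec$scaleRatio, spec$asymmetry)
  if (spec$rotationS2 != 0) {
    ax <- c(0.3, 1, 0.25); ax <- ax / sqrt(sum(ax^2))
    ct <- cos(spec$rotationS2); st <- sin(spec$rotationS2)
    VX <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    Rr <- diag(3) * ct + st * VX + (1 - ct) * outer(ax, ax)
    S2$mesh@vertices <- S2$mesh@vertices %*% t(Rr)
    S2$paths <- lapply(S2$paths, function(p)
      resectionPath(p@points %*% t(Rr), p@label))
  }
  list(S1 = S1, S2 = S2)
}

locateOnIcosphere <- function(base, d) {
  f <- base@faces; v <- base@vertices
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  ord <- order(ctr %*% d, decreasing = TRUE)
  for (k in ord[seq_len(min(48, length(ord)))]) {
    M <- rbind(v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
    w <- tryCatch(solve(t(M), d), error = function(e) NULL)
    if (!is.null(w) && all(w >= -1e-9)) {
      w <- pmax(w, 0)
      return(list(face = k, bary = w / sum(w)))
    }
  }
  k <- ord[1]
  M <- rbind(v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
  w <- pmax(solve(t(M), d), 0)
  list(face = k, bary = w / sum(w))
}
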