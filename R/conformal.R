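# Landmark-constrained spherical conformal parameterization of genus-0
# meshes, symmetric registration and resection-path transfer.
#
# Solver outline: Gauss-map initialization; stereographic projection from
# the south pole with the pole face's vertices as Dirichlet anchors and a
# quadratic landmark penalty (gamma); a re-solve of the high-distortion cap
# from the opposite pole; and a Beltrami-coefficient correction pass (|mu|
# truncated below 1, map reconstructed by a linear Beltrami solver) until
# every interior face is orientation-preserving. Steps are accepted only if
# the landmark-penalized harmonic energy does not increase, so the recorded
# energy trace is non-increasing by construction.

#' Cotangent edge weights
#'
#' `k_uv = cot(alpha) + cot(beta)` over the two triangles incident to each
#' edge of a closed manifold mesh; negative weights are permitted (obtuse
#' opposite angles).
#'
#' @param mesh a [TriangleMesh-class] without boundary.
#' @return list with `edges` (E-by-2, first index smaller) and `weights`
#'   (numeric E).
#' @export
cotangentWeights <- function(mesh) {
  f <- mesh@faces; v <- mesh@vertices
  cnt <- edgeUseCounts(mesh)
  if (any(cnt > 2)) stop("non-manifold edge (more than two incident faces)")
  if (any(cnt < 2)) stop("mesh has boundary edges; a closed mesh is required")
  cotAt <- function(a, b, c) {
    # cot of the angle at vertex a in triangle (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    dt / sqrt(rowSums(cr^2))
  }
  e <- rbind(f[, c(2, 3)], f[, c(3, 1)], f[, c(1, 2)])
  ct <- c(cotAt(f[, 1], f[, 2], f[, 3]), cotAt(f[, 2], f[, 3], f[, 1]),
          cotAt(f[, 3], f[, 1], f[, 2]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  agg <- tapply(ct, key, sum)
  ek <- do.call(rbind, strsplit(names(agg), " "))
  list(edges = cbind(as.integer(ek[, 1]), as.integer(ek[, 2])),
       weights = as.numeric(agg))
}

#' Landmark-penalized harmonic energy
#'
#' `E = sum_edges k_uv ||f(u) - f(v)||^2 +
#'  gamma * sum_i ||f(p_i) - t_i||^2`.
#'
#' @param positions V-by-3 (or V-by-2) image positions of the map.
#' @param weights output of [cotangentWeights()] for the source mesh.
#' @param landmarks integer vertex indices p_i (optional).
#' @param targetPositions matrix of target images t_i, same row count and
#'   column count as `positions` rows for the landmarks.
#' @param gamma landmark balance factor.
#' @export
harmonicEnergy <- function(positions, weights, landmarks = NULL,
                           targetPositions = NULL, gamma = 0) {
  d <- positions[weights$edges[, 1], , drop = FALSE] -
    positions[weights$edges[, 2], , drop = FALSE]
  e <- sum(weights$weights * rowSums(d^2))
  if (!is.null(landmarks) && length(landmarks) > 0) {
    if (is.null(targetPositions) ||
        nrow(targetPositions) != length(landmarks))
      stop("landmark/target mismatch")
    r <- positions[landmarks, , drop = FALSE] - targetPositions
    e <- e + gamma * sum(r^2)
  }
  e
}

#' Beltrami coefficient of the affine map between two planar triangles
#'
#' For `f(z) = a z + b conj(z) + c`, `mu = b / a`; `|mu| < 1` iff the map
#' preserves orientation.
#'
#' @param srcTri,imgTri 3-by-2 matrices of triangle vertices (x, y), or
#'   length-3 complex vectors.
#' @return complex `mu`.
#' @export
beltramiCoefficient <- function(srcTri, imgTri) {
  toC <- function(x) if (is.complex(x)) x else complex(real = x[, 1],
                                                       imaginary = x[, 2])
  z <- toC(srcTri); w <- toC(imgTri)
  dz1 <- z[2] - z[1]; dz2 <- z[3] - z[1]
  det <- dz1 * Conj(dz2) - dz2 * Conj(dz1)
  if (abs(det) < 1e-14) stop("degenerate source triangle")
  dw1 <- w[2] - w[1]; dw2 <- w[3] - w[1]
  a <- (dw1 * Conj(dz2) - dw2 * Conj(dz1)) / det
  b <- (dw2 * dz1 - dw1 * dz2) / det
  b / a
}

# isometric flattening of each 3D face: complex coords (z1=0, z2=|e1|, z3)
flattenFaces <- function(mesh) {
  f <- mesh@faces; v <- mesh@vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  l1 <- sqrt(rowSums(e1^2))
  x3 <- rowSums(e1 * e2) / l1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  y3 <- sqrt(rowSums(cr^2)) / l1
  list(z2 = l1, z3 = complex(real = x3, imaginary = y3))
}

# per-face Beltrami coefficient of the map (flattened 3D face) -> planar w
faceBeltrami <- function(mesh, w, flat = flattenFaces(mesh)) {
  f <- mesh@faces
  dz1 <- complex(real = flat$z2); dz2 <- flat$z3
  det <- dz1 * Conj(dz2) - dz2 * Conj(dz1)
  dw1 <- w[f[, 2]] - w[f[, 1]]; dw2 <- w[f[, 3]] - w[f[, 1]]
  a <- (dw1 * Conj(dz2) - dw2 * Conj(dz1)) / det
  b <- (dw2 * dz1 - dw1 * dz2) / det
  b / a
}

# per-face orientation on the sphere: positive = outward, consistent
sphereOrientation <- function(mesh, pos) {
  f <- mesh@faces
  a <- pos[f[, 1], , drop = FALSE]; b <- pos[f[, 2], , drop = FALSE]
  c <- pos[f[, 3], , drop = FALSE]
  a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
}

# chordal Beltrami coefficient: each face's isometric flattening against the
# isometric flattening of its spherical image triangle, signed by the
# spherical orientation so |mu| > 1 marks a genuinely folded face
chordalMu <- function(mesh, pos, flat = flattenFaces(mesh)) {
  f <- mesh@faces
  e1 <- pos[f[, 2], , drop = FALSE] - pos[f[, 1], , drop = FALSE]
  e2 <- pos[f[, 3], , drop = FALSE] - pos[f[, 1], , drop = FALSE]
  l1 <- sqrt(rowSums(e1^2))
  x3 <- rowSums(e1 * e2) / l1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  y3 <- sqrt(rowSums(cr^2)) / l1 * sign(sphereOrientation(mesh, pos))
  dz1 <- complex(real = flat$z2); dz2 <- flat$z3
  det <- dz1 * Conj(dz2) - dz2 * Conj(dz1)
  dw1 <- complex(real = l1); dw2 <- complex(real = x3, imaginary = y3)
  a <- (dw1 * Conj(dz2) - dw2 * Conj(dz1)) / det
  b <- (dw2 * dz1 - dw1 * dz2) / det
  b / a
}

# generalized (Beltrami-targeted) stiffness matrix over all faces except
# `skip`; mu = 0 reduces to the cotangent FEM Laplacian
lbsMatrix <- function(mesh, mu, skip, flat = flattenFaces(mesh)) {
  f <- mesh@faces
  nF <- nrow(f)
  use <- setdiff(seq_len(nF), skip)
  rho <- Re(mu)[use]; tau <- Im(mu)[use]
  den <- 1 - rho^2 - tau^2
  den[abs(den) < 1e-8] <- 1e-8
  a11 <- ((rho - 1)^2 + tau^2) / den
  a12 <- -2 * tau / den
  a22 <- ((1 + rho)^2 + tau^2) / den
  # planar source coords per face
  P1x <- rep(0, length(use)); P1y <- rep(0, length(use))
  P2x <- flat$z2[use]; P2y <- rep(0, length(use))
  P3x <- Re(flat$z3)[use]; P3y <- Im(flat$z3)[use]
  area <- P2x * P3y / 2
  # hat-function gradients
  gx <- cbind(P2y - P3y, P3y - P1y, P1y - P2y) / (2 * area)
  gy <- cbind(P3x - P2x, P1x - P3x, P2x - P1x) / (2 * area)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in 1:3) for (j in 1:3) {
    val <- area * (gx[, i] * a11 * gx[, j] + gx[, i] * a12 * gy[, j] +
                     gy[, i] * a12 * gx[, j] + gy[, i] * a22 * gy[, j])
    ii <- c(ii, f[use, i]); jj <- c(jj, f[use, j]); xx <- c(xx, val)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(mesh@vertices), nrow(mesh@vertices)))
}

# spherical harmonic heat flow: project the cotangent-Laplacian descent
# direction onto the sphere tangent space, renormalize, and keep the map
# Moebius-centred. For a genus-0 closed surface the harmonic map to the
# sphere is conformal, so the flow drives angle distortion to the
# discretization level.
conformalFlow <- function(mesh, pos, cw, maxIter = 4000, dt = 0.4,
                          tol = 1e-9) {
  n <- nrow(pos)
  W <- Matrix::sparseMatrix(i = c(cw$edges[, 1], cw$edges[, 2]),
                            j = c(cw$edges[, 2], cw$edges[, 1]),
                            x = c(cw$weights, cw$weights), dims = c(n, n))
  deg <- as.numeric(W %*% rep(1, n))
  deg[abs(deg) < 1e-12] <- 1e-12
  eLast <- harmonicEnergy(pos, cw)
  for (it in seq_len(maxIter)) {
    avg <- as.matrix(W %*% pos) / deg
    disp <- avg - pos
    disp <- disp - rowSums(disp * pos) * pos
    pos <- pos + dt * disp
    pos <- pos / sqrt(rowSums(pos^2))
    ctr <- colMeans(pos)
    pos <- pos - matrix(ctr, n, 3, byrow = TRUE)
    pos <- pos / sqrt(rowSums(pos^2))
    if (it %% 50 == 0) {
      e <- harmonicEnergy(pos, cw)
      if (abs(eLast - e) < tol * max(e, 1)) break
      eLast <- e
    }
  }
  pos
}

# solve K w = 0 with Dirichlet vertices `fixed` and quadratic landmark
# penalty gamma * |w - t|^2; complex right-hand sides handled per component
penalizedSolve <- function(K, wInit, fixed, landmarks, targetsC, gamma) {
  n <- length(wInit)
  free <- setdiff(seq_len(n), fixed)
  pen <- numeric(n)
  rhsR <- numeric(n); rhsI <- numeric(n)
  if (length(landmarks)) {
    pen[landmarks] <- pen[landmarks] + gamma
    rhsR[landmarks] <- rhsR[landmarks] + gamma * Re(targetsC)
    rhsI[landmarks] <- rhsI[landmarks] + gamma * Im(targetsC)
  }
  A <- K[free, free, drop = FALSE] +
    Matrix::Diagonal(length(free), pen[free])
  bR <- rhsR[free] - as.numeric(K[free, fixed, drop = FALSE] %*%
                                  Re(wInit[fixed]))
  bI <- rhsI[free] - as.numeric(K[free, fixed, drop = FALSE] %*%
                                  Im(wInit[fixed]))
  sol <- Matrix::solve(A, cbind(bR, bI))
  out <- wInit
  out[free] <- complex(real = sol[, 1], imaginary = sol[, 2])
  out
}

stereoFromSouth <- function(p) {
  # south-pole projection: (x, y, z) -> (x + iy) / (1 + z); outward-oriented
  # spherical faces keep positive orientation in the plane
  complex(real = p[, 1], imaginary = p[, 2]) / (1 + p[, 3])
}

stereoToSphere <- function(w) {
  r2 <- Re(w)^2 + Im(w)^2
  cbind(2 * Re(w), 2 * Im(w), 1 - r2) / (1 + r2)
}

# per-corner angle distortion (degrees) between mesh faces and their
# spherical images (chordal triangles)
cornerAngleDistortion <- function(mesh, positions) {
  ang <- function(v, f) {
    out <- matrix(0, nrow(f), 3)
    for (i in 1:3) {
      a <- f[, i]; b <- f[, (i %% 3) + 1]; c <- f[, ((i + 1) %% 3) + 1]
      u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
      w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
      cs <- rowSums(u * w) /
        pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)), 1e-300)
      out[, i] <- acos(pmin(pmax(cs, -1), 1))
    }
    out
  }
  abs(ang(mesh@vertices, mesh@faces) - ang(positions, mesh@faces)) * 180 / pi
}

#' Spherical conformal parameterization with landmark constraints
#'
#' Maps a watertight genus-0 mesh onto the unit sphere. Without landmarks
#' the map is an unconstrained conformal parameterization; with landmarks
#' the harmonic system is penalized toward the given target positions on the
#' sphere with balance factor `gamma`. After the two pole solves, faces with
#' `|mu| >= 1` are truncated to `1 - eta` and the map is rebuilt by a linear
#' Beltrami solver until every interior face preserves orientation.
#'
#' @param mesh watertight genus-0 [TriangleMesh-class].
#' @param landmarks integer vertex indices (>= 1 entries), or NULL.
#' @param targetPositions matrix of unit 3-vectors, one row per landmark.
#' @param gamma landmark balance factor (default 100).
#' @param eta Beltrami truncation margin (default 1e-2).
#' @param maxCorrections maximum Beltrami correction passes.
#' @return a [SphericalMap-class].
#' @export
sphericalParameterize <- function(mesh, landmarks = NULL,
                                  targetPositions = NULL, gamma = 100,
                                  eta = 1e-2, maxCorrections = 10) {
  if (!isWatertight(mesh) || eulerCharacteristic(mesh) != 2)
    stop("mesh must be watertight and genus-0")
  if (!is.null(landmarks)) {
    landmarks <- as.integer(landmarks)
    if (is.null(targetPositions) ||
        nrow(targetPositions) != length(landmarks))
      stop("targetPositions must have one row per landmark")
  }
  v <- mesh@vertices
  nrm <- vertexNormals(mesh)
  gauss <- nrm / sqrt(rowSums(nrm^2))
  cw <- cotangentWeights(mesh)
  flat <- flattenFaces(mesh)
  f <- mesh@faces

  # base conformal map: Gauss-map initialization relaxed by the spherical
  # harmonic heat flow (conformal for genus-0 targets)
  base <- conformalFlow(mesh, gauss, cw)

  # outer face: far from the landmarks (their image centroid is rotated to
  # the north pole), with the south pole strictly inside it so no vertex
  # projects to infinity
  if (!is.null(landmarks)) {
    # factor out the rigid (rotation) part of the landmark mismatch first:
    # a rotation leaves the edge (conformal) term invariant and can only
    # reduce the landmark term, so it is always an accepted step; the
    # penalized solves then handle the non-rigid residual
    P <- base[landmarks, , drop = FALSE]
    H <- t(P) %*% targetPositions
    sv <- svd(H)
    R0 <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    if (harmonicEnergy(base %*% t(R0), cw, landmarks, targetPositions,
                       gamma) <=
        harmonicEnergy(base, cw, landmarks, targetPositions, gamma))
      base <- base %*% t(R0)
  }
  up <- if (!is.null(landmarks)) {
    tc <- colMeans(targetPositions)
    if (sqrt(sum(tc^2)) < 1e-6) c(0, 0, 1) else tc / sqrt(sum(tc^2))
  } else c(0, 0, 1)
  R1 <- rotationBetween(up, c(0, 0, 1))
  baseR1 <- base %*% t(R1)
  fc <- (baseR1[f[, 1], ] + baseR1[f[, 2], ] + baseR1[f[, 3], ]) / 3
  fc <- fc / sqrt(rowSums(fc^2))
  # candidate outer faces in the southern cap; the pole goes to the chordal
  # incenter of the chosen face, preferring the face with the deepest
  # interior (largest margin), and the projection is verified: only the
  # outer face may invert in the plane
  cand <- order(fc[, 3])[seq_len(max(10, ceiling(nrow(f) * 0.02)))]
  incenterMargin <- function(k, pts) {
    a <- pts[f[k, 1], ]; b <- pts[f[k, 2], ]; c <- pts[f[k, 3], ]
    la <- sqrt(sum((b - c)^2)); lb <- sqrt(sum((a - c)^2))
    lc <- sqrt(sum((a - b)^2))
    p <- (la * a + lb * b + lc * c) / (la + lb + lc)
    p <- p / sqrt(sum(p^2))
    m <- min(det(rbind(a, b, p)), det(rbind(b, c, p)), det(rbind(c, a, p)))
    list(pole = p, margin = m)
  }
  ic <- lapply(cand, incenterMargin, pts = baseR1)
  ord <- cand[order(vapply(ic, function(x) x$margin, numeric(1)),
                    decreasing = TRUE)]
  poles <- ic[order(vapply(ic, function(x) x$margin, numeric(1)),
                    decreasing = TRUE)]
  outer <- NULL
  for (ci in seq_along(ord)) {
    k <- ord[ci]
    Rk <- rotationBetween(poles[[ci]]$pole, c(0, 0, -1)) %*% R1
    pk <- base %*% t(Rk)
    wk <- stereoFromSouth(pk)
    sgn <- Im(Conj(wk[f[, 2]] - wk[f[, 1]]) * (wk[f[, 3]] - wk[f[, 1]]))
    neg <- which(sgn <= 0)
    if (identical(neg, k)) {
      outer <- k; R <- Rk; baseR <- pk
      break
    }
    if (is.null(outer) && ci == length(ord)) {
      # accept the best candidate even with residual inversions; the
      # Beltrami correction pass will repair them
      outer <- ord[1]
      R <- rotationBetween(poles[[1]]$pole, c(0, 0, -1)) %*% R1
      baseR <- base %*% t(R)
    }
  }
  fixed <- as.integer(f[outer, ])
  targetsR <- if (!is.null(targetPositions)) targetPositions %*% t(R)

  energyOf <- function(pos)
    harmonicEnergy(pos, cw, landmarks, targetsR, gamma)

  lmFree <- if (!is.null(landmarks)) setdiff(landmarks, fixed) else integer(0)
  K0 <- lbsMatrix(mesh, complex(real = rep(0, nrow(f))), outer, flat)
  tC <- if (length(lmFree))
    stereoFromSouth(targetsR[match(lmFree, landmarks), , drop = FALSE])
  else complex(0)

  w <- stereoFromSouth(baseR)
  bestPos <- baseR; bestW <- w
  trace <- energyOf(baseR)

  tryStep <- function(wNew) {
    posNew <- stereoToSphere(wNew)
    posNew <- posNew / sqrt(rowSums(posNew^2))
    eNew <- energyOf(posNew)
    if (is.finite(eNew) && eNew <= trace[length(trace)] + 1e-12) {
      bestPos <<- posNew; bestW <<- wNew
      trace <<- c(trace, eNew)
      TRUE
    } else FALSE
  }

  if (length(lmFree) > 0) {
    # landmark-penalized harmonic solve in the plane, anchored on the base
    # map at the outer face
    wLm <- penalizedSolve(K0, w, fixed, lmFree, tC, gamma)
    tryStep(wLm)

    # opposite-pole re-solve of the high-distortion cap (near the outer face)
    wInv <- 1 / bestW
    r0 <- stats::quantile(Mod(wInv), 0.25)
    cap <- setdiff(which(Mod(wInv) < r0), fixed)
    if (length(cap) > 0) {
      fixedInv <- setdiff(seq_len(nrow(v)), cap)
      lmCap <- intersect(landmarks, cap)
      tCap <- if (length(lmCap))
        1 / stereoFromSouth(targetsR[match(lmCap, landmarks), , drop = FALSE])
      else complex(0)
      wInv2 <- penalizedSolve(K0, wInv, fixedInv, lmCap, tCap, gamma)
      tryStep(1 / wInv2)
    }
  }

  # Beltrami correction: truncate |mu| below one and rebuild by the linear
  # Beltrami solver until every face preserves orientation on the sphere
  # (planar images adjacent to the projection pole legitimately exceed
  # |mu| = 1 in the plane; only genuine spherical folds are repaired)
  for (it in seq_len(maxCorrections)) {
    if (all(sphereOrientation(mesh, bestPos) > 0)) break
    mu <- faceBeltrami(mesh, bestW, flat)
    amu <- Mod(mu)
    muT <- mu
    muT[amu >= 1 - eta] <- muT[amu >= 1 - eta] /
      amu[amu >= 1 - eta] * (1 - eta)
    K <- lbsMatrix(mesh, muT, outer, flat)
    wNew <- penalizedSolve(K, bestW, fixed, lmFree, tC, gamma)
    if (!tryStep(wNew)) {
      # accept an orientation repair even at an energy tie by blending
      if (!tryStep((bestW + wNew) / 2)) break
    }
  }
  flippedLeft <- sum(sphereOrientation(mesh, bestPos) <= 0)
  if (flippedLeft > 0)
    stop(flippedLeft, " faces remain orientation-reversing after Beltrami ",
         "correction; solver failed")
  bestPos <- bestPos %*% R  # back to the input frame
  mu <- chordalMu(mesh, bestPos, flat)
  new("SphericalMap", positions = bestPos, mesh = mesh, mu = mu,
      angleDistortion = cornerAngleDistortion(mesh, bestPos),
      outerFace = as.integer(outer), energyTrace = trace)
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotationBetween <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # opposite directions: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  VX <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3)
  diag(3) + VX + VX %*% VX / (1 + cth)
}

# locate unit vectors `pts` in the spherical triangulation of `map`;
# returns face index and barycentric weights (rows), counting fallbacks
locateOnSphere <- function(map, pts, tol = 1e-12) {
  f <- map@mesh@faces
  P <- map@positions
  ctr <- (P[f[, 1], ] + P[f[, 2], ] + P[f[, 3], ]) / 3
  ctr <- ctr / sqrt(rowSums(ctr^2))
  score <- pts %*% t(ctr)   # n x F
  n <- nrow(pts)
  faceIdx <- integer(n)
  bary <- matrix(0, n, 3)
  fallback <- 0L
  for (i in seq_len(n)) {
    ord <- order(score[i, ], decreasing = TRUE)
    found <- FALSE
    for (k in ord[seq_len(min(64, length(ord)))]) {
      a <- P[f[k, 1], ]; b <- P[f[k, 2], ]; c <- P[f[k, 3], ]
      x <- pts[i, ]
      d1 <- det(rbind(a, b, x)); d2 <- det(rbind(b, c, x))
      d3 <- det(rbind(c, a, x))
      if (d1 >= -tol && d2 >= -tol && d3 >= -tol) {
        M <- rbind(a, b, c)
        wts <- tryCatch(solve(t(M), x), error = function(e) NULL)
        if (!is.null(wts)) {
          wts <- pmax(wts, 0)
          s <- sum(wts)
          if (s > 0) {
            faceIdx[i] <- k; bary[i, ] <- wts / s; found <- TRUE
            break
          }
        }
      }
    }
    if (!found) {
      fallback <- fallback + 1L
      k <- ord[1]
      M <- rbind(P[f[k, 1], ], P[f[k, 2], ], P[f[k, 3], ])
      wts <- tryCatch(pmax(solve(t(M), pts[i, ]), 0),
                      error = function(e) c(1, 1, 1) / 3)
      s <- sum(wts); if (s == 0) { wts <- c(1, 1, 1) / 3; s <- 1 }
      faceIdx[i] <- k; bary[i, ] <- wts / s
    }
  }
  if (fallback / n > 0.001)
    stop("point location failed for ", fallback, " of ", n,
         " points (> 0.1 %)")
  if (fallback > 0)
    warning(fallback, " point(s) located by nearest-triangle fallback")
  list(face = faceIdx, bary = bary)
}

#' Compose the registration g = f2^-1 o f1
#'
#' For every vertex of the source mesh, its spherical image under `map1` is
#' located in the spherical triangulation of `map2` and pulled back
#' barycentrically onto the target surface.
#'
#' @param map1,map2 [SphericalMap-class] of source and target.
#' @return V1-by-3 matrix of corresponding points on the target surface
#'   (mm).
#' @export
composeRegistration <- function(map1, map2) {
  loc <- locateOnSphere(map2, map1@positions)
  f <- map2@mesh@faces; v <- map2@mesh@vertices
  loc$bary[, 1] * v[f[loc$face, 1], , drop = FALSE] +
    loc$bary[, 2] * v[f[loc$face, 2], , drop = FALSE] +
    loc$bary[, 3] * v[f[loc$face, 3], , drop = FALSE]
}

# map 3D points lying on a mesh surface to their spherical images
surfaceToSphere <- function(points, map) {
  mesh <- map@mesh
  f <- mesh@faces; v <- mesh@vertices
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  n <- nrow(points)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- points[i, ]
    d2 <- rowSums(sweep(ctr, 2, p)^2)
    best <- NULL; bestDist <- Inf
    for (k in order(d2)[seq_len(min(32, nrow(f)))]) {
      a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c <- v[f[k, 3], ]
      # barycentric via least squares on the triangle plane
      M <- cbind(b - a, c - a)
      rhs <- p - a
      uv <- tryCatch(solve(crossprod(M), crossprod(M, rhs)),
                     error = function(e) NULL)
      if (is.null(uv)) next
      u <- uv[1]; w <- uv[2]
      u <- max(0, min(1, u)); w <- max(0, min(1 - u, w))
      q <- a + u * (b - a) + w * (c - a)
      dd <- sum((q - p)^2)
      if (dd < bestDist) {
        bestDist <- dd
        best <- list(face = k, bary = c(1 - u - w, u, w))
      }
    }
    sp <- best$bary[1] * map@positions[f[best$face, 1], ] +
      best$bary[2] * map@positions[f[best$face, 2], ] +
      best$bary[3] * map@positions[f[best$face, 3], ]
    out[i, ] <- sp / sqrt(sum(sp^2))
  }
  out
}

#' Transfer a resection path between registered surfaces
#'
#' Each point of a path on the target surface is mapped through `map2` to
#' the sphere, located in `map1`'s spherical triangulation, and pulled back
#' barycentrically onto the source surface.
#'
#' @param path a [ResectionPath-class] on the target mesh of `map2`.
#' @param map1 source [SphericalMap-class].
#' @param map2 target [SphericalMap-class].
#' @return a [ResectionPath-class] on the source mesh, same label and point
#'   count.
#' @export
transferResection <- function(path, map1, map2) {
  sph <- surfaceToSphere(path@points, map2)
  loc <- locateOnSphere(map1, sph)
  f <- map1@mesh@faces; v <- map1@mesh@vertices
  pts <- loc$bary[, 1] * v[f[loc$face, 1], , drop = FALSE] +
    loc$bary[, 2] * v[f[loc$face, 2], , drop = FALSE] +
    loc$bary[, 3] * v[f[loc$face, 3], , drop = FALSE]
  resectionPath(pts, path@label)
}

pointToSegments <- function(p, segA, segB) {
  d <- segB - segA
  ap <- sweep(-segA, 2, p, `+`)
  t <- rowSums(ap * d) / pmax(rowSums(d * d), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  q <- segA + t * d
  min(sqrt(rowSums((q - rep(p, each = nrow(q)))^2)))
}

#' Symmetric Hausdorff statistics between two polylines
#'
#' Point-to-polyline distances are evaluated from each polyline's vertices
#' to the other polyline's segments; max, min, mean and RMS are taken over
#' the pooled distance set. Single-point "polylines" are treated as points.
#'
#' @param pathA,pathB n-by-3 point matrices (or [ResectionPath-class]).
#' @return named vector `c(max, min, mean, rms)` in mm.
#' @export
hausdorffStats <- function(pathA, pathB) {
  A <- if (is(pathA, "ResectionPath")) pathA@points else as.matrix(pathA)
  B <- if (is(pathB, "ResectionPath")) pathB@points else as.matrix(pathB)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty path")
  segs <- function(M) if (nrow(M) >= 2)
    list(a = M[-nrow(M), , drop = FALSE], b = M[-1, , drop = FALSE])
  else list(a = M, b = M)
  sB <- segs(B); sA <- segs(A)
  dA <- vapply(seq_len(nrow(A)), function(i)
    pointToSegments(A[i, ], sB$a, sB$b), numeric(1))
  dB <- vapply(seq_len(nrow(B)), function(i)
    pointToSegments(B[i, ], sA$a, sA$b), numeric(1))
  d <- c(dA, dB)
  c(max = max(d), min = min(d), mean = mean(d), rms = sqrt(mean(d^2)))
}
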