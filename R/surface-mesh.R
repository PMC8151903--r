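# Surface reconstruction and mesh conditioning.
#
# Isosurfacing uses marching tetrahedra on the Kuhn 6-tetrahedra cube
# subdivision (consistent across neighbouring cubes), with linear
# interpolation along cut edges. Binary masks are first smoothed by a 3x3x3
# box mean so the 0.5-level set sits close to the voxel boundary with low
# staircase bias; if the smoothed field drops everything below the level
# (tiny masks), the raw binary field is used instead.

cubeCorners <- matrix(c(
  0,0,0, 1,0,0, 0,1,0, 1,1,0,
  0,0,1, 1,0,1, 0,1,1, 1,1,1), ncol = 3, byrow = TRUE)

# Kuhn subdivision: six tetrahedra sharing the main diagonal 1-8
kuhnTets <- matrix(c(
  1,2,4,8,  1,4,3,8,  1,3,7,8,  1,7,5,8,  1,5,6,8,  1,2,6,8), ncol = 4,
  byrow = TRUE)

# build the 16-case triangle table for one tetrahedron (corner positions P);
# each triangle is a triple of cut edges, each edge (insideCorner,
# outsideCorner); orientation chosen so normals point toward the outside.
tetCaseTable <- function(P) {
  cases <- vector("list", 16)
  for (mask in 1:14) {
    inside <- which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0)
    outside <- setdiff(1:4, inside)
    edges <- as.matrix(expand.grid(a = inside, b = outside))
    mid <- (P[edges[, 1], , drop = FALSE] + P[edges[, 2], , drop = FALSE]) / 2
    ctr <- colMeans(mid)
    # cyclic order of the cut polygon: sort by angle in its plane
    if (nrow(mid) > 3) {
      n0 <- colMeans(P[outside, , drop = FALSE]) -
        colMeans(P[inside, , drop = FALSE])
      e1 <- mid[1, ] - ctr; e1 <- e1 - sum(e1 * n0) * n0 / sum(n0^2)
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(n0[2] * e1[3] - n0[3] * e1[2], n0[3] * e1[1] - n0[1] * e1[3],
              n0[1] * e1[2] - n0[2] * e1[1])
      e2 <- e2 / sqrt(sum(e2^2))
      ang <- atan2((mid - rep(ctr, each = nrow(mid))) %*% e2,
                   (mid - rep(ctr, each = nrow(mid))) %*% e1)
      ord <- order(ang)
      edges <- edges[ord, , drop = FALSE]
      mid <- mid[ord, , drop = FALSE]
    }
    tris <- if (nrow(edges) == 3) list(1:3) else list(c(1, 2, 3), c(1, 3, 4))
    dirOut <- colMeans(P[outside, , drop = FALSE]) -
      colMeans(P[inside, , drop = FALSE])
    out <- list()
    for (tr in tris) {
      v1 <- mid[tr[1], ]; v2 <- mid[tr[2], ]; v3 <- mid[tr[3], ]
      nrm <- c((v2 - v1)[2] * (v3 - v1)[3] - (v2 - v1)[3] * (v3 - v1)[2],
               (v2 - v1)[3] * (v3 - v1)[1] - (v2 - v1)[1] * (v3 - v1)[3],
               (v2 - v1)[1] * (v3 - v1)[2] - (v2 - v1)[2] * (v3 - v1)[1])
      if (sum(nrm * dirOut) < 0) tr <- rev(tr)
      out[[length(out) + 1]] <- edges[tr, , drop = FALSE]
    }
    cases[[mask + 1]] <- out
  }
  cases
}

box3Smooth <- function(arr) {
  d <- dim(arr)
  pad <- array(0, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  out <- array(0, d + 2)
  for (ds in -1:1) for (dr in -1:1) for (dc in -1:1)
    out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
      out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] +
      pad[2:(d[1] + 1) + ds, 2:(d[2] + 1) + dr, 2:(d[3] + 1) + dc]
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] / 27
}

#' Reconstruct a triangulated surface from a label volume
#'
#' Closed 0.5-isosurface between the label classes, in physical mm
#' coordinates (x = col spacing, y = row spacing, z = slice distance).
#'
#' @param labels a [LabelVolume-class] with a non-empty mask.
#' @param presmooth smooth the binary mask with a 3x3x3 box mean before
#'   isosurfacing (default TRUE; automatically disabled when it would erase
#'   the mask).
#' @return a [TriangleMesh-class], watertight and consistently oriented.
#' @export
reconstructSurface <- function(labels, presmooth = TRUE) {
  mask <- labels@labels
  if (sum(mask) == 0) stop("empty mask: no surface to reconstruct")
  field <- if (presmooth) box3Smooth(mask) else mask * 1.0
  if (presmooth && max(field) <= 0.5) field <- mask * 1.0
  d <- dim(field)
  # pad with background so the surface closes at the borders
  pf <- array(0, d + 2)
  pf[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  mt <- marchingTetrahedra(pf, 0.5)
  # grid index -> physical mm: padded index i corresponds to voxel i-1
  sp <- c(labels@sliceDistance, labels@pixelSpacing[2], labels@pixelSpacing[1])
  verts <- cbind(labels@origin[1] + (mt$vertices[, 3] - 2) * labels@pixelSpacing[1],
                 labels@origin[2] + (mt$vertices[, 2] - 2) * labels@pixelSpacing[2],
                 labels@origin[3] + (mt$vertices[, 1] - 2) * labels@sliceDistance)
  # the (slice,row,col) -> (x,y,z) axis permutation is orientation-reversing
  out <- triangleMesh(verts, mt$faces[, c(1, 3, 2)])
  if (meshVolume(out) < 0) out@faces <- out@faces[, c(1, 3, 2)]
  out
}

# field: 3D array (s, r, c); returns vertices in (s, r, c) grid coordinates
marchingTetrahedra <- function(field, iso) {
  d <- dim(field)
  nS <- d[1] - 1; nR <- d[2] - 1; nC <- d[3] - 1
  # grid point linear id (1-based): s + (r-1) d1 + (c-1) d1 d2
  baseS <- seq_len(nS); baseR <- seq_len(nR); baseC <- seq_len(nC)
  lin <- function(s, r, c) s + (r - 1) * d[1] + (c - 1) * d[1] * d[2]
  base <- as.vector(outer(outer(lin(baseS, 1, 1) - lin(1, 1, 1) + 1,
                                (baseR - 1) * d[1], `+`),
                          (baseC - 1) * d[1] * d[2], `+`))
  cornerOff <- cubeCorners[, 1] + cubeCorners[, 2] * d[1] +
    cubeCorners[, 3] * d[1] * d[2]  # corner order: (ds, dr, dc) = cubeCorners
  fv <- as.vector(field)
  cornerIds <- lapply(1:8, function(i) base + cornerOff[i])
  cornerVals <- lapply(cornerIds, function(id) fv[id])
  # per tet type, tables on the tet's corner positions in (s, r, c);
  # each triangle contributes a row of three (inside, outside) grid edges
  listA <- list(); listB <- list()
  for (tt in seq_len(nrow(kuhnTets))) {
    corn <- kuhnTets[tt, ]
    P <- cubeCorners[corn, ]
    tbl <- tetCaseTable(P)
    v <- cornerVals[corn]
    ins <- lapply(v, function(x) x > iso)
    case <- ins[[1]] + 2L * ins[[2]] + 4L * ins[[3]] + 8L * ins[[4]]
    for (cs in 1:14) {
      sel <- which(case == cs)
      if (!length(sel)) next
      for (tr in tbl[[cs + 1]]) {
        listA[[length(listA) + 1]] <-
          cbind(cornerIds[[corn[tr[1, 1]]]][sel],
                cornerIds[[corn[tr[2, 1]]]][sel],
                cornerIds[[corn[tr[3, 1]]]][sel])
        listB[[length(listB) + 1]] <-
          cbind(cornerIds[[corn[tr[1, 2]]]][sel],
                cornerIds[[corn[tr[2, 2]]]][sel],
                cornerIds[[corn[tr[3, 2]]]][sel])
      }
    }
  }
  if (!length(listA)) stop("no isosurface crossings found")
  Amat <- do.call(rbind, listA); Bmat <- do.call(rbind, listB)
  edgeA <- as.vector(t(Amat)); edgeB <- as.vector(t(Bmat))
  # interpolated vertex per unique undirected grid edge
  lo <- pmin(edgeA, edgeB); hi <- pmax(edgeA, edgeB)
  key <- lo * (prod(d) + 1) + hi
  uk <- unique(key)
  vid <- match(key, uk)
  first <- match(uk, key)
  a0 <- edgeA[first]; b0 <- edgeB[first]
  t <- (iso - fv[a0]) / (fv[b0] - fv[a0])
  toSRC <- function(id) {
    id0 <- id - 1L
    cbind(id0 %% d[1] + 1L, (id0 %/% d[1]) %% d[2] + 1L,
          id0 %/% (d[1] * d[2]) + 1L)
  }
  Pa <- toSRC(a0); Pb <- toSRC(b0)
  verts <- Pa + t * (Pb - Pa)
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  # drop degenerate faces (can appear if t hits 0/1 exactly)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

## ---- mesh utilities ----

#' Undirected edge list of a mesh
#' @param mesh a [TriangleMesh-class].
#' @return E-by-2 matrix, each edge once, first column smaller index.
#' @export
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic V - E + F
#' @param mesh a [TriangleMesh-class].
#' @export
eulerCharacteristic <- function(mesh) {
  nrow(mesh@vertices) - nrow(meshEdges(mesh)) + nrow(mesh@faces)
}

edgeUseCounts <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is the mesh watertight (every edge shared by exactly two faces)?
#' @param mesh a [TriangleMesh-class].
#' @export
isWatertight <- function(mesh) {
  all(edgeUseCounts(mesh) == 2)
}

#' Total surface area (mm^2)
#' @param mesh a [TriangleMesh-class].
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2], ] - v[f[, 1], ]; b <- v[f[, 3], ] - v[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed enclosed volume (mm^3); positive for outward orientation
#' @param mesh a [TriangleMesh-class].
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  p1 <- v[f[, 1], ]; p2 <- v[f[, 2], ]; p3 <- v[f[, 3], ]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Area-weighted outward vertex normals
#' @param mesh a [TriangleMesh-class].
#' @return V-by-3 matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2], ] - v[f[, 1], ]; b <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) for (k in 1:3) {
    tp <- tapply(fn[, k], f[, j], sum)[as.character(seq_len(nrow(v)))]
    tp[is.na(tp)] <- 0
    n[, k] <- n[, k] + unname(tp)
  }
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

meshComponents <- function(mesh) {
  e <- meshEdges(mesh)
  g <- igraph::make_graph(t(e), n = nrow(mesh@vertices), directed = FALSE)
  igraph::components(g)$membership
}

removeUnusedVertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh@faces)))
  map <- integer(nrow(mesh@vertices)); map[used] <- seq_along(used)
  triangleMesh(mesh@vertices[used, , drop = FALSE],
               matrix(map[mesh@faces], ncol = 3))
}

dropBadFaces <- function(mesh) {
  f <- mesh@faces
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  key <- apply(f, 1, function(r) paste(sort(r), collapse = ","))
  f <- f[!duplicated(key), , drop = FALSE]
  triangleMesh(mesh@vertices, f)
}

fillHoles <- function(mesh) {
  cnt <- edgeUseCounts(mesh)
  if (all(cnt == 2)) return(mesh)
  # boundary edges appear in exactly one face; fan-triangulate each loop
  f <- mesh@faces
  de <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  bnd <- de[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  newF <- list()
  while (nrow(bnd) > 0) {
    loop <- bnd[1, ]
    bnd <- bnd[-1, , drop = FALSE]
    while (loop[length(loop)] != loop[1] || length(loop) < 3) {
      nxt <- which(bnd[, 1] == loop[length(loop)])[1]
      if (is.na(nxt)) break
      loop <- c(loop, bnd[nxt, 2])
      bnd <- bnd[-nxt, , drop = FALSE]
    }
    loop <- loop[-length(loop)]
    if (length(loop) >= 3) {
      # boundary is traversed in face direction; the hole patch must run
      # opposite to stitch consistently
      loop <- rev(loop)
      for (i in 2:(length(loop) - 1))
        newF[[length(newF) + 1]] <- c(loop[1], loop[i], loop[i + 1])
    }
  }
  if (length(newF))
    mesh@faces <- rbind(mesh@faces,
                        matrix(as.integer(unlist(newF)), ncol = 3, byrow = TRUE))
  mesh
}

#' Laplacian (Taubin) smoothing
#'
#' Alternating shrink/expand passes that smooth without systematic volume
#' loss.
#'
#' @param mesh a [TriangleMesh-class].
#' @param iterations number of lambda/mu pairs.
#' @param lambda,mu Taubin factors.
#' @export
taubinSmooth <- function(mesh, iterations = 2, lambda = 0.5, mu = -0.53) {
  v <- mesh@vertices
  e <- meshEdges(mesh)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nrow(v), nrow(v)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    for (fac in c(lambda, mu)) {
      avg <- as.matrix(A %*% v) / deg
      v <- v + fac * (avg - v)
    }
  }
  triangleMesh(v, mesh@faces)
}

midpointSubdivide <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e <- meshEdges(mesh)
  key <- e[, 1] * (nrow(v) + 1) + e[, 2]
  mid <- (v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE]) / 2
  midId <- nrow(v) + seq_len(nrow(e))
  lookup <- function(a, b) {
    k <- pmin(a, b) * (nrow(v) + 1) + pmax(a, b)
    midId[match(k, key)]
  }
  m12 <- lookup(f[, 1], f[, 2]); m23 <- lookup(f[, 2], f[, 3])
  m31 <- lookup(f[, 3], f[, 1])
  nf <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  triangleMesh(rbind(v, mid), nf)
}

# batched shortest-edge collapse to an exact vertex count
decimateTo <- function(mesh, target, maxPasses = 200) {
  for (pass in seq_len(maxPasses)) {
    V <- nrow(mesh@vertices)
    need <- V - target
    if (need <= 0) break
    v <- mesh@vertices; f <- mesh@faces
    e <- meshEdges(mesh)
    A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(V, V))
    CN <- A %*% A
    cn <- CN[e]
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                           v[e[, 2], , drop = FALSE])^2))
    ord <- order(len)
    used <- logical(V)
    selected <- integer(0)
    for (i in ord) {
      if (cn[i] != 2) next
      u1 <- e[i, 1]; u2 <- e[i, 2]
      if (used[u1] || used[u2]) next
      used[c(u1, u2)] <- TRUE
      selected <- c(selected, i)
      if (length(selected) >= need) break
    }
    if (!length(selected)) stop("decimation stalled before reaching target")
    map <- seq_len(V)
    map[e[selected, 2]] <- e[selected, 1]
    v[e[selected, 1], ] <- (v[e[selected, 1], , drop = FALSE] +
                              v[e[selected, 2], , drop = FALSE]) / 2
    mesh <- removeUnusedVertices(dropBadFaces(triangleMesh(v, matrix(
      map[f], ncol = 3))))
  }
  mesh
}

#' Clean and resample a mesh to a target resolution
#'
#' Removes degenerate and duplicate faces, optionally keeps the largest
#' component, fills holes, applies light Taubin smoothing, and remeshes
#' (midpoint subdivision and/or batched shortest-edge collapse with the
#' manifold link condition) to `targetVertices` within 2 %. The result must
#' be watertight genus-0, otherwise an error is raised.
#'
#' @param mesh a [TriangleMesh-class].
#' @param targetVertices target vertex count (default 12000).
#' @param keepLargest keep only the largest connected component instead of
#'   erroring on multi-component input.
#' @param smoothIterations Taubin smoothing pairs (default 2; 0 disables).
#' @return a [TriangleMesh-class] with `V` within 2 % of the target.
#' @export
cleanAndResample <- function(mesh, targetVertices = 12000,
                             keepLargest = FALSE, smoothIterations = 2) {
  mesh <- dropBadFaces(mesh)
  comp <- meshComponents(mesh)
  if (max(comp) > 1) {
    sizes <- sort(tabulate(comp), decreasing = TRUE)
    if (!keepLargest)
      stop("mesh has ", max(comp), " connected components (sizes ",
           paste(sizes, collapse = ", "),
           "); set keepLargest = TRUE to keep the largest")
    keep <- which.max(tabulate(comp))
    fkeep <- comp[mesh@faces[, 1]] == keep
    mesh <- removeUnusedVertices(triangleMesh(mesh@vertices,
                                              mesh@faces[fkeep, , drop = FALSE]))
  }
  mesh <- fillHoles(mesh)
  if (smoothIterations > 0) mesh <- taubinSmooth(mesh, smoothIterations)
  V <- nrow(mesh@vertices)
  if (abs(V - targetVertices) / targetVertices > 0.02) {
    while (nrow(mesh@vertices) < targetVertices)
      mesh <- midpointSubdivide(mesh)
    if (nrow(mesh@vertices) > targetVertices)
      mesh <- decimateTo(mesh, targetVertices)
  }
  if (!isWatertight(mesh))
    stop("cleaned mesh is not watertight")
  chi <- eulerCharacteristic(mesh)
  if (chi != 2)
    stop("mesh is not genus-0 after cleaning (Euler characteristic ", chi, ")")
  if (meshVolume(mesh) < 0)  # enforce outward orientation
    mesh@faces <- mesh@faces[, c(1, 3, 2)]
  mesh
}
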