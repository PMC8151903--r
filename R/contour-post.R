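# Per-slice contour extraction and the two anatomical constraints:
# bottleneck decomposition (chord / shorter-arc ratio with an outer-angle
# candidate filter) and the interslice overlap constraint
# T_s = 0.8 - 0.05 (D - 1).
#
# Polygons are n x 2 matrices of (row, col) pixel-centre coordinates, closed
# implicitly (last vertex connects to first) and oriented counter-clockwise
# in the (x = col, y = row) plane so the interior lies to the left.

polygonSignedArea <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

ensureCcw <- function(poly) {
  if (nrow(poly) >= 3 && polygonSignedArea(poly) < 0)
    poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

polygonPerimeter <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - poly)^2)))
}

#' Rasterize a closed polygon onto the pixel grid
#'
#' Even-odd scanline fill over pixel centres, with all boundary pixels along
#' the edges included; exact for pixel-aligned fixtures.
#'
#' @param poly n-by-2 (row, col) polygon.
#' @param nrow,ncol grid size.
#' @return logical matrix.
#' @export
rasterizePolygon <- function(poly, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  n <- base::nrow(poly)
  if (n == 0) return(mask)
  y1 <- poly[, 1]; x1 <- poly[, 2]
  y2 <- c(y1[-1], y1[1]); x2 <- c(x1[-1], x1[1])
  if (n >= 3) {
    ne <- y1 != y2
    for (rr in seq_len(nrow)) {
      hit <- ne & (pmin(y1, y2) <= rr) & (rr < pmax(y1, y2))
      if (!any(hit)) next
      xc <- sort(x1[hit] + (rr - y1[hit]) * (x2[hit] - x1[hit]) /
                   (y2[hit] - y1[hit]))
      for (k in seq_len(length(xc) %/% 2)) {
        a <- ceiling(xc[2 * k - 1] - 1e-9); b <- floor(xc[2 * k] + 1e-9)
        if (b >= a) mask[rr, max(a, 1):min(b, ncol)] <- TRUE
      }
    }
  }
  # boundary pixels
  for (i in seq_len(n)) {
    len <- max(abs(x2[i] - x1[i]), abs(y2[i] - y1[i]), 1)
    t <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
    rr <- pmin(pmax(round(y1[i] + t * (y2[i] - y1[i])), 1), nrow)
    cc <- pmin(pmax(round(x1[i] + t * (x2[i] - x1[i])), 1), ncol)
    mask[cbind(rr, cc)] <- TRUE
  }
  mask
}

#' Extract closed contours from every axial slice
#'
#' Binary label volumes are traced directly; probability volumes are first
#' binarized by a single volume-wide Otsu threshold. Each connected in-plane
#' component yields one counter-clockwise boundary polygon; cached areas are
#' the component pixel counts.
#'
#' @param labels a [LabelVolume-class] or [ProbabilityVolume-class].
#' @return a [SliceContourSet-class].
#' @export
extractSliceContours <- function(labels) {
  if (is(labels, "ProbabilityVolume")) {
    vals <- as.vector(labels@values)
    thr <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)),
                         range = c(0, 1))
    arr <- array(as.integer(labels@values > thr), dim(labels))
  } else arr <- labels@labels
  d <- dim(arr)
  contours <- vector("list", d[1]); areas <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    m <- arr[s, , ]
    if (!any(m == 1L)) {
      contours[[s]] <- list(); areas[[s]] <- numeric(0)
      next
    }
    lab <- EBImage::bwlabel(m)
    oc <- EBImage::ocontour(lab)
    polys <- lapply(oc, function(p)
      ensureCcw(cbind(row = p[, 1] + 1, col = p[, 2] + 1)))
    contours[[s]] <- polys
    areas[[s]] <- as.numeric(tabulate(lab[lab > 0]))[seq_along(polys)]
  }
  new("SliceContourSet", contours = contours, areas = areas,
      dim = as.integer(d), pixelSpacing = labels@pixelSpacing,
      sliceDistance = labels@sliceDistance, origin = labels@origin)
}

dpSimplify <- function(pts, tol) {
  # open-chain Douglas-Peucker; returns indices to keep
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- rep(FALSE, n); keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; L2 <- sum(ab^2)
    idx <- (i + 1):(j - 1)
    dp <- sweep(pts[idx, , drop = FALSE], 2, a)
    if (L2 == 0) {
      dist <- sqrt(rowSums(dp^2))
    } else {
      cross <- abs(dp[, 1] * ab[2] - dp[, 2] * ab[1])
      dist <- cross / sqrt(L2)
    }
    mx <- which.max(dist)
    if (dist[mx] > tol) {
      k <- idx[mx]; keep[k] <- TRUE
      stack[[length(stack) + 1]] <- c(i, k)
      stack[[length(stack) + 1]] <- c(k, j)
    }
  }
  which(keep)
}

#' Simplify a closed polygon (Douglas-Peucker)
#'
#' Splits the closed ring at the vertex farthest from vertex 1 and simplifies
#' both chains within the tolerance; `tolerance = 0` removes nothing and
#' returns the polygon unchanged.
#'
#' @param poly n-by-2 (row, col) closed polygon.
#' @param tolerance maximum allowed deviation in pixels, >= 0.
#' @export
approximatePolygon <- function(poly, tolerance) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  n <- nrow(poly)
  if (tolerance == 0 || n <= 4) return(poly)
  d1 <- rowSums(sweep(poly, 2, poly[1, ])^2)
  far <- which.max(d1)
  idx1 <- 1:far; idx2 <- c(far:n, 1)
  k1 <- idx1[dpSimplify(poly[idx1, , drop = FALSE], tolerance)]
  k2 <- idx2[dpSimplify(poly[idx2, , drop = FALSE], tolerance)]
  keep <- sort(unique(c(k1, k2)))
  poly[keep[keep <= n], , drop = FALSE]
}

#' Outer angle at a polygon vertex
#'
#' The angle at the vertex measured through the exterior of the region:
#' 360 degrees minus the interior angle. For a counter-clockwise polygon a
#' convex right-angle corner gives 270, a collinear vertex 180, and a reflex
#' notch with interior 270 gives 90.
#'
#' @param poly n-by-2 (row, col) CCW polygon.
#' @param i vertex index.
#' @return angle in degrees, in (0, 360).
#' @export
outerAngle <- function(poly, i) {
  n <- nrow(poly)
  p <- poly[if (i == 1) n else i - 1, ]
  v <- poly[i, ]
  q <- poly[if (i == n) 1 else i + 1, ]
  u1 <- c(v[2] - p[2], v[1] - p[1])  # incoming, (x, y)
  u2 <- c(q[2] - v[2], q[1] - v[1])  # outgoing
  if (all(u1 == 0) || all(u2 == 0))
    stop("duplicate consecutive vertices at index ", i)
  turn <- atan2(u1[1] * u2[2] - u1[2] * u2[1], sum(u1 * u2)) * 180 / pi
  unname(180 + turn)
}

outerAngles <- function(poly) {
  vapply(seq_len(nrow(poly)), function(i) outerAngle(poly, i), numeric(1))
}

#' Detect bottlenecks on a closed contour
#'
#' A bottleneck is a vertex pair whose chord is short relative to the shorter
#' boundary arc between them: `epsilon = chord / min(arc_cw, arc_ccw) < Tb`.
#' Vertices whose outer angle is below `Tc` are discarded from the candidate
#' set first, and only pairs separated by more than `minSeparation` (measured
#' along the shorter arc by default, or by chord) are considered.
#'
#' @param poly simplified CCW closed polygon (n-by-2, row/col).
#' @param Tb bottleneck ratio threshold (default 0.6).
#' @param Tc outer-angle threshold in degrees (default 135).
#' @param minSeparation minimum pair separation in pixels (default 60).
#' @param separationMetric "arc" (default) or "chord".
#' @return data frame with columns `i`, `j`, `epsilon`, sorted by ascending
#'   `epsilon` (zero rows when nothing detected).
#' @export
detectBottlenecks <- function(poly, Tb = 0.6, Tc = 135, minSeparation = 60,
                              separationMetric = c("arc", "chord")) {
  separationMetric <- match.arg(separationMetric)
  empty <- data.frame(i = integer(0), j = integer(0), epsilon = numeric(0))
  n <- nrow(poly)
  if (n < 4) return(empty)
  ang <- outerAngles(poly)
  cand <- which(ang >= Tc)
  if (length(cand) < 2) return(empty)
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  edgeLen <- sqrt(rowSums((nxt - poly)^2))
  total <- sum(edgeLen)
  cum <- c(0, cumsum(edgeLen))  # cum[i] = arc length from vertex 1 to vertex i
  pr <- t(combn(cand, 2))
  a1 <- abs(cum[pr[, 2]] - cum[pr[, 1]])
  arcMin <- pmin(a1, total - a1)
  chord <- sqrt(rowSums((poly[pr[, 1], , drop = FALSE] -
                           poly[pr[, 2], , drop = FALSE])^2))
  sep <- if (separationMetric == "arc") arcMin else chord
  eps <- chord / arcMin
  ok <- sep > minSeparation & eps < Tb & arcMin > 0
  out <- data.frame(i = pr[ok, 1], j = pr[ok, 2], epsilon = eps[ok])
  out[order(out$epsilon), , drop = FALSE]
}

segmentsIntersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

#' Split a contour along a detected bottleneck chord
#'
#' Cuts the polygon along the chord `p_i p_j` into two closed polygons. By
#' default both are returned (the interslice filter decides survival);
#' `keep = "larger"` returns only the larger-area piece.
#'
#' @param poly CCW closed polygon.
#' @param pair integer(2) vertex indices (or one row of
#'   [detectBottlenecks()] output).
#' @param keep "both" or "larger".
#' @return list of polygons (length 2 or 1).
#' @export
removeBottleneck <- function(poly, pair, keep = c("both", "larger")) {
  keep <- match.arg(keep)
  i <- as.integer(pair[[1]]); j <- as.integer(pair[[2]])
  if (i > j) { t <- i; i <- j; j <- t }
  n <- nrow(poly)
  if (j - i < 2 || (n - (j - i)) < 2)
    stop("degenerate bottleneck pair (adjacent vertices)")
  # the chord must not cross the boundary elsewhere
  a <- poly[i, c(2, 1)]; b <- poly[j, c(2, 1)]
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (any(c(k, k2) %in% c(i, j))) next
    if (segmentsIntersect(a, b, poly[k, c(2, 1)], poly[k2, c(2, 1)]))
      stop("bottleneck chord crosses the boundary: non-simple split")
  }
  c1 <- poly[i:j, , drop = FALSE]
  c2 <- poly[c(j:n, 1:i), , drop = FALSE]
  pieces <- list(ensureCcw(c1), ensureCcw(c2))
  if (keep == "both") return(pieces)
  areas <- vapply(pieces, function(p) abs(polygonSignedArea(p)), numeric(1))
  pieces[which.max(areas)]
}

#' Interslice overlap constraint
#'
#' With `T_s = 0.8 - 0.05 (D - 1)`, traversal starts at the slice with the
#' largest total contour area and proceeds ascending, then descending. A
#' contour survives only if its rasterized overlap with some kept contour of
#' the previously accepted slice exceeds `T_s` of the smaller of the two
#' areas.
#'
#' @param contourSet a [SliceContourSet-class].
#' @param D slice distance in mm (defaults to the set's).
#' @return the filtered [SliceContourSet-class].
#' @export
intersliceFilter <- function(contourSet, D = contourSet@sliceDistance) {
  Ts <- 0.8 - 0.05 * (D - 1)
  d <- contourSet@dim
  nS <- d[1]
  total <- vapply(contourSet@areas, function(a) sum(a), numeric(1))
  if (all(total == 0)) return(contourSet)
  start <- which.max(total)
  masks <- lapply(seq_len(nS), function(s)
    lapply(contourSet@contours[[s]], rasterizePolygon, nrow = d[2],
           ncol = d[3]))
  keptC <- vector("list", nS); keptA <- vector("list", nS)
  keptM <- vector("list", nS)
  keptC[[start]] <- contourSet@contours[[start]]
  keptA[[start]] <- vapply(masks[[start]], sum, numeric(1))
  keptM[[start]] <- masks[[start]]
  sweepDir <- function(idx) {
    prev <- start
    for (s in idx) {
      keepI <- logical(length(masks[[s]]))
      for (ci in seq_along(masks[[s]])) {
        mi <- masks[[s]][[ci]]; ai <- sum(mi)
        for (cj in seq_along(keptM[[prev]])) {
          aj <- keptA[[prev]][cj]
          inter <- sum(mi & keptM[[prev]][[cj]])
          if (inter / min(ai, aj) > Ts) { keepI[ci] <- TRUE; break }
        }
      }
      keptC[[s]] <<- contourSet@contours[[s]][keepI]
      keptM[[s]] <<- masks[[s]][keepI]
      keptA[[s]] <<- vapply(keptM[[s]], sum, numeric(1))
      if (length(keptM[[s]]) > 0) prev <- s
    }
  }
  if (start < nS) sweepDir((start + 1):nS)
  if (start > 1) sweepDir((start - 1):1)
  new("SliceContourSet", contours = keptC,
      areas = keptA, dim = contourSet@dim,
      pixelSpacing = contourSet@pixelSpacing,
      sliceDistance = contourSet@sliceDistance, origin = contourSet@origin)
}

#' Rasterize a contour set back to a label volume
#'
#' @param contourSet a [SliceContourSet-class].
#' @return a [LabelVolume-class].
#' @export
contoursToLabels <- function(contourSet) {
  d <- contourSet@dim
  arr <- array(0L, d)
  for (s in seq_len(d[1]))
    for (p in contourSet@contours[[s]])
      arr[s, , ][rasterizePolygon(p, d[2], d[3])] <- 1L
  labelVolume(arr, pixelSpacing = contourSet@pixelSpacing,
              sliceDistance = contourSet@sliceDistance,
              origin = contourSet@origin)
}

# after detecting a pair on the simplified polygon, move each endpoint to
# the nearby original vertex minimizing the chord (the true neck corners),
# keeping both arcs above the separation threshold
refineBottleneckPair <- function(orig, a, b, minSeparation, window = 25) {
  da <- sqrt(rowSums(sweep(orig, 2, a)^2))
  db <- sqrt(rowSums(sweep(orig, 2, b)^2))
  ia <- which(da <= window); ib <- which(db <= window)
  if (!length(ia) || !length(ib)) return(NULL)
  nxt <- rbind(orig[-1, , drop = FALSE], orig[1, , drop = FALSE])
  cum <- c(0, cumsum(sqrt(rowSums((nxt - orig)^2))))
  total <- cum[length(cum)]
  best <- NULL; bestChord <- Inf
  for (i in ia) {
    ch <- sqrt((orig[ib, 1] - orig[i, 1])^2 + (orig[ib, 2] - orig[i, 2])^2)
    arc1 <- abs(cum[ib] - cum[i]); arcMin <- pmin(arc1, total - arc1)
    ok <- arcMin > minSeparation & ch < bestChord
    if (any(ok)) {
      j <- ib[ok][which.min(ch[ok])]
      bestChord <- sqrt(sum((orig[j, ] - orig[i, ])^2))
      best <- c(i, j)
    }
  }
  best
}

#' Full anatomical contour post-processing
#'
#' Extracts per-slice contours from a segmentation, detects bottlenecks on a
#' polygon simplified within `simplifyTol`, refines each detected pair to
#' the narrowest nearby chord on the original contour, iteratively splits
#' (keeping the larger piece), applies an optional programmatic mask-edit
#' hook (e.g. manual IVC removal on chosen slices), and finally enforces the
#' interslice overlap constraint. Contours without detections are passed
#' through unmodified, so no area is lost to simplification.
#'
#' @param labels a [LabelVolume-class] (or [ProbabilityVolume-class], which
#'   is Otsu-binarized first).
#' @param simplifyTol polygon simplification tolerance in pixels used for
#'   detection (default 2).
#' @param Tb,Tc,minSeparation bottleneck parameters, see
#'   [detectBottlenecks()].
#' @param editHook optional `function(SliceContourSet) -> SliceContourSet`
#'   applied after bottleneck removal and before the interslice filter.
#' @param maxSplitsPerContour safety cap on repeated splits of one contour.
#' @return list with `contours` (filtered [SliceContourSet-class]) and
#'   `labels` (rasterized [LabelVolume-class]).
#' @export
postprocessContours <- function(labels, simplifyTol = 2, Tb = 0.6, Tc = 135,
                                minSeparation = 60, editHook = NULL,
                                maxSplitsPerContour = 4) {
  cs <- extractSliceContours(labels)
  d <- cs@dim
  splitOnce <- function(poly) {
    # returns the larger piece after one bottleneck split, or NULL
    simp <- approximatePolygon(poly, simplifyTol)
    bn <- detectBottlenecks(simp, Tb, Tc, minSeparation)
    if (nrow(bn) == 0) return(NULL)
    pair <- refineBottleneckPair(poly, simp[bn$i[1], ], simp[bn$j[1], ],
                                 minSeparation)
    if (is.null(pair)) pair <- c(match(paste(simp[bn$i[1], ], collapse = ","),
                                       apply(poly, 1, paste, collapse = ",")),
                                 match(paste(simp[bn$j[1], ], collapse = ","),
                                       apply(poly, 1, paste, collapse = ",")))
    if (any(is.na(pair))) return(NULL)
    tryCatch(removeBottleneck(poly, pair, keep = "larger")[[1]],
             error = function(e) NULL)
  }
  arr <- if (is(labels, "LabelVolume")) labels@labels else NULL
  masks <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    out <- list(); outMask <- list()
    comp <- if (!is.null(arr) && any(arr[s, , ] == 1L))
      EBImage::bwlabel(arr[s, , ]) else NULL
    for (ci in seq_along(cs@contours[[s]])) {
      poly <- cs@contours[[s]][[ci]]
      touched <- FALSE
      for (it in seq_len(maxSplitsPerContour)) {
        nxt <- splitOnce(poly)
        if (is.null(nxt)) break
        poly <- nxt; touched <- TRUE
      }
      out <- c(out, list(poly))
      # untouched contours keep their exact raster component; split ones
      # are re-rasterized from the cut polygon
      m <- if (!touched && !is.null(comp)) comp == ci else
        rasterizePolygon(poly, d[2], d[3])
      outMask <- c(outMask, list(m))
    }
    cs@contours[[s]] <- out
    masks[[s]] <- outMask
    cs@areas[[s]] <- vapply(outMask, sum, numeric(1))
  }
  if (!is.null(editHook)) cs <- editHook(cs)
  kept <- intersliceFilterMasks(cs, masks)
  list(contours = kept$set, labels = kept$labels)
}

# interslice filtering over precomputed per-contour masks; returns both the
# filtered contour set and the rasterized label volume
intersliceFilterMasks <- function(contourSet, masks,
                                  D = contourSet@sliceDistance) {
  Ts <- 0.8 - 0.05 * (D - 1)
  d <- contourSet@dim
  nS <- d[1]
  total <- vapply(contourSet@areas, function(a) sum(a), numeric(1))
  out <- array(0L, d)
  keptC <- vector("list", nS); keptA <- vector("list", nS)
  keptM <- vector("list", nS)
  for (s in seq_len(nS)) { keptC[[s]] <- list(); keptA[[s]] <- numeric(0) }
  if (all(total == 0)) {
    lv <- labelVolume(out, pixelSpacing = contourSet@pixelSpacing,
                      sliceDistance = contourSet@sliceDistance,
                      origin = contourSet@origin)
    return(list(set = contourSet, labels = lv))
  }
  start <- which.max(total)
  keptC[[start]] <- contourSet@contours[[start]]
  keptM[[start]] <- masks[[start]]
  keptA[[start]] <- vapply(masks[[start]], sum, numeric(1))
  sweepDir <- function(idx) {
    prev <- start
    for (s in idx) {
      keepI <- logical(length(masks[[s]]))
      for (ci in seq_along(masks[[s]])) {
        mi <- masks[[s]][[ci]]; ai <- sum(mi)
        if (ai == 0) next
        for (cj in seq_along(keptM[[prev]])) {
          inter <- sum(mi & keptM[[prev]][[cj]])
          if (inter / min(ai, keptA[[prev]][cj]) > Ts) {
            keepI[ci] <- TRUE; break
          }
        }
      }
      keptC[[s]] <<- contourSet@contours[[s]][keepI]
      keptM[[s]] <<- masks[[s]][keepI]
      keptA[[s]] <<- vapply(keptM[[s]], sum, numeric(1))
      if (length(keptM[[s]]) > 0) prev <- s
    }
  }
  if (start < nS) sweepDir((start + 1):nS)
  if (start > 1) sweepDir((start - 1):1)
  for (s in seq_len(nS))
    for (m in keptM[[s]]) out[s, , ][m] <- 1L
  set <- new("SliceContourSet", contours = keptC, areas = keptA,
             dim = contourSet@dim, pixelSpacing = contourSet@pixelSpacing,
             sliceDistance = contourSet@sliceDistance,
             origin = contourSet@origin)
  lv <- labelVolume(out, pixelSpacing = contourSet@pixelSpacing,
                    sliceDistance = contourSet@sliceDistance,
                    origin = contourSet@origin)
  list(set = set, labels = lv)
}
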