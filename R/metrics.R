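# SLIVER07-style evaluation: volumetric overlap error (VOE), relative
# volume difference (RVD), and average / RMS / maximum symmetric surface
# distances, plus the per-metric score max(100 - 25 e / e_ref, 0).

#' Volumetric overlap metrics
#'
#' `VOE = 100 (1 - |A n B| / |A u B|)`;
#' `RVD = 100 (|A| - |B|) / |B|`, signed: negative when the segmentation
#' under-covers the reference.
#'
#' @param segmented,reference co-registered [LabelVolume-class] objects
#'   (A = segmented, B = reference).
#' @return named vector `c(voe, rvd)` in percent.
#' @export
overlapMetrics <- function(segmented, reference) {
  A <- segmented@labels == 1L; B <- reference@labels == 1L
  if (!identical(dim(A), dim(B))) stop("volumes differ in shape")
  nB <- sum(B)
  if (nB == 0) stop("empty reference mask")
  c(voe = 100 * (1 - sum(A & B) / sum(A | B)),
    rvd = 100 * (sum(A) - nB) / nB)
}

boundaryVoxels <- function(mask) {
  d <- dim(mask)
  er <- mask
  er[-1, , ] <- er[-1, , ] & mask[-d[1], , ]
  er[-d[1], , ] <- er[-d[1], , ] & mask[-1, , ]
  er[, -1, ] <- er[, -1, ] & mask[, -d[2], ]
  er[, -d[2], ] <- er[, -d[2], ] & mask[, -1, ]
  er[, , -1] <- er[, , -1] & mask[, , -d[3]]
  er[, , -d[3]] <- er[, , -d[3]] & mask[, , -1]
  # voxels on the volume border are boundary by definition
  er[c(1, d[1]), , ] <- FALSE; er[, c(1, d[2]), ] <- FALSE
  er[, , c(1, d[3])] <- FALSE
  which(mask & !er, arr.ind = TRUE)
}

nearestDistances <- function(from, to, chunk = 2000L) {
  # min Euclidean distance from each row of `from` to the set `to` (mm)
  n <- nrow(from)
  out <- numeric(n)
  t2 <- rowSums(to^2)
  for (i0 in seq(1, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    f <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), t2, `+`) - 2 * f %*% t(to)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Symmetric surface distances
#'
#' Distances between the boundary-voxel surface points of the two masks, in
#' physical mm; statistics are taken over the pooled set of both directions:
#' average (ASD), root mean square (RMSD) and maximum (MSD).
#'
#' @inheritParams overlapMetrics
#' @return named vector `c(asd, rmsd, msd)` in mm.
#' @export
surfaceDistances <- function(segmented, reference) {
  A <- segmented@labels == 1L; B <- reference@labels == 1L
  if (sum(A) == 0 || sum(B) == 0) stop("empty mask")
  pa <- voxelToPhysical(segmented, boundaryVoxels(A))
  pb <- voxelToPhysical(reference, boundaryVoxels(B))
  d <- c(nearestDistances(pa, pb), nearestDistances(pb, pa))
  c(asd = mean(d), rmsd = sqrt(mean(d^2)), msd = max(d))
}

#' Per-metric score
#'
#' `score = max(100 - 25 epsilon / epsilonBar, 0)`: 100 at zero error, 75
#' when the error equals the reference error, clamped at 0.
#'
#' @param epsilon observed error, >= 0 (use `abs(RVD)` for the signed
#'   metric).
#' @param epsilonBar reference error for the metric, > 0.
#' @export
metricScore <- function(epsilon, epsilonBar) {
  if (any(epsilonBar <= 0)) stop("reference error must be > 0")
  if (any(epsilon < 0)) stop("error must be >= 0")
  pmax(100 - 25 * epsilon / epsilonBar, 0)
}

#' Full metric report
#'
#' The five SLIVER07 metrics, optionally with per-metric scores and their
#' unweighted mean. Reference errors are deliberately required input
#' (`refErrors`): they encode the comparison population (e.g. human-rater
#' errors) and no default is invented.
#'
#' @inheritParams overlapMetrics
#' @param refErrors named numeric vector with entries `voe, rvd, asd, rmsd,
#'   msd` (reference errors, per-metric units), or NULL to skip scores.
#' @return list with `metrics` (named vector), and when `refErrors` is
#'   given, `scores` and `overall` (their unweighted mean).
#' @export
metricReport <- function(segmented, reference, refErrors = NULL) {
  m <- c(overlapMetrics(segmented, reference),
         surfaceDistances(segmented, reference))
  out <- list(metrics = m)
  if (!is.null(refErrors)) {
    refErrors <- unlist(refErrors)
    need <- c("voe", "rvd", "asd", "rmsd", "msd")
    if (!all(need %in% names(refErrors)))
      stop("refErrors must name all of: ", paste(need, collapse = ", "))
    eps <- c(m["voe"], abs(m["rvd"]), m["asd"], m["rmsd"], m["msd"])
    out$scores <- stats::setNames(
      metricScore(eps, refErrors[need]), need)
    out$overall <- mean(out$scores)
  }
  out
}
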