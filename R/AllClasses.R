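#' @import methods
#' @importFrom stats median quantile rnorm runif sd var
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Volume geometry (virtual base)
#'
#' Common geometry carried by every volumetric object: in-plane pixel spacing
#' `(dx, dy)` in mm, inter-slice distance `D` in mm, and the physical origin of
#' voxel `(1,1,1)` in mm. Voxel arrays are indexed `(slice, row, col)`; the
#' slice index increases with physical z.
#'
#' @slot pixelSpacing numeric(2), `(dx, dy)` in mm, both > 0.
#' @slot sliceDistance numeric(1), inter-slice distance `D` in mm, > 0.
#' @slot origin numeric(3), physical `(x, y, z)` of the first voxel in mm.
#' @keywords internal
setClass("VolumeGeometry", representation("VIRTUAL",
  pixelSpacing = "numeric",
  sliceDistance = "numeric",
  origin = "numeric"
))

validGeometry <- function(object) {
  errs <- character(0)
  if (length(object@pixelSpacing) != 2 || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    errs <- c(errs, "pixelSpacing must be two positive finite numbers (dx, dy)")
  if (length(object@sliceDistance) != 1 || !is.finite(object@sliceDistance) ||
      object@sliceDistance <= 0)
    errs <- c(errs, "sliceDistance must be a single positive number")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    errs <- c(errs, "origin must be three finite numbers")
  errs
}

#' CT volume
#'
#' A 3D scalar CT volume in Hounsfield-like units with its acquisition
#' geometry. The intensity array is indexed `(slice, row, col)`.
#'
#' @slot intensities 3D numeric array `(slice, row, col)`.
#' @seealso [ctVolume()], [readCtVolume()]
#' @export
setClass("CtVolume", contains = "VolumeGeometry",
  representation(intensities = "array"))

setValidity("CtVolume", function(object) {
  errs <- validGeometry(object)
  if (length(dim(object@intensities)) != 3)
    errs <- c(errs, "intensities must be a 3D array (slice, row, col)")
  if (length(errs)) errs else TRUE
})

#' Binary label volume
#'
#' Voxel labels on the same grid as a [CtVolume-class]: 0 = background,
#' 1 = liver.
#'
#' @slot labels 3D integer array with values in \{0, 1\}.
#' @seealso [labelVolume()], [writeLabelmap()]
#' @export
setClass("LabelVolume", contains = "VolumeGeometry",
  representation(labels = "array"))

setValidity("LabelVolume", function(object) {
  errs <- validGeometry(object)
  if (length(dim(object@labels)) != 3)
    errs <- c(errs, "labels must be a 3D array (slice, row, col)")
  v <- unique(as.vector(object@labels))
  if (!all(v %in% c(0L, 1L)))
    errs <- c(errs, "labels must contain only 0 and 1")
  if (length(errs)) errs else TRUE
})

#' Per-voxel liver membership map
#'
#' Values in `[0, 1]`; produced by [liverProbability()] and refined by
#' [relaxProbability()].
#'
#' @slot values 3D numeric array in `[0, 1]`.
#' @export
setClass("ProbabilityVolume", contains = "VolumeGeometry",
  representation(values = "array"))

setValidity("ProbabilityVolume", function(object) {
  errs <- validGeometry(object)
  if (length(dim(object@values)) != 3)
    errs <- c(errs, "values must be a 3D array (slice, row, col)")
  rng <- range(object@values)
  if (!all(is.finite(rng)) || rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
    errs <- c(errs, "values must lie in [0, 1]")
  if (length(errs)) errs else TRUE
})

#' Local statistical feature volume
#'
#' Per-voxel local mean and standard deviation of intensity, computed over an
#' in-plane N-by-N window within each slice.
#'
#' @slot mu 3D array of local means.
#' @slot sigma 3D array of local standard deviations (sample sd, >= 0).
#' @slot windowWidth odd integer window width N.
#' @seealso [computeLocalFeatures()]
#' @export
setClass("FeatureVolume", contains = "VolumeGeometry",
  representation(mu = "array", sigma = "array", windowWidth = "integer"))

setValidity("FeatureVolume", function(object) {
  errs <- validGeometry(object)
  if (!identical(dim(object@mu), dim(object@sigma)))
    errs <- c(errs, "mu and sigma must have identical dimensions")
  if (min(object@sigma) < -1e-9)
    errs <- c(errs, "sigma must be non-negative")
  if (object@windowWidth %% 2L != 1L || object@windowWidth < 3L)
    errs <- c(errs, "windowWidth must be odd and >= 3")
  if (length(errs)) errs else TRUE
})

#' Per-seed bivariate Gaussian feature model
#'
#' One record per seed point: the mean feature vector (local mean, local sd)
#' and its 2x2 covariance over the (2N-1)x(2N-1) patch around the seed.
#'
#' @slot means k-by-2 matrix of per-seed mean features.
#' @slot covariances list of k symmetric positive-definite 2x2 matrices.
#' @slot seeds k-by-3 matrix of seed voxel coordinates (slice, row, col).
#' @slot windowWidth window width N the model was built with.
#' @seealso [fitSeedModels()]
#' @export
setClass("SeedModel", representation(
  means = "matrix", covariances = "list", seeds = "matrix",
  windowWidth = "integer"))

setValidity("SeedModel", function(object) {
  errs <- character(0)
  k <- nrow(object@means)
  if (k < 1) errs <- c(errs, "at least one seed is required")
  if (ncol(object@means) != 2) errs <- c(errs, "means must be k x 2")
  if (length(object@covariances) != k)
    errs <- c(errs, "one covariance per seed required")
  for (S in object@covariances) {
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      errs <- c(errs, "each covariance must be symmetric positive-definite")
      break
    }
  }
  if (nrow(object@seeds) != k || ncol(object@seeds) != 3)
    errs <- c(errs, "seeds must be k x 3 (slice, row, col)")
  if (length(errs)) errs else TRUE
})

#' Multi-slice relaxation-labeling neighbour weights
#'
#' Normalized inverse-distance weights over the 26 neighbourhood offsets
#' `(dx, dy, ds)` in `{-1,0,1}^3` minus the origin, with the slice term scaled
#' by the physical slice distance D.
#'
#' @slot offsets 26-by-3 integer matrix of offsets (dx, dy, ds).
#' @slot weights numeric(26), positive, summing to one.
#' @slot sliceDistance slice distance D (mm) used to build the table.
#' @seealso [mrlWeightTable()]
#' @export
setClass("NeighborWeights", representation(
  offsets = "matrix", weights = "numeric", sliceDistance = "numeric"))

setValidity("NeighborWeights", function(object) {
  errs <- character(0)
  if (nrow(object@offsets) != 26 || length(object@weights) != 26)
    errs <- c(errs, "exactly 26 neighbour offsets are required")
  if (any(object@weights <= 0)) errs <- c(errs, "weights must be positive")
  if (abs(sum(object@weights) - 1) > 1e-12)
    errs <- c(errs, "weights must sum to 1")
  # symmetry under offset negation
  key <- apply(object@offsets, 1, paste, collapse = ",")
  nkey <- apply(-object@offsets, 1, paste, collapse = ",")
  if (any(abs(object@weights - object@weights[match(nkey, key)]) > 1e-12))
    errs <- c(errs, "weights must be symmetric under offset negation")
  if (length(errs)) errs else TRUE
})

#' Per-pixel structure-tensor field of one slice
#'
#' Local orientation, anisotropic measure, corner strength and adaptive kernel
#' axes of a 2D image, from windowed products of first-order derivatives.
#'
#' @slot theta orientation in radians, in `[0, pi)`.
#' @slot g anisotropic measure in `[0, 1]`.
#' @slot c corner strength, >= 0.
#' @slot s1,s2 kernel major/minor axes (s2 <= s1).
#' @slot r support radius; @slot lambda corner-strength weight.
#' @seealso [structureField()]
#' @export
setClass("StructureField", representation(
  theta = "matrix", g = "matrix", c = "matrix",
  s1 = "matrix", s2 = "matrix", r = "numeric", lambda = "numeric"))

setValidity("StructureField", function(object) {
  errs <- character(0)
  if (min(object@g) < -1e-12 || max(object@g) > 1 + 1e-12)
    errs <- c(errs, "g must lie in [0, 1]")
  if (min(object@c) < -1e-12) errs <- c(errs, "c must be non-negative")
  if (any(object@s2 > object@s1 + 1e-9)) errs <- c(errs, "s2 must be <= s1")
  th <- range(object@theta)
  if (th[1] < -1e-9 || th[2] >= pi + 1e-9)
    errs <- c(errs, "theta must lie in [0, pi)")
  if (length(errs)) errs else TRUE
})

#' Per-slice closed contour set
#'
#' For every axial slice, a list of closed simple polygons (n-by-2 matrices of
#' pixel coordinates `(row, col)`, counter-clockwise in image coordinates so
#' the interior lies to the left) with cached areas (pixel counts of the
#' rasterized interior).
#'
#' @slot contours list (one element per slice) of lists of polygons.
#' @slot areas list parallel to `contours` with rasterized pixel-count areas.
#' @slot dim integer(3) grid dimensions (slices, rows, cols).
#' @seealso [extractSliceContours()], [intersliceFilter()]
#' @export
setClass("SliceContourSet", contains = "VolumeGeometry",
  representation(contours = "list", areas = "list", dim = "integer"))

setValidity("SliceContourSet", function(object) {
  errs <- validGeometry(object)
  if (length(object@contours) != object@dim[1])
    errs <- c(errs, "one contour list per slice required")
  if (length(object@areas) != length(object@contours))
    errs <- c(errs, "areas must parallel contours")
  if (length(errs)) errs else TRUE
})

#' Triangle surface mesh
#'
#' A triangulated surface in physical (mm) coordinates. Pipeline outputs
#' destined for conformal mapping must be watertight and genus-0
#' (V - E + F = 2).
#'
#' @slot vertices V-by-3 numeric matrix (mm).
#' @slot faces F-by-3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals).
#' @seealso [triangleMesh()], [reconstructSurface()], [cleanAndResample()]
#' @export
setClass("TriangleMesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  errs <- character(0)
  if (ncol(object@vertices) != 3) errs <- c(errs, "vertices must be V x 3")
  if (ncol(object@faces) != 3) errs <- c(errs, "faces must be F x 3")
  if (nrow(object@faces) > 0) {
    rng <- range(object@faces)
    if (rng[1] < 1 || rng[2] > nrow(object@vertices))
      errs <- c(errs, "face indices out of range")
  }
  if (length(errs)) errs else TRUE
})

#' Spherical conformal parameterization of a mesh
#'
#' Per-vertex unit-sphere positions of a genus-0 mesh together with the
#' per-face Beltrami coefficients of the final map and per-corner angle
#' distortions. After Beltrami correction every interior face satisfies
#' `|mu| < 1` (orientation preserved).
#'
#' @slot positions V-by-3 matrix of unit vectors.
#' @slot mesh the source [TriangleMesh-class].
#' @slot mu complex per-face Beltrami coefficient (NA for the outer face of
#'   the planar representation).
#' @slot angleDistortion per-corner absolute angle distortion (degrees),
#'   F-by-3.
#' @slot outerFace index of the face used as the planar outer boundary.
#' @slot energyTrace harmonic-energy value after each accepted solver step
#'   (non-increasing).
#' @seealso [sphericalParameterize()]
#' @export
setClass("SphericalMap", representation(
  positions = "matrix", mesh = "TriangleMesh", mu = "complex",
  angleDistortion = "matrix", outerFace = "integer",
  energyTrace = "numeric"))

setValidity("SphericalMap", function(object) {
  errs <- character(0)
  if (nrow(object@positions) != nrow(object@mesh@vertices))
    errs <- c(errs, "one spherical position per mesh vertex required")
  nrm <- sqrt(rowSums(object@positions^2))
  if (any(abs(nrm - 1) > 1e-9))
    errs <- c(errs, "all spherical positions must have unit norm (1e-9)")
  if (length(errs)) errs else TRUE
})

#' Labelled resection path
#'
#' An ordered 3D polyline lying on a mesh surface, labelled by the vascular
#' structure it follows (LHV/MHV/RHV along the hepatic veins, LPV/RPV along
#' the portal veins).
#'
#' @slot points n-by-3 matrix (mm), n >= 2.
#' @slot label one of "LHV", "MHV", "RHV", "LPV", "RPV".
#' @export
setClass("ResectionPath", representation(points = "matrix", label = "character"))

setValidity("ResectionPath", function(object) {
  errs <- character(0)
  if (ncol(object@points) != 3 || nrow(object@points) < 2)
    errs <- c(errs, "points must be an n x 3 matrix with n >= 2")
  if (length(object@label) != 1 ||
      !(object@label %in% c("LHV", "MHV", "RHV", "LPV", "RPV")))
    errs <- c(errs, "label must be one of LHV, MHV, RHV, LPV, RPV")
  if (length(errs)) errs else TRUE
})
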