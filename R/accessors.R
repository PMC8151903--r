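# Constructors, accessors and show methods.

#' Construct a CtVolume
#'
#' @param intensities 3D numeric array, indexed (slice, row, col).
#' @param pixelSpacing numeric(2) in-plane spacing (dx, dy) in mm.
#' @param sliceDistance inter-slice distance D in mm.
#' @param origin physical (x, y, z) of voxel (1,1,1) in mm.
#' @return A [CtVolume-class].
#' @examples
#' v <- ctVolume(array(0, c(4, 8, 8)), c(1, 1), 2)
#' sliceDistance(v)
#' @export
ctVolume <- function(intensities, pixelSpacing = c(1, 1), sliceDistance = 1,
                     origin = c(0, 0, 0)) {
  new("CtVolume", intensities = intensities,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceDistance = as.numeric(sliceDistance), origin = as.numeric(origin))
}

#' Construct a LabelVolume
#'
#' @param labels 3D array of 0/1 labels.
#' @inheritParams ctVolume
#' @return A [LabelVolume-class].
#' @export
labelVolume <- function(labels, pixelSpacing = c(1, 1), sliceDistance = 1,
                        origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, pixelSpacing = as.numeric(pixelSpacing),
      sliceDistance = as.numeric(sliceDistance), origin = as.numeric(origin))
}

#' Construct a ProbabilityVolume
#'
#' @param values 3D numeric array in \[0, 1\].
#' @inheritParams ctVolume
#' @return A [ProbabilityVolume-class].
#' @export
probabilityVolume <- function(values, pixelSpacing = c(1, 1),
                              sliceDistance = 1, origin = c(0, 0, 0)) {
  new("ProbabilityVolume", values = values,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceDistance = as.numeric(sliceDistance), origin = as.numeric(origin))
}

#' Construct a TriangleMesh
#'
#' @param vertices V-by-3 numeric matrix (mm).
#' @param faces F-by-3 matrix of 1-based vertex indices.
#' @return A [TriangleMesh-class].
#' @export
triangleMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' Construct a ResectionPath
#'
#' @param points n-by-3 matrix of points (mm) on a mesh surface.
#' @param label path label ("LHV", "MHV", "RHV", "LPV" or "RPV").
#' @return A [ResectionPath-class].
#' @export
resectionPath <- function(points, label) {
  new("ResectionPath", points = as.matrix(points), label = label)
}

#' @describeIn ctVolume Intensity array accessor.
#' @param x object.
#' @export
intensities <- function(x) x@intensities

#' Label array accessor
#' @param x a [LabelVolume-class].
#' @export
labelArray <- function(x) x@labels

#' Probability array accessor
#' @param x a [ProbabilityVolume-class].
#' @export
probArray <- function(x) x@values

#' In-plane pixel spacing (dx, dy) in mm
#' @param x a volumetric object.
#' @export
pixelSpacing <- function(x) x@pixelSpacing

#' Inter-slice distance D in mm
#' @param x a volumetric object.
#' @export
sliceDistance <- function(x) x@sliceDistance

#' Physical origin (mm) of the first voxel
#' @param x a volumetric object.
#' @export
originMm <- function(x) x@origin

#' Mesh vertex matrix accessor
#' @param x a [TriangleMesh-class] or [SphericalMap-class].
#' @export
meshVertices <- function(x) {
  if (is(x, "SphericalMap")) x@mesh@vertices else x@vertices
}

#' Mesh face matrix accessor
#' @param x a [TriangleMesh-class] or [SphericalMap-class].
#' @export
meshFaces <- function(x) {
  if (is(x, "SphericalMap")) x@mesh@faces else x@faces
}

#' Unit-sphere vertex positions of a spherical map
#' @param x a [SphericalMap-class].
#' @export
spherePositions <- function(x) x@positions

#' Per-face Beltrami coefficients of a spherical map
#' @param x a [SphericalMap-class].
#' @export
beltrami <- function(x) x@mu

#' Path point matrix accessor
#' @param x a [ResectionPath-class].
#' @export
pathPoints <- function(x) x@points

#' @rdname pathPoints
#' @export
pathLabel <- function(x) x@label

setMethod("dim", "CtVolume", function(x) dim(x@intensities))
setMethod("dim", "LabelVolume", function(x) dim(x@labels))
setMethod("dim", "ProbabilityVolume", function(x) dim(x@values))

geomLine <- function(x) {
  sprintf("spacing %.3g x %.3g mm, D = %.3g mm, origin (%.3g, %.3g, %.3g) mm",
          x@pixelSpacing[1], x@pixelSpacing[2], x@sliceDistance,
          x@origin[1], x@origin[2], x@origin[3])
}

setMethod("show", "CtVolume", function(object) {
  d <- dim(object)
  cat(sprintf("CtVolume: %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(" ", geomLine(object), "\n")
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object)
  cat(sprintf("LabelVolume: %d slices x %d rows x %d cols, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@labels)))
  cat(" ", geomLine(object), "\n")
})

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object)
  cat(sprintf("ProbabilityVolume: %d slices x %d rows x %d cols, mean %.4f\n",
              d[1], d[2], d[3], mean(object@values)))
  cat(" ", geomLine(object), "\n")
})

setMethod("show", "FeatureVolume", function(object) {
  d <- dim(object@mu)
  cat(sprintf("FeatureVolume: %d x %d x %d, window N = %d\n",
              d[1], d[2], d[3], object@windowWidth))
})

setMethod("show", "SeedModel", function(object) {
  cat(sprintf("SeedModel: k = %d seeds, window N = %d\n",
              nrow(object@means), object@windowWidth))
  for (i in seq_len(nrow(object@means)))
    cat(sprintf("  seed %d at (%d, %d, %d): mean feature (%.3f, %.3f)\n", i,
                object@seeds[i, 1], object@seeds[i, 2], object@seeds[i, 3],
                object@means[i, 1], object@means[i, 2]))
})

setMethod("show", "NeighborWeights", function(object) {
  cat(sprintf("NeighborWeights: 26 offsets, D = %.3g mm, in-plane weight mass %.4f\n",
              object@sliceDistance, sum(object@weights[object@offsets[, 3] == 0])))
})

setMethod("show", "StructureField", function(object) {
  cat(sprintf("StructureField: %d x %d, r = %g, lambda = %g, mean g = %.4f\n",
              nrow(object@g), ncol(object@g), object@r, object@lambda,
              mean(object@g)))
})

setMethod("show", "SliceContourSet", function(object) {
  n <- vapply(object@contours, length, integer(1))
  cat(sprintf("SliceContourSet: %d slices, %d contours (%d non-empty slices)\n",
              object@dim[1], sum(n), sum(n > 0)))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces, Euler characteristic %s\n",
              nrow(object@vertices), nrow(object@faces),
              tryCatch(eulerCharacteristic(object), error = function(e) NA)))
})

setMethod("show", "SphericalMap", function(object) {
  amu <- abs(object@mu)
  cat(sprintf(
    "SphericalMap: %d vertices; max |mu| = %.4f; mean angle distortion %.3f deg\n",
    nrow(object@positions), max(amu[is.finite(amu)]),
    mean(object@angleDistortion, na.rm = TRUE)))
})

setMethod("show", "ResectionPath", function(object) {
  cat(sprintf("ResectionPath %s: %d points\n", object@label,
              nrow(object@points)))
})
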