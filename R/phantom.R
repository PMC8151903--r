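# Synthetic CT phantom: an inhomogeneous bright "liver" superellipsoid with a
# smooth multiplicative bias field and Gaussian noise, optionally joined to a
# similar-intensity adjacent "organ" blob through a thin neck, plus an
# optional tubular IVC-like structure half-embedded at the liver boundary.
# Ground truth is the liver superellipsoid interior only.

#' Specify a CT phantom
#'
#' Defaults emulate a contrast-enhanced abdominal CT at desk scale: liver
#' around 120 HU over a 40 HU soft-tissue background (80 HU contrast), an
#' adjacent organ of nearly identical density (2 HU below the liver, well
#' inside the noise), 10 HU Gaussian noise and a mild 3 % multiplicative
#' bias field producing the few-HU parenchymal inhomogeneity the
#' relaxation-labeling stage is meant to homogenize.
#'
#' @param shape integer(3) grid size (slices, rows, cols).
#' @param liverCenter,liverSemiAxes numeric(3) superellipsoid centre and
#'   semi-axes in voxel units (slice, row, col).
#' @param liverExponent superellipsoid exponent (2 = ellipsoid).
#' @param liverMean,organMean,backgroundMean intensities (HU-like).
#' @param biasAmplitude amplitude of the multiplicative bias field, as a
#'   fraction (0 disables it).
#' @param noiseSd Gaussian noise standard deviation (intensity units).
#' @param neckWidth in-plane width (voxels) of the neck joining liver and
#'   adjacent organ; 0 removes organ and neck. The default 12 exceeds twice
#'   the feature-window half-width, so the neck's core survives the region
#'   term and genuinely connects the two structures.
#' @param ivcRadius radius (voxels) of the vertical IVC-like cylinder
#'   half-embedded at the liver boundary; 0 removes it.
#' @param biasWavelength in-plane wavelength of the bias modes, voxels.
#' @param pixelSpacing in-plane spacing (dx, dy) mm.
#' @param D inter-slice distance, mm.
#' @param seed integer seed; all randomness flows from it.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(shape = c(24L, 96L, 128L),
                        liverCenter = c(12.5, 48, 44),
                        liverSemiAxes = c(8, 30, 32),
                        liverExponent = 2.2,
                        liverMean = 120, organMean = 118, backgroundMean = 40,
                        biasAmplitude = 0.03, noiseSd = 10,
                        neckWidth = 12, ivcRadius = 0,
                        biasWavelength = 40, pixelSpacing = c(0.25, 0.25),
                        D = 1.5, seed = 1L) {
  spec <- list(shape = as.integer(shape), liverCenter = liverCenter,
               liverSemiAxes = liverSemiAxes, liverExponent = liverExponent,
               liverMean = liverMean, organMean = organMean,
               backgroundMean = backgroundMean, biasAmplitude = biasAmplitude,
               noiseSd = noiseSd, neckWidth = neckWidth, ivcRadius = ivcRadius,
               biasWavelength = biasWavelength, pixelSpacing = pixelSpacing,
               D = D, seed = as.integer(seed))
  stopifnot(all(spec$shape > 0), spec$noiseSd >= 0, spec$neckWidth >= 0,
            spec$ivcRadius >= 0, all(liverSemiAxes > 0), D > 0,
            all(pixelSpacing > 0))
  class(spec) <- "PhantomSpec"
  spec
}

superellipsoidMask <- function(shape, center, semi, e) {
  s <- abs((seq_len(shape[1]) - center[1]) / semi[1])^e
  r <- abs((seq_len(shape[2]) - center[2]) / semi[2])^e
  c <- abs((seq_len(shape[3]) - center[3]) / semi[3])^e
  outer(outer(s, r, `+`), c, `+`) <= 1
}

#' Analytic volume of a superellipsoid
#'
#' Volume of \{ |x/a|^e + |y/b|^e + |z/c|^e <= 1 \}:
#' `8 a b c Gamma(1 + 1/e)^3 / Gamma(1 + 3/e)`.
#'
#' @param semiAxes numeric(3) semi-axes.
#' @param exponent exponent e > 0.
#' @export
superellipsoidVolume <- function(semiAxes, exponent) {
  8 * prod(semiAxes) * gamma(1 + 1 / exponent)^3 / gamma(1 + 3 / exponent)
}

organGeometry <- function(spec) {
  # organ sits beside the liver along +col, similar density, ~45 % size;
  # the 20-voxel gap gives the joining neck a genuine neck-like length
  semi <- pmax(spec$liverSemiAxes * c(0.55, 0.45, 0.45), 3)
  gap <- 20
  center <- spec$liverCenter +
    c(0, 0, spec$liverSemiAxes[3] + gap + semi[3])
  list(center = center, semi = semi, gap = gap)
}

#' Generate a CT-like phantom with ground truth
#'
#' Deterministic given `spec$seed`. The truth mask is the liver
#' superellipsoid interior only: the adjacent organ, the joining neck and the
#' IVC-like cylinder are excluded from truth even where they touch or indent
#' the liver.
#'
#' @param spec a [phantomSpec()].
#' @return list with elements `volume` ([CtVolume-class]), `truth`
#'   ([LabelVolume-class]), and logical component masks `organMask`,
#'   `neckMask`, `ivcMask`.
#' @export
generatePhantomCt <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  shape <- spec$shape
  lo <- spec$liverCenter - spec$liverSemiAxes
  hi <- spec$liverCenter + spec$liverSemiAxes
  if (any(lo < 2) || any(hi > shape - 1))
    stop("liver superellipsoid is not fully inside the volume")

  liver <- superellipsoidMask(shape, spec$liverCenter, spec$liverSemiAxes,
                              spec$liverExponent)
  organ <- array(FALSE, shape); neck <- array(FALSE, shape)
  if (spec$neckWidth > 0) {
    og <- organGeometry(spec)
    if (og$center[3] + og$semi[3] > shape[3] - 1)
      stop("adjacent organ does not fit inside the volume; widen the grid")
    organ <- superellipsoidMask(shape, og$center, og$semi, spec$liverExponent)
    organZ <- which(apply(organ, 1, any))
    rows <- which(abs(seq_len(shape[2]) - spec$liverCenter[2]) <=
                    spec$neckWidth / 2)
    cols <- which(seq_len(shape[3]) >= spec$liverCenter[3] &
                    seq_len(shape[3]) <= og$center[3])
    neck[organZ, rows, cols] <- TRUE
    neck <- neck & !liver & !organ
  }
  ivc <- array(FALSE, shape)
  if (spec$ivcRadius > 0) {
    # vertical cylinder touching the liver boundary at its +row extreme
    ctr <- c(spec$liverCenter[2] + spec$liverSemiAxes[2], spec$liverCenter[3])
    rr <- outer((seq_len(shape[2]) - ctr[1])^2,
                (seq_len(shape[3]) - ctr[2])^2, `+`) <= spec$ivcRadius^2
    for (s in seq_len(shape[1])) ivc[s, , ] <- rr
  }

  img <- array(spec$backgroundMean, shape)
  img[liver] <- spec$liverMean
  img[organ] <- spec$organMean
  img[neck] <- (spec$liverMean + spec$organMean) / 2
  img[ivc] <- spec$liverMean - 2

  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(spec$seed)

  if (spec$biasAmplitude > 0) {
    # two in-plane modes at the stated wavelength plus a milder through-plane
    # mode; in-plane wavelengths are comparable to the seed-model patch so a
    # seed's covariance can capture the inhomogeneity it sits in
    ph <- runif(3, 0, 2 * pi)
    bs <- 0.2 * cos(pi * seq_len(shape[1]) / shape[1] + ph[1])
    br <- 0.4 * cos(2 * pi * seq_len(shape[2]) / spec$biasWavelength + ph[2])
    bc <- 0.4 * cos(2 * pi * seq_len(shape[3]) / spec$biasWavelength + ph[3])
    bias <- outer(outer(bs, br, `+`), bc, `+`)
    img <- img * (1 + spec$biasAmplitude * bias)
  }
  if (spec$noiseSd > 0)
    img <- img + array(rnorm(prod(shape), 0, spec$noiseSd), shape)

  truth <- liver & !ivc & !organ & !neck
  list(volume = ctVolume(img, pixelSpacing = spec$pixelSpacing,
                         sliceDistance = spec$D),
       truth = labelVolume(array(as.integer(truth), shape),
                           pixelSpacing = spec$pixelSpacing,
                           sliceDistance = spec$D),
       organMask = organ, neckMask = neck, ivcMask = ivc)
}
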