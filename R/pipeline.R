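# End-to-end orchestration: segmentation (seed model -> MRL -> anisotropy ->
# graph cut -> contour post-processing -> surface) and cross-individual
# resection correspondence, with config validation, deterministic seeding
# and per-stage logging.

#' Pipeline configuration
#'
#' All stage parameters with their defaults: `model.window_n = 9`,
#' `model.k = 2`, `mrl.iterations = 5`, `mrl.physical_units = FALSE`,
#' `aniso.r = 3`, `aniso.lambda = 0.75`, `gc.alpha = 0.6`,
#' `gc.delta = NULL` (auto), `gc.neighborhood = "in-plane-8"` (per-slice
#' cuts; `"volumetric-26"` available), `bn.tb = 0.6`, `bn.tc_deg = 135`,
#' `bn.min_separation = 60`, `post.simplify_tol = 2`,
#' `mesh.target_vertices = 12000`, `conf.gamma = 100`.
#'
#' @param ... overrides as named values using the dotted keys above.
#' @param file optional YAML config file; values in `...` override the file.
#' @return validated named list.
#' @export
hsConfig <- function(..., file = NULL) {
  defaults <- list(
    "model.window_n" = 9L, "model.k" = 2L,
    "mrl.iterations" = 5L, "mrl.physical_units" = FALSE,
    "aniso.r" = 3L, "aniso.lambda" = 0.75,
    "gc.alpha" = 0.6, "gc.delta" = NULL,
    "gc.neighborhood" = "in-plane-8",
    "bn.tb" = 0.6, "bn.tc_deg" = 135, "bn.min_separation" = 60,
    "post.simplify_tol" = 2,
    "mesh.target_vertices" = 12000L,
    "conf.gamma" = 100,
    "score.ref_errors" = NULL)
  cfg <- defaults
  if (!is.null(file)) {
    fromFile <- yaml::read_yaml(file)
    unknown <- setdiff(names(fromFile), names(defaults))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(fromFile)] <- fromFile
  }
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$`model.window_n` %% 2 == 1, cfg$`model.window_n` >= 3,
            cfg$`mrl.iterations` >= 0, cfg$`gc.alpha` >= 0,
            cfg$`gc.alpha` <= 1, cfg$`bn.tb` > 0,
            cfg$`gc.neighborhood` %in% c("in-plane-8", "volumetric-26"),
            cfg$`conf.gamma` >= 0)
  cfg
}

stageLog <- function(verbose, stage, t0, ...) {
  if (verbose)
    message(sprintf("[%s] %.1f s %s", stage,
                    as.numeric(Sys.time() - t0, units = "secs"),
                    paste(..., collapse = " ")))
}

#' Run the full segmentation pipeline
#'
#' seed model -> multi-slice relaxation labeling -> per-slice anisotropy ->
#' graph cut -> bottleneck and interslice contour post-processing -> surface
#' reconstruction, with optional evaluation against a reference mask.
#'
#' @param ct a [CtVolume-class].
#' @param seeds k-by-3 matrix of liver seed voxels (slice, row, col).
#' @param config a [hsConfig()] list.
#' @param reference optional reference [LabelVolume-class]; adds a metric
#'   report.
#' @param editHook optional contour-set hook applied before the interslice
#'   filter (programmatic IVC removal), see [postprocessContours()].
#' @param mesh reconstruct the surface mesh (default TRUE).
#' @param verbose log stage timings to stderr.
#' @return list with `probability` (after MRL), `gc` (solver result),
#'   `labels` (post-processed [LabelVolume-class]), `contours`
#'   ([SliceContourSet-class]), `mesh` ([TriangleMesh-class] or NULL),
#'   `report` (metric list or NULL) and `config`.
#' @export
runSegmentation <- function(ct, seeds, config = hsConfig(),
                            reference = NULL, editHook = NULL, mesh = TRUE,
                            verbose = FALSE) {
  stopifnot(is(ct, "CtVolume"))
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (nrow(seeds) < 1) stop("at least one seed is required")
  t0 <- Sys.time()
  feats <- computeLocalFeatures(ct, config$`model.window_n`)
  model <- fitSeedModels(feats, seeds, config$`model.window_n`)
  p0 <- liverProbability(feats, model)
  stageLog(verbose, "seed_model", t0, sprintf("k=%d", nrow(seeds)))

  t0 <- Sys.time()
  w <- mrlWeightTable(ct@sliceDistance, ct@pixelSpacing,
                      config$`mrl.physical_units`)
  p1 <- relaxProbability(p0, w, config$`mrl.iterations`)
  stageLog(verbose, "relaxation", t0,
           sprintf("iterations=%d", config$`mrl.iterations`))

  t0 <- Sys.time()
  gvol <- anisotropyVolume(ct, config$`aniso.r`, config$`aniso.lambda`)
  stageLog(verbose, "anisotropy", t0)

  t0 <- Sys.time()
  gcc <- gcConfig(alpha = config$`gc.alpha`, delta = config$`gc.delta`,
                  neighborhood = config$`gc.neighborhood`)
  gc <- segmentMincut(ct, p1, gvol, gcc, seeds = seeds)
  stageLog(verbose, "graph_cut", t0,
           sprintf("energy=%.4g voxels=%d", gc$energy,
                   sum(gc$labels@labels)))

  t0 <- Sys.time()
  post <- postprocessContours(gc$labels,
                              simplifyTol = config$`post.simplify_tol`,
                              Tb = config$`bn.tb`, Tc = config$`bn.tc_deg`,
                              minSeparation = config$`bn.min_separation`,
                              editHook = editHook)
  stageLog(verbose, "contour_post", t0,
           sprintf("voxels=%d", sum(post$labels@labels)))

  surf <- NULL
  if (mesh && sum(post$labels@labels) > 0) {
    t0 <- Sys.time()
    surf <- reconstructSurface(post$labels)
    stageLog(verbose, "surface", t0,
             sprintf("V=%d F=%d", nrow(surf@vertices), nrow(surf@faces)))
  }
  report <- NULL
  if (!is.null(reference))
    report <- metricReport(post$labels, reference,
                           refErrors = config$`score.ref_errors`)
  list(probability = p1, gc = gc, labels = post$labels,
       contours = post$contours, mesh = surf, report = report,
       config = config)
}

#' Cross-individual resection correspondence
#'
#' Parameterizes the target mesh unconstrained, then the source mesh with
#' landmark anchors at the target's landmark images, composes the
#' registration `g = f2^-1 o f1`, transfers every labelled resection path
#' from the target onto the source, and tabulates symmetric Hausdorff
#' statistics against the source's own paths where available.
#'
#' @param meshS1,meshS2 genus-0 [TriangleMesh-class] source / target.
#' @param landmarksS1,landmarksS2 named integer vectors (matching label
#'   sets) of 1-based vertex indices.
#' @param pathsS2 list of [ResectionPath-class] on the target.
#' @param pathsS1 optional list of the source's own paths (same labels) for
#'   evaluation.
#' @param config a [hsConfig()] list (uses `conf.gamma`).
#' @param verbose log stage timings.
#' @return list with `map1`, `map2` ([SphericalMap-class]), `transferred`
#'   (list of [ResectionPath-class] on S1), `registered` (S1 vertices mapped
#'   onto S2) and `hausdorff` (data frame Max/Min/Mean/RMS per path plus
#'   column averages, NULL without `pathsS1`).
#' @export
runCorrespondence <- function(meshS1, landmarksS1, meshS2, landmarksS2,
                              pathsS2, pathsS1 = NULL, config = hsConfig(),
                              verbose = FALSE) {
  common <- intersect(names(landmarksS1), names(landmarksS2))
  if (length(setdiff(names(landmarksS1), common)) ||
      length(setdiff(names(landmarksS2), common)))
    stop("landmark label sets differ between the meshes")
  t0 <- Sys.time()
  map2 <- sphericalParameterize(meshS2)
  stageLog(verbose, "parameterize_target", t0)
  t0 <- Sys.time()
  targets <- map2@positions[landmarksS2[common], , drop = FALSE]
  map1 <- sphericalParameterize(meshS1, landmarks = landmarksS1[common],
                                targetPositions = targets,
                                gamma = config$`conf.gamma`)
  stageLog(verbose, "parameterize_source", t0)
  t0 <- Sys.time()
  reg <- composeRegistration(map1, map2)
  transferred <- lapply(pathsS2, function(p) transferResection(p, map1, map2))
  stageLog(verbose, "transfer", t0)
  hd <- NULL
  if (!is.null(pathsS1)) {
    lbl1 <- vapply(pathsS1, pathLabel, character(1))
    rows <- lapply(transferred, function(tp) {
      ref <- pathsS1[[match(tp@label, lbl1)]]
      if (is.null(ref)) return(NULL)
      st <- hausdorffStats(tp@points, ref@points)
      data.frame(path = tp@label, Max = st["max"], Min = st["min"],
                 Mean = st["mean"], RMS = st["rms"], row.names = NULL)
    })
    hd <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(hd) && nrow(hd) > 0)
      hd <- rbind(hd, data.frame(path = "Average", Max = mean(hd$Max),
                                 Min = mean(hd$Min), Mean = mean(hd$Mean),
                                 RMS = mean(hd$RMS)))
  }
  list(map1 = map1, map2 = map2, transferred = transferred,
       registered = reg, hausdorff = hd)
}
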