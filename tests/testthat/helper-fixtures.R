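# Shared fixtures. Heavy objects (full phantom segmentations, parameterized
# mesh pairs) are built once per session and memoized.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixtureCache)) assign(key, builder(), .fixtureCache)
  get(key, .fixtureCache)
}

# interior seed grid for the standard phantom geometry (emulates a user
# placing seeds across the organ; spacing ~ the bias wavelength/2)
phantomSeedGrid <- function(truth) {
  pos <- as.matrix(expand.grid(s = c(9, 12, 15), r = seq(34, 62, by = 14),
                               c = seq(26, 62, by = 18)))
  keep <- apply(pos, 1, function(p)
    all(truth[p[1], (p[2] - 5):(p[2] + 5), (p[3] - 5):(p[3] + 5)] == 1L))
  unname(pos[keep, , drop = FALSE])
}

segmentPhantom <- function(spec) {
  ph <- generatePhantomCt(spec)
  seeds <- phantomSeedGrid(labelArray(ph$truth))
  res <- runSegmentation(ph$volume, seeds, mesh = FALSE)
  c(ph, list(seeds = seeds, res = res))
}

noiseFreeRun <- function() memo("noiseFree", function()
  segmentPhantom(phantomSpec(noiseSd = 0, biasAmplitude = 0, neckWidth = 0)))

noisyRun <- function() memo("noisy", function()
  segmentPhantom(phantomSpec(noiseSd = 12, neckWidth = 0, seed = 8)))

organRun <- function() memo("organ", function()
  segmentPhantom(phantomSpec(seed = 3)))

biasedPhantom <- function() memo("biasedPhantom", function() {
  ph <- generatePhantomCt(phantomSpec(neckWidth = 0, seed = 7))
  seeds <- phantomSeedGrid(labelArray(ph$truth))
  feats <- computeLocalFeatures(ph$volume, 9)
  model <- fitSeedModels(feats, seeds, 9)
  p0 <- liverProbability(feats, model)
  c(ph, list(seeds = seeds, feats = feats, model = model, p0 = p0))
})

voePct <- function(seg, truth) {
  overlapMetrics(seg, truth)["voe"]
}

# mesh-pair fixtures (subdivision 3: 642 vertices, fast to parameterize)
identicalPair <- function() memo("identicalPair", function()
  generateLiverMeshPair(meshPairSpec(subdivision = 3, rotationS2 = 0,
                                     seed = 2)))

asymmetricPair <- function() memo("asymmetricPair", function()
  generateLiverMeshPair(meshPairSpec(subdivision = 3,
                                     deformAmplitude = c(0.12, 0.10),
                                     scaleRatio = 1.1, asymmetry = 0.25,
                                     seed = 5)))

asymmetricMaps <- function() memo("asymmetricMaps", function() {
  pr <- asymmetricPair()
  map2 <- sphericalParameterize(pr$S2$mesh)
  targets <- spherePositions(map2)[pr$S2$landmarks, ]
  list(pair = pr, map2 = map2, targets = targets)
})

# transfer all paths from S2 to S1 under a landmark subset; returns the mean
# Hausdorff error per path label
transferErrors <- function(lmSel, gamma = 100) {
  am <- asymmetricMaps()
  pr <- am$pair
  m1 <- sphericalParameterize(pr$S1$mesh,
                              landmarks = pr$S1$landmarks[lmSel],
                              targetPositions = am$targets[lmSel, ,
                                                           drop = FALSE],
                              gamma = gamma)
  errs <- vapply(seq_along(pr$S2$paths), function(i) {
    tp <- transferResection(pr$S2$paths[[i]], m1, am$map2)
    hausdorffStats(tp, pr$S1$paths[[i]])[["mean"]]
  }, numeric(1))
  names(errs) <- vapply(pr$S2$paths, pathLabel, character(1))
  errs
}

digitalBall <- function(radius = 10, pad = 3) {
  n <- 2 * (radius + pad)
  ctr <- n / 2 + 0.5
  arr <- array(0L, c(n, n, n))
  for (s in seq_len(n)) {
    d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`) +
      (s - ctr)^2
    arr[s, , ] <- as.integer(d2 <= radius^2)
  }
  labelVolume(arr)
}
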