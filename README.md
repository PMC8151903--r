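# hepaseg

Semi-automatic liver segmentation from 3D CT and cross-subject transfer of
hepatectomy resection paths, in R.

Accurately extracting the liver from CT is hard because neighbouring
abdominal organs share its X-ray attenuation, boundaries are fuzzy, and
anatomy varies widely across patients. This package implements a seeded,
model-free pipeline for that problem, plus the geometric machinery to map
one patient's surgical resection paths onto another patient's liver — the
planning step for procedures such as living-donor transplantation — with
synthetic phantoms and mesh fixtures that make every stage testable
without any external dataset.

## The method

**Segmentation.** Each voxel `q` carries local statistics
`F_q = (mu_q, sigma_q)` over an in-plane `N x N` window (`N = 9`). For each
user seed `p`, a bivariate Gaussian `(Fbar, Sigma)` is fitted to the
features of the `(2N-1) x (2N-1)` patch around `p`; densities are fused
across seeds by the maximum and calibrated to `[0, 1]`. The map is refined
by five iterations of multi-slice relaxation labeling with 26-neighbour
inverse-distance weights `[(dx)^2 + (dy)^2 + D^2 (ds)^2]^(-1/2)` (D = slice
distance), and segmented by an exact minimum s-t cut of

    E(L) = alpha * sum_p R(l_p)
         + (1 - alpha) * sum_{p,q} B(p,q) [l_p != l_q],

with region term `R(liver) = 1 - Pr(p)` and a boundary term modulated by a
structure-tensor anisotropy measure `g`:

    B(p,q) = exp(-max(g(p), g(q)) |I(p) - I(q)|^2 / (2 delta^2)) / ||p-q||.

Extracted slice contours are cleaned by bottleneck decomposition
(`epsilon = chord / min(arc, arc') < 0.6`, outer-angle candidate filter,
60-px separation) and an interslice overlap constraint
`T_s = 0.8 - 0.05 (D - 1)`, then triangulated into a watertight genus-0
surface and evaluated with the SLIVER07 metric suite (VOE, RVD, ASD, RMSD,
MSD; score `max(100 - 25 e / e_ref, 0)`).

**Correspondence.** Both liver surfaces are conformally parameterized onto
the unit sphere (spherical harmonic heat flow with Gauss-map
initialization, landmark-penalized harmonic solve
`E(f1) = sum k_uv ||f1(u) - f1(v)||^2 + gamma sum ||f1(p_i) - f2(q_i)||^2`
with cotangent weights, Beltrami-coefficient correction to keep the map
bijective). The correspondence `g = f2^-1 o f1` transports labelled
resection polylines (LHV/MHV/RHV along the hepatic veins, LPV/RPV along
the portal veins) between the surfaces; transfer quality is reported as
symmetric Hausdorff statistics.

## Worked example

Segment the built-in CT phantom (liver + similar-intensity neighbour organ
joined by a neck) and evaluate against its ground truth:

```r
library(hepaseg)
ph <- generatePhantomCt(phantomSpec(seed = 3))
# a grid of interior seed picks, emulating the user seeding across the organ
pos <- as.matrix(expand.grid(s = c(9, 12, 15), r = seq(34, 62, by = 14),
                             c = seq(26, 62, by = 18)))
inside <- apply(pos, 1, function(p)
  all(labelArray(ph$truth)[p[1], (p[2] - 5):(p[2] + 5),
                           (p[3] - 5):(p[3] + 5)] == 1L))
seeds <- pos[inside, ]
res <- runSegmentation(ph$volume, seeds, reference = ph$truth)
round(res$report$metrics, 3)
```

This prints

      voe   rvd   asd  rmsd   msd
    1.230 0.085 0.028 0.155 1.820

i.e. 1.23 % volumetric overlap error against truth, a signed volume
difference of +0.085 %, and sub-voxel average surface distance (mm) — the
graph cut initially *includes* the neighbouring organ (its density is 2 HU
from the liver's), and the bottleneck + interslice stages remove it
entirely. `res$mesh` is the reconstructed surface:

    TriangleMesh: 31622 vertices, 63240 faces, Euler characteristic 2

Transfer resection paths between two generated liver-like surfaces whose
right hemi-livers genuinely differ:

```r
pr <- generateLiverMeshPair(meshPairSpec(subdivision = 3,
                                         deformAmplitude = c(0.12, 0.10),
                                         scaleRatio = 1.1,
                                         asymmetry = 0.25, seed = 5))
out <- runCorrespondence(pr$S1$mesh, pr$S1$landmarks,
                         pr$S2$mesh, pr$S2$landmarks,
                         pathsS2 = pr$S2$paths, pathsS1 = pr$S1$paths)
print(out$hausdorff, digits = 3)
```

         path   Max     Min  Mean   RMS
    1     LHV 0.582 0.00471 0.214 0.266
    2     MHV 0.469 0.00509 0.206 0.243
    3     RHV 3.711 0.41632 1.119 1.307
    4     LPV 0.520 0.09315 0.415 0.431
    5     RPV 2.733 0.02654 1.576 1.790
    6 Average 1.603 0.10916 0.706 0.807

All distances in mm on ~100 mm meshes: the left-system paths (LHV, LPV)
transfer an order of magnitude more accurately than the right-system paths
crossing the artificially decorrelated right hemi-liver. Restricting the
landmarks to the left system (labels 1, 2, 3, 4, 10) further reduces the
LHV/LPV errors — the localized-constraint behaviour the method is designed
to exploit.

A thin command-line front end over the same functions lives in
`inst/cli/hepaseg.R` (`synth-ct`, `synth-mesh`, `segment`, `postprocess`,
`reconstruct`, `parameterize`, `register`, `evaluate`).

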