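# foci3d

Automated 3D detection and quantification of γH2AX DNA-repair foci in
confocal fluorescence z-stacks, with kinetics modelling of DSB repair.

DNA double-strand breaks (DSBs) recruit phosphorylated histone H2AX
(γH2AX), which forms micrometre-sized nuclear foci that immunofluorescence
makes countable. Most free foci counters are 2D and only see the nuclear
midsection. `foci3d` implements a fully 3D pipeline for radiation
biologists and microscopists:

* **Stain-free nucleus recognition** by *gradual signal separation*: a
  windowed mean auto-local threshold (ALT) of the dim nuclear
  autofluorescence, Gaussian smoothing, mid-gray ALT, basal-cutoff
  z-projection, tolerance watershed and particle filtering — no DNA
  counterstain needed.
* **3D focus segmentation**: slice-wise median ALT over a disc of radius
  `2 × focus diameter` in pixels, 26-connected component labeling,
  two-sided size exclusion, and an optional seeded 3D watershed on the
  anisotropic distance transform to split touching foci (seeds are 3D
  intensity maxima filtered by prominence). Per focus it reports voxel
  count, volume (µm³), surface area (µm²), centroid and intensities; per
  nucleus the 3D count `fn3d` and optionally the 2D midsection count
  `fn2d`.
* **Repair kinetics**: the modified Mariotti induction–decay model
  `N(t) = A²(1 − e^(−t/τ₁)) e^(−t/τ₂) + R` with bounded multi-start
  least-squares fitting and the analytic peak time
  `t* = τ₁ ln(1 + τ₂/τ₁)`.
* **Agreement statistics** for method comparison: Pearson r, Lin's
  concordance ρ_c, linear / linear-quadratic regression, relative
  differences.
* **A ground-truthed synthetic scene generator** (nuclei, foci,
  photobleaching, glass-surface artifacts) so the entire pipeline is
  verifiable without any external data.

All thresholding uses the rule *object iff `p > S − c`* with `S` the mean,
mid-gray or median of the disc of radius `r` around the pixel, computed
exactly (border-clipped, no padding) and verified bit-identical against a
brute-force reference.

## Worked example

```r
library(foci3d)

# a synthetic stack: one nucleus, 50 well-separated foci, 224x224x60 voxels
sc <- renderScene(fociFieldScene(50, seed = 42))
sc$stack
#> ImageStack: 224 x 224 px, 60 slices (16-bit source, 1 channel)
#>   intensity range [600, 1.63e+04]
#> Calibration: 0.1 x 0.1 x 0.25 um/voxel; nucleus ~16 um, focus ~1.5 um

res <- analyzeStack(sc$stack, mode = "both")
nucleusROIs(res$nuclei)
#>   label areaUm2  xUm  yUm circularity touchesEdge
#> 1     1  192.76 11.2 11.2   0.9148657       FALSE
fociCounts(res$foci)
#>   nucleusLabel fn3d fn2d
#> 1            1   50    5
head(fociTable(res$foci), 3)
#>   focusId nucleusLabel voxelCount volumeUm3 surfaceUm2   xUm ...
```

The nucleus is recovered at its true centroid (11.2, 11.2) µm with
circularity 0.91; all 50 rendered foci are found (`fn3d == 50`), of which
5 intersect the midsection slice ~3 µm above the glass (`fn2d`). Per-focus
rows carry the calibrated measurements.

Fitting a repair time course (minutes, mean foci/nucleus):

```r
tt <- c(0, 2, 5, 10, 20, 45, 90, 180, 360, 720, 1440)
d  <- simulateKinetics(tt, A = 6, tau1 = 2.8, tau2 = 125, R = 15)
fitMariotti(d$time, d$count)
#> Induction-decay (Mariotti) model fit
#>   A = 6  tau1 = 2.8 min  tau2 = 125 min  R = 15 foci
#>   peak time t* = 10.7 min;  RSS = 0;  converged: TRUE (n = 11)
```

A time constant pair (τ₁ = 2.8 min, τ₂ = 125 min) peaks at
`mariottiPeakTime(2.8, 125)` ≈ 10.7 min; a slower-repairing line
(τ₁ = 8.4, τ₂ = 326) peaks at ≈ 30.9 min.

Batch processing of directories of TIFF stacks, kinetics fits, agreement
reports and scene export are available as functions (`runBatch`,
`runKinetics`, `agreementReport`, `writeStack`) and through the thin CLI at
`inst/scripts/foci3d` (subcommands `detect`, `kinetics`, `agree`,
`simulate`).

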