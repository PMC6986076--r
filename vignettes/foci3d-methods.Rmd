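---
title: "Counting DNA repair foci in 3D: methods and design notes"
author: "foci3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting DNA repair foci in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foci3d)
```

## The problem

Ionizing radiation induces DNA double-strand breaks (DSBs). Within minutes,
histone H2AX around each break is phosphorylated to γH2AX, forming a
micrometre-sized nuclear focus that can be immunostained and imaged.
Counting γH2AX foci per nucleus is the standard readout of DSB induction
and repair. Conventional counters work on single 2D images and therefore
only see foci near one imaging plane; `foci3d` implements a fully 3D
pipeline for confocal z-stacks: stain-free nucleus recognition, 3D focus
segmentation with optional watershed splitting of touching foci, calibrated
per-focus measurements, and an induction–decay model for post-irradiation
time courses.

The pipeline operates on `ImageStack` objects: calibrated voxel grids
stored `[y, x, z]` with slice 1 at the glass surface. All physical
coordinates are voxel centres times the voxel size. Reference acquisition
geometry is 0.1 × 0.1 µm lateral and 0.25 µm axial voxels with roughly 60
slices per stack, i.e. the stack tightly brackets one cell layer.

## Per-slice normalization

Fluorophores bleach as a z-stack is acquired plane by plane, so later
slices are systematically dimmer. `normalizeSlicewise()` rescales every
slice independently so its observed minimum maps to 0 and its maximum to
255 (no percentile saturation), rounding half-up. Any per-slice
multiplicative intensity drift therefore cancels exactly, which is the
property the photobleaching tests verify. Two pinned details: a constant
slice maps to all zeros (avoiding a divide by zero and spurious objects),
and rounding is half-up so results are platform-independent.

## Auto-local thresholding (ALT)

All segmentation rests on one primitive: a pixel `p` is object iff
`p > S − c`, where `S` is the mean, mid-gray `(max+min)/2`, or median of
the grey values in the disc of radius `r` around the pixel, clipped at
image borders (no padding is invented). The offset `c` defaults to 0; the
comparison is strictly greater, so a perfectly flat region yields no
objects. The median of an even-sized window is the lower middle order
statistic. Internally each operator has an exact fast implementation
(prefix sums; monotonic-deque sliding extrema; a sliding histogram with a
running median pointer), and the test suite proves all three bit-identical
to a naive double-loop reference over a grid of radii and offsets.

## Stain-free nucleus recognition

Nuclei are found without a DNA stain, using only the dim unspecific
fluorescence of the nuclear area, by *gradual signal separation*:

1. mean ALT with radius `rNuc` on each normalized slice, turning the faint
   nuclear signal into a binary estimate;
2. Gaussian blur (`sigmaBlur`) of that estimate, which spreads nucleus,
   cytosol and exterior into distinct grey bands;
3. mid-gray ALT, keeping the brightest band — candidate nuclear voxels;
4. logical-OR z-projection over slices above the `basalCutoff`, excluding
   glass-surface artifacts from the footprint while leaving the projected
   area (dominated by the midsection) untouched;
5. a Euclidean-distance-transform watershed with minima-suppression
   `watershedTolerance` separating converging nuclei;
6. particle filtering by area, circularity and border contact.

Two derived defaults matter. The window radius is one expected nucleus
radius in pixels, `rNuc = round(0.5 · nucleusDiameter/dx)`: the disc must
span from inside a nucleus into the surrounding cytosol, otherwise the
local statistic cannot distinguish the two; this derivation is exposed as
an override. The blur sigma is 10% of the nucleus diameter in pixels. The
particle filter defaults are deliberately permissive — areas between 0.25×
and 4× the area of a disc of the stated nucleus diameter, circularity at
least 0.3 — because the sharpest exclusion rule is the edge rule: nuclei
touching the image border are partially imaged and always discarded. The
basal cutoff defaults to 0 because the artifact depth depends on the slide
tilt of each acquisition; test scenes set it to the rendered artifact
depth.

Circularity is `4π·area/perimeter²` with the perimeter measured as the
8-connected contour chain length (unit and √2 steps). Under this estimator
a digital disc of radius 20 px scores ≈ 0.91; the estimator is pinned
because circularity values are meaningless without naming one.

## 3D focus segmentation

Foci are bright, roughly 0.5–1 µm puncta. The median ALT with radius
`rFoci = round(2 · fociDiameter/dx)` (30 px at the reference calibration,
with `fociDiameter` the *effective* focus extent of 1.5 µm including the
dim halo) marks voxels brighter than the robust local background; the
26-connected components of this mask are candidate foci. An optional
Gaussian pre-blur exists for noisy acquisitions but defaults to off —
additional blurring is usually unnecessary and slightly erodes faint foci.

Components are filtered by size on both sides. The minimum
(`minFocusVoxels`, default: volume of a sphere a quarter of the effective
focus diameter wide, at least 2 voxels) suppresses speckle. The maximum
(`maxFocusVoxels`, default: sphere of twice the effective diameter)
discards objects far larger than any plausible focus; such objects are
threshold artifacts, most prominently the thin object shell that the
median ALT produces just inside every nucleus boundary (boundary pixels of
a convex region see half their window in the dark background, so their
local median collapses; the resulting shell is one giant connected
component). Size exclusion on both ends mirrors how practitioners
configure 3D object counting.

Each retained focus is measured on the normalized stack: voxel count,
volume (`voxels × dx·dy·dz`), surface area by exposed-face counting with
anisotropic face areas, centroid in µm, mean and maximum intensity.
Intensities are reported on the normalized 8-bit scale, since that is the
scale all detection operates on; raw-intensity quantification is
deliberately not offered. A focus belongs to the nucleus whose 2D
footprint contains its (x, y) centroid; foci outside every footprint are
not reported.

### Splitting touching foci

At high foci densities adjacent foci fuse into one component. When
`use3dws` is on, seeds are found as 26-neighbourhood intensity maxima of
the normalized stack whose prominence (height above the saddle towards a
higher maximum) exceeds `maximaTolerance` (default 10 grey levels);
plateaus contribute one seed at their centroid. Components holding two or
more seeds are split by priority-flooding the anisotropic Euclidean
distance transform from the seeds; components with one or zero seeds are
kept whole — a focus whose maximum fell below the seed tolerance must
still count once. Seeds landing outside the foreground are dropped with a
warning. Flood ties are broken by distance, then raster order, then
insertion order, so label maps are reproducible.

### The 2D midsection mode

For comparison with 2D counters the same machinery runs on a single slice:
median ALT, 8-connected labeling, optional seeded splitting, per-nucleus
assignment, with 2D analogues of both size bounds. The default midsection
is the slice whose centre lies nearest 3 µm above the glass
(`midsectionSlice(dz)`; slice 13, i.e. 0-based index 12, at dz = 0.25 µm).
Because the midsection foci are a subset of the volume foci, `fn3d ≥ fn2d`
on every scene where both are computed, and the tests assert exactly that.

## The induction–decay kinetics model

Mean foci counts after irradiation follow the modified Mariotti model

$$N(t) = A^2\,(1 - e^{-t/\tau_1})\,e^{-t/\tau_2} + R,$$

with induction time constant τ₁ (min), decay constant τ₂ (min), amplitude
A (the peak-scale excess is A²) and background R, the foci count
pre-existing in unirradiated cells; mock-irradiated controls enter at
t = 0, where N(0) = R. The unique stationary point is

$$t^\* = \tau_1 \log(1 + \tau_2/\tau_1),$$

independent of A and R — the package cross-checks this closed form against
a numeric grid argmax. `fitMariotti()` performs bounded least squares
(all parameters ≥ 0, weights 1/se² when standard errors are given) via
Levenberg–Marquardt with a data-driven start (R from the t = 0 count, A
from the excess at the maximum, τ₁ a third of the peak time, τ₂ ten times
τ₁) plus four fixed rescaled restarts; the lowest residual sum of squares
wins. A degenerate candidate with A = 0 and R the weighted mean is always
evaluated too: it is the exact bounded optimum for flat series, where
gradient-based fitting is singular. The fit is parameterized in A, exactly
as the model is written, with the sign ambiguity removed by the A ≥ 0
bound. Times are minutes throughout.

Simulation-based tests show noiseless series are recovered to well under
1% and, at 5% Gaussian noise over 100 replicates, the median relative
error of both time constants stays within 15%.

## Agreement statistics

For method comparison the package reports the Pearson correlation, Lin's
concordance correlation coefficient

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$

with population (1/n) moments — pinned so the worked examples are exact —
ordinary least-squares regression of degree 1 (slope ± SE) or 2 (the
linear-quadratic shape seen when one method undercounts dense nuclei), and
the relative difference `(FN − FN_ref)/FN_ref × 100%`. ρ_c penalizes both
scatter and systematic offset, so |ρ_c| ≤ |r| always; regression is
directional (automated counts on the ordinate). No p-values are attached
to these descriptive statistics.

## The synthetic verification substrate

No reference image data are deposited for this kind of pipeline, so the
package carries its own ground-truthed generator. A `SceneSpec` renders:
ellipsoidal nuclei of constant dim interior (3000 a.u. over a 600 a.u.
background, 16-bit), isotropic-in-µm Gaussian foci truncated at 4σ
(σ = 0.2 µm, FWHM 0.47 µm, at the lower edge of the reported 0.5–1 µm
focus diameters; peak amplitude 13 000 a.u.), a per-slice multiplicative
decay factor emulating photobleaching, an optional bright basal artifact
layer (fixed smooth bumps on the lowest slices, mimicking glass-surface
imperfections), and Gaussian read noise. Rendering is additive (permuting
the foci list changes nothing) and deterministic per seed. Nuclei are
rendered with an axial semi-axis (9.5 µm) exceeding the stack half-depth:
the 15 µm stack brackets the central dome of the nucleus, as in
acquisitions that allot ~60 slices to one nucleus, so no slice contains a
vanishingly small cross-section.

Three generator choices deserve emphasis because they were forced by
observed behaviour of the algorithm itself, not by convenience:

* **Noise defaults to zero.** Per-slice min–max normalization anchors the
  brightest structure of each slice at grey level 255. In slices without a
  focus that structure is the flat nucleus interior; whenever its rescaled
  level lands near a half-integer, *any* sub-quantization noise splits the
  interior across two adjacent grey levels and the strict `p > median`
  comparison turns a sizeable fraction of interior voxels into false
  objects — in 3D these percolate into large spurious components. There is
  no positive noise level free of this knife edge. With exactly zero
  noise every flat region quantizes to a single level and the chain is
  exactly clean. The tests therefore characterize geometric and
  algorithmic correctness, not photon-noise robustness; on real, noisy
  data the same mechanism inflates automated 3D counts, consistent with
  automated-vs-manual discrepancies reported for such pipelines. The
  `noiseSd` parameter remains first-class for studying exactly this
  failure mode.
* **Interior texture defaults to zero** for the same reason: a smooth
  staining texture shifts the local median near the nuclear boundary and
  reads out as thick spurious rings. The `textureAmp` parameter is kept so
  the effect can be reproduced.
* **Scene samplers keep focus centres ≥ 1.5 µm inside the nuclear
  envelope** (biologically, foci live in interior chromatin): the
  nucleus-boundary shell described above absorbs any focus rendered
  within reach of it.

The decay factor is applied to the fully formed slice (signal plus noise,
before quantization), i.e. as acquisition-gain drift; only under that
model is detection exactly invariant to bleaching via per-slice
normalization, which is the property being tested.

Standard presets cover the regimes of interest: empty field, one nucleus,
two overlapping nuclei (centre distance 0.8 diameters), an edge-clipped
nucleus, sparse foci (≤ 15 per nucleus, the unirradiated background
level), dense foci (200 per nucleus, the upper range the method is
expected to resolve), fused focus pairs, a basal-artifact scene and a
photobleached scene. Count-recovery scenes place n ∈ {0, 10, 50, 100} foci
with pairwise centre distances above 2 µm (more than 3 focus FWHMs, and
far enough that the +1-grey-level visible extents of two foci cannot touch
even in strongly amplified dim slices). Fused-pair scenes put the two
members 1.2 FWHM apart and add 48 companion singleton foci laddered across
z: dense bright signal in every slice is precisely the regime in which a
3D watershed is worth its cost, and without it the per-slice rescaling
lifts the inter-summit saddle of a pair to the top grey level, erasing the
prominence the seed finder needs.

## Problem sizes and performance

Full-scale test scenes are 224 × 224 × 60 voxels (two-nucleus scenes
224 × 352 × 60) at the reference calibration; one complete analysis takes
a few seconds, dominated by the large-radius ALT passes. The acceptance
suite runs 20 replicates per foci count n ∈ {0, 10, 50, 100} and requires
exact recovery in at least 95% of replicates per n (exact at n = 0), plus
the watershed split rate, bleach invariance, edge/basal rules and kinetics
recovery described above.

## Known limitations

* Noise and texture robustness: see above; the strict-inequality ALT on
  per-slice-normalized data is exactly clean only in the high-SNR regime.
  For noisy material the pre-blur option (and a negative `c`) helps, at
  the cost of faint-focus sensitivity.
* Intensities are reported on the normalized scale; absolute photometry is
  out of scope.
* Nucleus assignment uses the 2D footprint, so foci of vertically
  overlapping nuclei (rare in monolayers) cannot be distinguished.
* Only TIFF and PNG containers are read; vendor formats should be
  converted upstream.
* Cell types with very low unspecific nuclear staining defeat stain-free
  recognition; pointing `channel` at a DNA-stain channel is the supported
  workaround.
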