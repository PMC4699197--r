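---
title: "Graph-based retinal layer segmentation and enface mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based retinal layer segmentation and enface mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`octlayers` implements a semi-automated pipeline for quantifying retinal
layers in high-density spectral-domain optical coherence tomography (SDOCT)
macular raster volumes:

1. **Segmentation** of five cell-layer interfaces per B-scan — vitreous/ILM,
   INL/OPL, ONL/ISe, ISe/RPE, RPE/choroid — by a minimum-weight path search
   on gradient-derived graph weights, executed in a fixed anatomical order
   with search-region restriction, plus band-restricted manual correction.
2. **Enface products**: thickness maps and vertically averaged reflectance
   images of the total retina (TR), inner retina (IR), outer retina (OR)
   and the inner segment ellipsoid band (ISe), one enface row per B-scan.
3. **Normative statistics**: per-pixel mean/SD/limit atlases from control
   cohorts and tri-level deviation maps (below / within / above the normal
   range) for patient maps.
4. A seeded **synthetic phantom** generator with exported ground truth and
   diabetic-retinopathy-style lesion injectors, which stands in for patient
   data in every test.

The default scan geometry is a Spectralis-like protocol: 145 horizontal
B-scans of 768 A-scans over a 15°×15° field centred on the fovea, 3.9 µm
axial sampling, ~31 µm B-scan spacing, 9 frames averaged per location.

# The boundary model

## Graph, weights and path search

Each B-scan is a graph whose nodes are pixels and whose edges join nodes in
laterally adjacent columns. A layer interface is modelled as a
*column-monotone path*: exactly one row per A-scan column, with the row
change between adjacent columns bounded by `max_step` (default 5 px). This
guarantees a single-valued boundary function per column, keeps the search
exactly solvable by dynamic programming, and makes a brute-force
enumeration oracle tractable for testing.

Weights come from the signed vertical intensity gradient. After optional
Gaussian pre-smoothing (`smooth_sigma`, default 1 px, for speckle
suppression) the central-difference derivative along depth is rectified
for the requested polarity — positive gradients for dark-to-bright
interfaces, negated negative gradients for bright-to-dark — and rescaled
by its per-B-scan maximum to `g ∈ [0, 1]`. The edge between nodes with
normalized gradients `g_a`, `g_b` has weight

$$ w = 2 - (g_a + g_b) + w_{\min}, $$

strictly positive and strictly decreasing in the gradient sum, so the
minimum-total-weight path clings to the strongest transition of the chosen
polarity. `w_min = 1e-5` keeps all weights positive so that degenerate
(zero-gradient) instances still have well-defined shortest paths.
Endpoints are free: virtual zero-weight start/end nodes attach to every
allowed row of the first and last columns, so the path is not forced
through any particular corner.

Ties are broken deterministically — smallest total row sum, then the
topmost row at the first differing column (the lexicographically smallest
row sequence) — so repeated runs and regression tests are bit-stable even
on pathological constant images.

## The ordered five-interface protocol

A single shortest path finds only the globally strongest transition, so
the five interfaces are extracted in a fixed order, each search restricted
relative to the paths already found:

1. **Vitreous/ILM** (dark→bright) over the whole image: the vitreous is
   nearly signal-free above the bright inner retinal surface, making this
   the strongest positive transition.
2. **ONL/ISe** (dark→bright), restricted to rows below the vitreous/ILM
   path: the hypo-reflective ONL sits above the hyper-reflective ISe band.
3. **RPE/choroid** (bright→dark), restricted below the ONL/ISe path.
4. **INL/OPL** (dark→bright), restricted between the vitreous/ILM and
   ONL/ISe paths.
5. **ISe/RPE**, restricted between the ONL/ISe and RPE/choroid paths.

Each restriction is offset by `exclude_margin` pixels so a search cannot
re-detect the transition just found. The construction guarantees the
anatomical depth ordering per column, which `validate_boundary_set()`
checks explicitly and every downstream product relies on.

Design choices worth stating:

* **ISe/RPE polarity.** Not stated anywhere authoritative; this package
  uses bright→dark, because the hyper-reflective ISe band ends above the
  darker interdigitation zone that separates it from the RPE. It is the
  only negative transition between the ONL/ISe and RPE/choroid paths, so
  the restricted search is well-posed.
* **Exclusion margin.** A single margin (default 3 px) is used for both
  "below" and "between" restrictions. A 1 px margin would leave the flank
  of the just-found interface's own gradient ridge inside the next search
  region (a Gaussian-blurred step retains roughly 40% of its peak gradient
  one pixel away), which can capture the INL/OPL search on the ILM tail;
  3 px suppresses the tail while costing only ~12 µm of search depth.
* **Degenerate "between" regions.** Where the inset bounds cross (bands
  thinner than twice the margin, e.g. a shallow fovea), the region
  collapses to the single midpoint row: feasibility and ordering are both
  preserved, at the cost of locally pinning the path — exactly the
  situation the manual-correction workflow exists for.
* **Integer paths.** The automated search returns integer rows (the graph
  is pixel-level); boundary containers store doubles so corrected or
  synthetic boundaries may carry sub-pixel values.
* **Indexing.** All rows/columns are 1-based (R convention), row 1 on the
  vitreous side; every on-disk artifact states this in its sidecar.

## Manual correction

Automated paths fail around irregular pathology (cystoid fluid, exudates).
The correction operator takes a drawn polyline, interpolates it to every
column it spans, restricts the search to a band of
`± correction_halfwidth` pixels (default 5) around the rounded drawn line,
re-solves the path inside that band, and splices the revised segment into
the boundary. Columns outside the polyline's x-range are never touched;
`correction_halfwidth = 0` forces the path onto the rounded drawn line
itself. Corrections enter as data (CSV/JSON vertex tables) — there is no
interactive UI in this package.

# Enface products

Thickness at each (B-scan, A-scan) position is the interface separation
converted to micrometres, `(lower − upper) × axial_um_per_px`, using
boundary rows at full (possibly sub-pixel) precision. The layer table is
fixed: TR = vitreous/ILM→RPE/choroid, IR = vitreous/ILM→INL/OPL,
OR = INL/OPL→RPE/choroid, ISe = ONL/ISe→ISe/RPE. Because IR and OR share
the INL/OPL interface, TR = IR + OR holds identically (to floating-point
roundoff) — a structural invariant the tests assert.

Reflectance is the vertical mean of the normalized intensity across the
layer's rounded row band, half-open `[round(upper), round(lower))` so the
shared interface row is never counted twice by IR and OR; a degenerate
band falls back to the single pixel at the upper row. Averaging is done on
linear normalized intensity, not log/dB: the source intensities arrive
already display-mapped from the scanner, their native dynamic range is
unknown, and a linear mean keeps the maps' linearity in the input (tested:
rescaling the volume rescales reflectance maps by the same factor and
leaves thickness maps untouched).

Validity masks propagate: a pixel invalid in any contributing boundary is
invalid (NA) in every derived map. No cross-B-scan smoothing is applied to
boundaries before mapping — each B-scan is segmented independently, and
smoothing would blur exactly the focal pathology these maps exist to show.

# Normative atlases and deviation maps

`build_atlas()` computes, per enface pixel across control subjects, the
mean, sample SD (n−1), and limits `mean ± z·SD` with `z` the two-sided
standard-normal quantile of the coverage (1.960 at 0.95). The "95% CI" is
deliberately read as the **population normal range** of individual
subjects, not the confidence interval of the cohort mean: deviation maps
classify an individual patient's pixel, which requires an interval that
contains a healthy individual's value with the nominal probability. The
mean-CI reading (`mean ± z·SD/√n`) is available via
`build_atlas(..., limits = "mean_ci")` for cohort-level comparisons. With
small control cohorts a z-quantile population range under-covers slightly
(a tolerance-interval t/chi-square construction would be wider); the
Monte-Carlo coverage checks therefore use large simulated cohorts, where
the distinction vanishes.

Classification is per pixel: `below` if under the lower limit, `above` if
over the upper, `within` otherwise, with boundary values inclusive
(within); pixels invalid in patient or atlas are `invalid`. The fixed
rendering palette is blue/green/red for below/within/above and gray for
invalid. Maps are assumed fovea-centred on a common grid (the acquisition
protocol centres scans on the fovea); no spatial registration between
subjects is performed, matching the upstream acquisition assumption, and
no multiple-testing control is applied across pixels.

# The synthetic phantom

The generator renders each A-scan as piecewise-constant band
reflectivities at smooth interface surfaces, applies an axial Gaussian
blur (1 px scale) for realistic transition profiles, and multiplies by
unit-mean gamma speckle. All randomness comes from the seed recorded in
the spec; identical specs give bit-identical volumes. The exact surfaces
are exported as the ground-truth boundary set.

What it emulates, and the values chosen:

* **Geometry**: ~340 µm total retina (IR 117, INL/OPL→ONL/ISe 156,
  ISe 35, RPE 31 µm), a 78 µm foveal depression carried by the ILM, a
  slight (4 µm) central INL/OPL rise, and an 8 µm central increase of the
  ONL/ISe→ISe/RPE separation. This reproduces the qualitative normal
  maps: TR foveal depression, IR thinning, OR/ISe central thickening. The
  pit is an anisotropic 2-D Gaussian (σ = 500 µm), isotropic in retinal
  micrometres given the ~31 µm B-scan vs ~5.6 µm A-scan pitch.
* **Contrast structure**: dark vitreous (0.02) under a flat bright RNFL
  cap (0.80) — making vitreous/ILM the strongest dark→bright step, as in
  real scans — an inner retina ramping down to a dark INL (0.25), a thin
  bright OPL strip (0.65), dark ONL (0.20), bright ISe (0.82), an
  interdigitation dip (0.45), the brightest RPE (0.92) whose lower edge is
  the strongest bright→dark step, and a medium choroid (0.35). These
  relations are what make each protocol step discriminative; they mirror
  real SDOCT anatomy and were fixed at design time. An early variant
  without the RNFL cap let the descending inner-retina ramp erode the ILM
  gradient until the ONL/ISe ridge out-competed it — the cap, not a tuned
  threshold, is the fix, and it is also the anatomically correct picture.
* **Speckle**: multiplicative unit-mean gamma noise with relative SD 0.25
  (shape 16), approximating the residual speckle after 9-frame averaging.
  This is a statistical stand-in, not a physical speckle model: no
  spatial correlation, no depth-dependent attenuation, no instrument PSF.
  A green recovery test therefore establishes robustness to uncorrelated
  multiplicative noise at a realistic magnitude, nothing more.
* **Pathologies** (all strictly local to a raised-cosine footprint, with
  the ground truth updated exactly): outer-retinal edema and cysts
  displace the ONL/ISe, ISe/RPE and RPE/choroid surfaces downward
  (TR/OR thicken, IR does not), cysts additionally inserting
  hypo-reflective fluid; hard exudates are hyper-reflective inner-retinal
  blobs that attenuate everything beneath (IR reflectance up, OR/ISe
  reflectance down); laser scars pull ISe/RPE toward ONL/ISe (ISe
  thinning) and darken the remaining band; vessel shadows attenuate
  columns below the INL/OPL surface; atrophy shifts the INL/OPL surface
  and everything below it upward (IR and TR thin).
* **Cohorts**: per-subject Gaussian perturbations of axial placement
  (SD 10 µm), IR/ONL/ISe band separations (6, 8, 2 µm) and pit depth
  (8 µm) — the order of normal between-subject macular variability. The
  cohort seed drives only the parameter draws; rendering reuses the
  template seed, so zero variability yields bit-identical subjects (a
  determinism contract the tests rely on). Between-subject offsets are
  common across the map, so a 10-subject per-pixel sample SD carries ~24%
  relative noise — the SD-recovery test averages over independent cohorts
  accordingly.

Limitations worth keeping in mind: layers are laterally homogeneous apart
from the foveal terms and injected lesions (no vasculature unless
injected, no tilt or curvature, no motion artifacts), and the speckle is
uncorrelated. Green tests on the phantom validate the algorithmic
machinery, not clinical performance on scanner data.

# Numerical choices

* Path costs are compared exactly in the solver; identical-weight ties
  resolve by the documented deterministic rule. The enumeration oracle in
  the tests compares costs at 1e-9 (different summation orders).
* The TR = IR + OR identity is exact up to one ulp (two subtraction
  orders of the same three rows); tests assert a 1e-9 µm bound.
* The Gaussian smoothing kernel is truncated at 4σ and renormalized;
  image borders use reflection padding. Band centres of the phantom are
  exactly flat only where the band is wider than the kernel support —
  thin strips (OPL, interdigitation, RPE) only approach their nominal
  reflectivity, and the tests assert them with correspondingly looser
  tolerances.
* 8/16-bit volumes are normalized to [0, 1] by the type maximum on read;
  writers quantize by the same scale, so write→read round-trips are
  lossless on the quantized grid.
* Per-B-scan segmentation failures mark that B-scan invalid in the
  boundary set (with a warning) instead of aborting a 145-B-scan volume.

# Interfaces and formats

Everything on disk is a documented open format: volumes as multi-page
grayscale TIFF (uncompressed baseline, written/read by a built-in minimal
codec, since no TIFF-capable R package is available in the target
environment) or raw little-endian samples, both with a JSON sidecar
stating shape, sample type, axis order and scan metadata; boundary tables
as long-format CSV (`bscan, ascan, interface, row`) or JSON; enface maps
as float32 TIFF and CSV with JSON sidecars; atlases as directories of four
float32 TIFFs plus JSON; deviation maps as plain-text PPM (fixed palette)
plus integer-label CSV; run configuration as JSON (unknown keys rejected);
and a manifest with per-file MD5 checksums so a run is reproducible from
its recorded config and seed. The CLI
(`system.file("cli", "octlayers.R", package = "octlayers")`) chains the
pipeline from a shell: `simulate`, `segment`, `correct`, `enface`,
`atlas`, `deviate`.

```{r example}
library(octlayers)

# simulate a small phantom, segment it, map it, and check the recovery
ph <- generate_phantom(phantom_spec(meta = scan_metadata(
  n_bscans = 7, n_ascans = 96, n_depth = 160), speckle = 0.25, seed = 1))
bs <- segment_volume(ph$volume)
products <- all_enface_products(ph$volume, bs)
summary(products$thickness$TR)

atlas_maps <- lapply(phantom_cohort(10, ph$spec, seed = 2),
                     function(s) thickness_map(s$truth, "TR"))
atlas <- build_atlas(atlas_maps)
dev <- deviation_map(products$thickness$TR, atlas)
print(dev)
```
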