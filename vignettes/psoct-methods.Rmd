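---
title: "Depolarization-based RPE analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depolarization-based RPE analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoct)
```

## The measurement problem

Polarization-sensitive OCT measures, besides reflectivity, the polarization
state of back-scattered light as a Stokes vector (I, Q, U, V) per voxel. Most
retinal layers preserve the polarization state; the retinal pigment
epithelium (RPE), by virtue of its melanin, scrambles it. The degree of
polarization uniformity (DOPU) quantifies this: the per-pixel Stokes
components Q, U, V are normalized by I, each component is averaged over a
small rectangular window within the B-scan, and DOPU is the Euclidean norm
of the averaged vector. In polarization-preserving or birefringent tissue
the per-pixel states agree and DOPU is near 1; over a depolarizing layer the
states are dispersed on the Poincaré sphere and the average shrinks. Voxels
with DOPU strictly below 0.8 are classified as depolarizing RPE, giving a
tissue-specific segmentation that intensity-based OCT cannot provide.

Downstream of the segmentation, the package quantifies RPE atrophy the way
the clinical algorithm does: an evaluation band around the RPE/Bruch complex
restricts counting to the band (excluding depolarizing choroid), the number
of depolarizing pixels along each A-line forms an en-face thickness map of
depolarizing tissue, the map is binarized and smoothed, connected atrophic
patches are detected, and patch areas follow from the known en-face pixel
area. Patches of at least 0.1 mm² count as geographic atrophy (GA); smaller
components feed the focal-atrophy rule. Per-B-scan rules grade RPE porosity,
focal atrophy, thinning, accumulation of depolarizing material at the RPE
level, and ectopic depolarizing foci in the outer retina; per-eye scores are
0/1 ("any positive B-scan") per visit, and cohort statistics (prevalence,
paired t, Cohen's κ with CI, percent agreement, Spearman r) summarize them.

Because no raw clinical volumes are available, every stage is validated
against a synthetic phantom whose ground truth is known by construction.

## The phantom

`generate_phantom()` builds a layered eye: signal-free vitreous (I = 0),
polarization-preserving neurosensory retina (I = 1), a depolarizing RPE band
(I = 1.2, nominal thickness 5 px at the downscaled profile), and
polarization-preserving choroid (I = 0.8). All polarization-preserving
voxels share the state (Q,U,V)/I = (1,0,0). A depolarizing voxel's direction
is moved along the great circle from that common state towards an
independently drawn uniformly random direction, with interpolation weight
`depol_strength`; at weight 1 the direction is uniform on the sphere. This
is the simplest model in which windowed DOPU decreases monotonically with
the scrambling strength, which the test suite verifies.

Noise is additive Gaussian on Q, U, V (default SD 0.05 in intensity units),
after which the polarized magnitude is rescaled where it would exceed I, so
every voxel satisfies the physicality constraint sqrt(Q²+U²+V²) ≤ I. The
random direction field is drawn for every voxel and consumed only where
tissue depolarizes, so planting or removing a lesion never changes the
realization elsewhere — ground truth is exactly invariant to seed and noise
level, and band-exclusion invariants can be tested bitwise.

Deliberate simplifications: no speckle or point-spread modelling, no
birefringent nerve-fibre layer, no pigment-epithelial-detachment curvature,
and a signal-free vitreous instead of a realistic noise floor. Consequently,
passing tests demonstrate correctness of the analysis chain under the
stated model, not robustness to the raw-signal statistics of a real
instrument, which the source study does not characterize.

Planted lesions follow the clinical taxonomy: `ga_patch` and
`focal_atrophy` (circular RPE loss, analytic area πr²), `gap_series` (a row
of rectangular gaps with intact residuals — the anatomy of porosity),
`thinning` and `thickening` (band thickness scaled on a rectangle), and
`ectopic_focus` (a depolarizing cube offset axially from the band; positive
offsets place it in the choroid to exercise band exclusion).

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| DOPU threshold | 0.8 (strict `<`) | – | printed classification inequality |
| DOPU window (axial × lateral) | 3 × 5 | px | see below |
| intensity floor | background mean + 2 SD | a.u. | DOPU is meaningless at noise-level intensity; estimated from the top (vitreous) 10% of each B-scan |
| band margins (up/down) | 10 / 10 | px | covers the segmented band with headroom; running median over 31 A-lines |
| `atrophy_count_max` | 0 | px | atrophy is the absence of depolarizing RPE |
| smoothing | 3×3 median, closing+opening, disc r = 1 | px | minimal denoising; radius 0 disables |
| GA floor | 0.1 | mm² | minimal GA area detectable by the algorithm |
| porosity | ≥ 3 gaps, ≥ 2 residuals, ≥ 20% cumulative width | – | "series of gaps" operationalized; width per printed threshold |
| thinning | count < 0.5 × normal over ≥ 10% width (contiguous) | – | printed definition; zero counts are gaps, not thinning |
| accumulation | count ≥ 2 × normal over ≥ 5 A-lines | – | printed factor; run minimum suppresses single-pixel noise |
| ectopic foci | 26-connected, ≥ 5 px above band, ≥ 3 voxels | – | discontinuity from the RPE required |
| eligibility | CRT > 250 (strict) | µm | inclusion criterion |

**Why a 3 × 5 window rather than a large square window.** The segmented band
is the convolution of the true depolarizing layer with the evaluation
window: with per-pixel fully polarized states, a voxel classifies as
depolarizing as soon as roughly 20% of its window pixels are RPE. An axial
window comparable to the band thickness therefore dilates the measured band
by several pixels on each side. That dilation is fatal to the
thickness-*ratio* rules: with a 9-px axial window, a 5-px band measures
~11 px and no planted thinning can ever fall below half of it, nor can any
plausible thickening reach twice it. Keeping the axial extent below the
band thickness (3 px) preserves the ratios; the 5-px lateral extent is a
compromise between DOPU estimation variance and lateral erosion of atrophic
gaps (about 2 px per side). Both window sizes are configurable
(`pipeline_config(window_z_px =, window_x_px =)`).

**Window convolution and planted GA sizes.** The same convolution erodes a
measured atrophic patch by approximately the lateral half-window per side
(δ = 2 px ≈ 0.097 mm at the downscaled profile). The study's printed GA
areas are themselves outputs of the segmentation algorithm, so the
month-24 fixture plants anatomic discs whose *measured* area reproduces the
printed distribution, using the analytic inverse πR² − 4Rδ = A. The printed
area list ships separately (`ga_areas_month24.txt`). The same reasoning
sizes the porosity gap series: graders applied the 20%-width criterion to
segmented images, so gaps are planted wide enough (11 A-lines each) that
their segmented appearance spans the required width.

## Numerical and degenerate-case choices

* Stokes averaging is the unweighted mean of per-pixel intensity-normalized
  components. The alternative (intensity-weighted averaging) is defensible;
  unweighted was chosen because the normalization already removes intensity
  information and the classification acts on polarization geometry alone.
* Windows are truncated at B-scan edges — never padded. Zero-intensity
  pixels are excluded from the average; an all-zero window marks the voxel
  invalid (NA), and invalid voxels are never classified.
* Evaluation-band holes (A-lines without depolarizing pixels, e.g. inside
  atrophy) are filled by linear interpolation from flanking A-lines; a fully
  empty B-scan falls back to the volume-wide median centroid. Manual
  per-B-scan overrides, supplied as a YAML file, replace fitted bounds and
  make the "semi-automated" adjustment reproducible.
* Connected components use 8-connectivity en face and 26-connectivity in
  3-D (union-find); ties in lesion ordering are broken by the top-left-most
  pixel in scan order.
* Width thresholds ("at least 20% / 10%") are inclusive: with n A-lines the
  flip happens at ceiling(0.2 n). The thinning comparison is strict
  (< half), the accumulation comparison inclusive (≥ twice), matching the
  printed wording in each case.
* A gap is attributed to GA rather than focal atrophy when it overlaps a
  detected ≥-floor lesion footprint dilated by (3, 2) px; gaps whose en-face
  component is sub-threshold *or was removed by smoothing* are focal. This
  honours "not quantifiable as advanced GA" without making focal atrophy
  disappear whenever smoothing erases a tiny component.
* `paired_t` returns t = 0, p = 1 for identical inputs but refuses a
  constant non-zero difference (zero variance) instead of reporting an
  infinite statistic. Cohen's κ uses the large-sample Fleiss-type standard
  error with a normal 95% CI clipped to [−1, 1]; the all-agree
  single-category table returns κ = 1 with a degeneracy flag. The source
  study's table legend calls its statistic an intraclass correlation while
  the text says κ; the implementation is Cohen's κ on 2×2 presence tables.
* The per-visit "difference %" column convention of the source table is
  undefined there and is deliberately not reproduced.

## Problem sizes

Simulation studies run on a downscaled profile of the same 6.2 × 6.7 mm²
field: 128 A-scans × 64 B-scans × 128 depth samples (the acquisition
protocol's full profile, 512 × 128 × 256, is the default for
`scan_geometry()`). One downscaled volume analyzes in about a second; the
31-eye month-24 cohort runs in under a minute. The fixture cohort encodes
the study's month-24 lesion prevalence per eye (19/31 GA, 20/31 porosity,
30/31 focal atrophy, 3/31 thinning, 8/31 accumulation, 16/31 ectopic foci)
and the printed GA-area distribution; `scripts/acceptance.R` regenerates and
re-measures it from scratch.

## Known limitations

* Recovered GA areas carry the window-convolution bias discussed above;
  the acceptance check therefore bounds recovery by the perimeter ×
  pixel-pitch quantization term, which dominates it at the downscaled
  B-scan pitch.
* No en-face registration across visits is modelled (the instrument had no
  eye tracking), so longitudinal analyses treat visits independently.
* The rule constants that the source text leaves qualitative ("series" of
  gaps, "several" residuals, smoothing operator, binarization cutoff,
  connectivity) are package decisions, exposed in `rule_params()` and
  `pipeline_config()` rather than hard-coded.

```{r example}
g <- scan_geometry_test()
sim <- generate_phantom(phantom_spec(geometry = g, lesions = list(
  lesion_ga_patch(3.0, 3.3, radius_mm = 0.6))), seed = 1)
res <- analyze_eye_visit(sim$volume, pipeline_config())
res$ga$lesions
```
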