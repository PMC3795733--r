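---
title: "Quantifying microvessel morphology in immunostained hot-spot fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvessel morphology in immunostained hot-spot fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The problem

Tumour angiogenesis is classically quantified in the *hot spot* — the
subjectively selected most vascular microscope field of a tumour section —
by counting microvessels (MVD) or estimating relative vascular area
(Chalkley count). Both ignore the *morphology* of the individual vessels.
`vesselmorph` implements an image-analysis pipeline that segments
CD34-immunostained microvessel profiles from photographed hot-spot fields
and summarizes their size, shape and spatial arrangement into a per-field
marker vector, together with the statistical protocol used to validate
such markers as prognostic factors against survival endpoints.

The pipeline targets calibrated RGB photomicrographs; the default
calibration is a 0.38 mm&sup2; field at 0.34 &micro;m/pixel. Because no
public image set accompanies this kind of material, the package ships a
synthetic-field generator with exact continuum ground truth and a
proportional-hazards cohort simulator, so every stage is testable end to
end without external data.

## Segmentation model

A pixel is *stain* when it is dark and not counterstain:

1. **Darkness.** A dynamic threshold is recomputed per image on the
   intensity channel (mean of R, G, B). The default is Otsu's
   parameter-free method; a percentile alternative is exposed in
   `segmentation_config()`. The original acquisition system's exact
   dynamic-threshold rule is not restated in the source material for this
   design, so the standard parameter-free choice is used.
2. **Hue rejection.** Pixels whose HSV hue falls in the haematoxylin band
   (default 180&deg;–280&deg;, covering blue to blue-purple counterstain)
   are rejected regardless of darkness, so dark nuclei never enter the
   stain mask while brown DAB reaction product does.

Stain pixels are grouped into 8-connected candidate objects; enclosed
background gaps are 4-connected — the standard dual pairing that avoids
topological paradoxes. Each fully enclosed gap is classified by its width:

* gap width &ge; 1.0 &micro;m &rarr; **lumen** (kept as luminal pixels);
* narrower &rarr; noise, filled back into the stain.

*Width* is defined once, as the diameter of the largest inscribable
circle — twice the maximum over pixels of the Euclidean distance to the
nearest complement pixel — and is applied uniformly to gaps and objects.
Finally, an object is a **microvessel** only if its filled profile
(lumens included) is at least 3.5 &micro;m wide; everything narrower is
discarded as noise or artefact. Border-touching vessels are retained by
default: hot-spot photographs crop vessels at the frame, and discarding
them would bias the size markers downward (configurable).

## Per-vessel descriptors

For each vessel profile the package computes:

* **areas** — endothelial (stained), luminal, and vascular
  (endothelial + luminal) area; pixel counts scaled by the squared pitch,
  so additivity is exact;
* **outer perimeter** — the traced outer boundary of the filled profile;
  lumen boundaries are excluded, so a ring and its filled disc measure
  identically;
* **width** — largest inscribed circle, as above;
* **solidity** — vascular (filled) area over the area of the convex hull
  of the filled profile; compact profiles approach 1, branched or
  tortuous profiles fall well below;
* **skeleton** — topology-preserving Zhang–Suen thinning to
  one-pixel-wide strokes; length sums inter-pixel steps (1 or &radic;2
  pixels), and branch points are skeleton pixels with at least three
  skeleton neighbours, with triple-points closer than 2 px merged (a
  well-known thinning artefact produces adjacent triplets);
* **centroid** — centre of mass of the filled pixels (used for the
  spatial markers; it may legitimately fall outside a crescent-shaped
  profile).

### Numerical choices

**Perimeter.** Chain-coded boundaries overestimate smooth outlines when
steps are weighted 1 and &radic;2 (about +4–5% on digitized circles). The
package therefore uses the corner-calibrated weights 0.948 per straight
and 1.340 per diagonal step (Proffitt–Rosenfeld), which measure digitized
circles of radii 30–80 px to well within 3% and behave consistently
across orientations. Degenerate objects whose outer contour collapses to
a few points are measured by their exposed pixel-edge length, so a single
pixel reports `4 * pitch`. The residual bias on axis-aligned rectangles
(about &minus;5%) is accepted: markers are compared across fields under a
common estimator.

**Solidity.** The hull is taken over *mid-crack* points — midpoints of
the exposed pixel edges. This makes the hull exact for axis-aligned
outlines (a scaled plus-pentomino measures its continuum value 5/7 to
within 0.02) and nearly unbiased for smooth ones; hulls over pixel
corners were measurably inflated by staircase notches (about 1/r relative
error on discs). A degenerate hull is floored at the filled area, so
solidity never exceeds 1.

**Width.** The distance transform treats the image border as complement,
and the reported width is exactly `2 * max(distance)` — the same
quantity an exhaustive per-pixel search maximizes, which the test suite
verifies on random blobs.

## Field-level markers

With vessel set $V$ of a field:

* `MVD` — vessels per mm&sup2;; `MVA_sigma`, `MVA_mu`, `MVA_CV` — total,
  mean and coefficient of variation (sample SD over mean) of the vascular
  areas; `MVP_mu`, `MVP_sigma` — mean and total outer perimeter;
  `MVE_mu` — mean endothelial area; `MVL_mu` — mean skeleton length.
* `MVS_mu` — unweighted mean solidity; `MV_luminal` — fraction of
  profiles with at least one lumen.
* `MVA_rx4` — the field's total vascular area divided by that of the
  highest-scoring subfield whose linear dimensions are one quarter of the
  field's ("four times higher magnification"). The window *slides* with
  stride `max(1, window/8)`: sliding upper-bounds the tiled maximum and
  is robust to the stride choice, which the source material leaves open.
  Values range from 1 (all vasculature in one window) to ~16 (uniform).
* `MV_scale` — the slope of mean skeleton content versus window size in
  log-log coordinates: 50 geometrically spaced square window sizes from
  3 px to the image height, 200 uniformly random placements per size
  (seeded), averaging over *non-empty* windows only, and a single OLS fit
  through all usable sizes. Unconditional averaging would make the
  expected slope identically 2 for every pattern, which carries no
  information; the conditional rule yields 2 for a space-filling pattern,
  1 for a line, 0 for an isolated point, and therefore scores extended,
  complex vasculature above small simple profiles. Geometric size spacing
  keeps the fit from being dominated by large windows. Note that under
  this definition spatial *compression* of a fixed mass lowers the slope
  (the content curve saturates above the cluster extent); the marker
  separates vessel size/complexity, not aggregation.
* `ICD` — mean intercapillary distance: vessel centroids are joined by a
  Gabriel graph (two centres are neighbours iff the closed disc on their
  connecting segment contains no third centre) and the mean edge length
  is reported in &micro;m. Centre points are used, not
  boundary-to-boundary distances. The closed-disc tie rule is fixed for
  reproducibility — a point exactly on the circle blocks the edge, so the
  four corners of a square yield the four sides and no diagonals;
  coincident centres are jittered by $10^{-6}$ px with a seeded RNG.

Markers whose preconditions fail (no vessels for means, fewer than two
for `MVA_CV` and `ICD`) are reported as `NA`, never as zero.

## The synthetic-field generator

`sample_field_spec()` draws a field population and `render_field()`
renders it bit-deterministically under the spec's seed:

* **Archetypes**: annuli, elliptical rings, wavy ribbons and three-armed
  branched profiles — with or without lumens — mirroring the appearance of
  compact rounded capillaries, elongated profiles, and complex branched
  vessels. Default mix: 45% annuli, 20% elliptical rings, 20% ribbons,
  15% branched; lumen probability 0.6.
* **Sizes** are drawn in micrometres (log-normal mean outer radius
  5.1 &micro;m, &sigma;&#8345; 0.30; wall thickness around 1.7 &micro;m)
  and converted by the pitch, giving vessel diameters of roughly
  7–17 &micro;m — typical of tumour microvasculature. Every intended
  vessel renders at least the 3.5 &micro;m minimum width; every noise
  speck (1–3 px) stays below it, so the intended vessel count is exactly
  recoverable.
* **Colours**: DAB walls at hue 30&deg; with per-pixel value jitter,
  haematoxylin nuclei at hue 230&deg;, near-white background with mild
  Gaussian noise — chosen to exercise both the darkness and the hue tests
  of segmentation. Within-vessel stain heterogeneity is deliberately
  simplified to value jitter around a uniform colour.
* **Placement** is rejection-sampled so vessels never touch
  (bounding-disc separation); overlap aborts rendering unless explicitly
  allowed, keeping per-vessel ground truth unambiguous.
* **Ground truth**: annuli and elliptical rings carry closed-form areas,
  perimeters (elliptic integral) and widths; ribbons carry dense-sampled
  centreline geometry (area $L t + \pi t^2/4$, perimeter $2L + \pi t$,
  hull of the offset outline); branched profiles are measured by a
  10&times;-resolution raster oracle of the generating capsule union.
  Solidity 1 is exact for the convex families.

What the generator does *not* emulate: stain-intensity gradients within
vessels, out-of-focus blur, touching or overlapping vessels,
CD34-positive stromal fibrocytes (excluded at case level in practice),
and tissue texture. Passing the recovery tests therefore demonstrates
correctness of the measurement chain on well-separated, well-stained
profiles — not robustness to every real-world staining artefact.

## The synthetic cohort and the validation protocol

`generate_cohort()` draws per-patient marker values from normal
distributions and simulates two endpoints — distant disease-free survival
(DDFS) and breast-cancer-specific survival (BCSS), in months — from an
exponential proportional-hazards model: hazard
$\lambda_0 \exp(\sum_m \beta_m z_m + \text{covariate effects})$ with
$\beta_m$ expressed per SD of marker $m$. Censoring is independent and
uniform on $(0, u)$, with $u$ calibrated by root-finding so the realized
censoring fraction matches the target (default 0.79, typical of an
operable breast-carcinoma cohort with long follow-up); the extremes 0 and
1 are handled exactly. Categorical covariates (grade, nodal status, T
stage, vascular invasion, disseminated tumour cells, hormone receptor
status, systemic therapy) are drawn with frequencies typical of such a
cohort.

The validation protocol mirrors standard biomarker-panel practice:

* **Screening**: each marker standardized (mean 0, sample SD 1) and fit
  by continuous Cox regression (Efron ties) per endpoint; HRs are per
  +1 SD.
* **Panel gate**: Bonferroni threshold $\alpha/m$ (0.05/7 = 0.0071 for
  the seven-marker panel); the boundary passes (`p <= threshold`). A
  marker is *prognostic* only if it passes for **both** endpoints — a
  rule strictly more conservative than either endpoint alone.
* **Dichotomization**: median split with ties going low, reproducing the
  147/146 split at n = 293; Kaplan–Meier curves, two-sided log-rank, and
  the group HR from a binary Cox fit.
* **Associations**: Pearson chi-square (nominal) or linear-by-linear
  trend (ordinal) tests with p-values from the exact conditional
  distribution given the margins, approximated by seeded Monte Carlo
  (Patefield's algorithm, $10^5$ draws by default — full enumeration is
  rarely feasible at these table sizes).
* **Subgroups**: the binary factors (DTC, VI) are tested within each
  marker stratum, reporting per-stratum HR, CI and log-rank p and whether
  each stratum's HR falls outside the other's CI.
* **Multivariate**: joint Cox fits with a warning below ten events per
  variable, and a flag for collinear covariates.
* A seeded 25/75 pilot/validation split utility is provided for
  exploratory workflows.

### Simulation design for the recovery checks

The test suite verifies estimator recovery at n = 400 with a true HR/SD
of 1.4 and 30% censoring. The censoring level is a design choice made for
identification: with ~280 events the SE of the log HR is ~0.06, so the
estimate falls in [1.2, 1.6] in well over 80% of replicates, making the
check sharp rather than noise-dominated. The family-wise error of the
dual-endpoint gate is checked on 500 null cohorts of n = 300; the
subgroup analysis is checked on cohorts where a factor carries a hazard
ratio of 4 in exactly one stratum.

## Problem sizes and determinism

Rendered test fields are 512–640 px (about 0.05 mm&sup2; at the default
pitch) with 5–10 vessels; the marker-recovery suite uses 20 such fields,
and full-size 1814 px fields process in seconds. All stochastic stages —
field sampling, rendering, window placement in `MV_scale`, Monte Carlo
tests, cohort simulation — are seeded explicitly, and identical
spec + seed yields bit-identical images and tables. Every CSV written by
the pipeline carries a provenance header (package version, configuration
hash, seed).

## Known limitations

* Colour handling is threshold-based; no colour deconvolution into stain
  density channels is attempted, and fields dominated by CD34+ stromal
  fibrocytes must be excluded upstream.
* The perimeter estimator is unbiased for smooth and diagonal outlines
  but ~5% low on long axis-aligned straight edges; solidity carries a
  small negative bias (≲0.03) for convex vessels below ~25 px diameter.
* Touching vessels are segmented as one profile; the generator avoids
  this regime by construction, and real hot spots with many contacting
  vessels would need a separation step (e.g. watershed) that is out of
  scope here.
* `MV_scale` depends on random window placement; with the default 200
  placements per size its replicate-to-replicate SD is small (&lt;0.02)
  but not zero unless the seed is fixed.
* The cohort simulator's exponential baseline satisfies proportional
  hazards by construction; it does not emulate competing risks or
  informative censoring.
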