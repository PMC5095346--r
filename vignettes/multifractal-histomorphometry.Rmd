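---
title: "Multifractal histomorphometry of tumor-stroma interfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal histomorphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histomf)
```

## The problem

The irregularity of the invasive front of a carcinoma — how raggedly tumor
cell clusters interdigitate with the surrounding stroma — carries prognostic
information that pathologists grade visually (tumor border configuration,
tumor budding). `histomf` quantifies that irregularity from
immunohistochemistry sections stained with a pan-epithelial marker (DAB
chromogen, hematoxylin counterstain): the tumor compartment is segmented,
its boundary is reduced to one-pixel contour images, and the contours are
summarized by multifractal box-counting metrics that can then be evaluated
as survival biomarkers on a cohort table.

The pipeline has four stages, each re-enterable from its serialized
artifact:

1. **Segmentation** — color deconvolution of the RGB image into stain
   optical densities, thresholding, object-level cleanup; output is a
   binary tumor-vs-non-tumor mask.
2. **Contours** — the *outline* variant (holes filled, so only the
   tumor-stroma interface remains) and the *internal-structure* variant
   (lumina and internal stroma interfaces retained).
3. **Multifractal spectrum** — box counting over a window of scales, the
   direct (Chhabra-Jensen) estimates of `alpha(q)` and `f(q)`, generalized
   dimensions `D(q)`, and the exported per-case metrics `alpha_max` and
   `f_alpha_max` for each contour variant.
4. **Cohort statistics** — Spearman correlations, Mann-Whitney /
   Kruskal-Wallis group comparisons, Kaplan-Meier and Cox models for time
   to recurrence (TTR) and cancer-specific survival (CSS), and the
   marker-by-treatment interaction test.

## Segmentation model

Pixel intensities are converted to optical density with the Beer-Lambert
transform `OD = -log10((I + 1)/256)` per channel and projected onto a
stain basis (default: the widely used H-DAB calibration vectors, user
overridable) by solving the 3x3 linear system; negative stain
contributions are clamped to zero. Classification is intentionally simple
and parameter-free by default:

* glass/background: total OD below `tissue_od_min` (default 0.10);
* tumor: DAB OD above a threshold chosen by Otsu's method on the tissue
  DAB histogram, **floored** at `dab_od_min` (default 0.15) — without the
  floor, an image with no specific staining would have its noise split in
  two and tumor invented where there is none;
* stroma: remaining tissue.

Tumor objects below `min_object_px` (default 64 px) are returned to the
stroma class and holes below `fill_small_holes_px` are filled, replacing
the per-case manual review such masks normally receive. An optional
k-nearest-neighbour pixel classifier trainable from labeled rectangles
(`knn_classify_tissue`) is provided for parity with object-based
commercial workflows; the default chain does not use it.

Connectivity conventions are fixed package-wide: 8-connectivity for
foreground objects, 4-connectivity for background and holes (the standard
complementary pairing that avoids topological paradoxes), 0-based
row-major coordinates with the origin at top left.

## Contour operators

The boundary operator is the morphological inner boundary: the mask minus
its erosion by the 4-connected cross, which yields 1-px-wide contours and
is idempotent on 1-px curves. The outline variant first fills every
background region not connected to the image border (flood-fill
semantics), so only the interface with the surrounding stroma survives;
the internal variant skips the filling. All disjoint tumor regions
contribute contours by default (`largest_component_only = FALSE`).

## Multifractal estimation

The measure analyzed is the normalized foreground pixel count per box.
For box edge `s` (px) and grid placement `g`, box masses `m_i` define
`P_i = m_i / M`. Three scaling sums are regressed against `log(s)` over
the scale window (unweighted OLS, natural logs):

* `tau(q)`: slope of `log Z(q)`, `Z(q) = sum_i P_i^q`; `D(q) =
  tau(q)/(q-1)` with `D(1)` from the information sum `sum_i P_i log P_i`;
* `alpha(q)`: slope of `sum_i mu_i(q) log P_i`, with the Chhabra-Jensen
  normalized measures `mu_i(q) = P_i^q / Z(q)`;
* `f(q)`: slope of `sum_i mu_i(q) log mu_i(q)`.

The direct route is used because it is stable at strongly negative `q`; a
Legendre-transform cross-check (`legendre_check`) is provided as a
diagnostic only. All per-`q` quantities are computed in log space
(log-sum-exp), so `q = +/-10` cannot overflow. `alpha_max` and
`f_alpha_max` are the maxima of `alpha(q)` and `f(q)` over the `q` grid;
for a monotone spectrum that is the `q = q_min` end. The per-case QC
additionally records the r-squared of an OLS line through `D(q)` vs `q`
(a monofractal's flat spectrum is reported as r-squared 1 plus a
`monofractal` flag, since a horizontal line is a perfect fit and the
usual formula divides by zero variance).

### Edge-corrected moment sums

Boxes clipped at the image border cover less area than `s^2`, and their
genuinely smaller masses would be mistaken for measure heterogeneity —
on a perfectly uniform square the naive sums produce a spurious spectrum
width of ~0.3. The sums are therefore computed in an area-referenced
form: each box enters with weight `w_i = a_i / s^2` (its intersection
area over the full box area) and density-equivalent mass `P~_i = (m_i /
a_i) s^2 / M`, and `f(q)` uses `log(mu_i / w_i)`. For interior boxes
`w_i = 1` and everything reduces to the standard sums; `Z(1) = 1` and the
tangency identity `alpha(1) = f(1)` hold exactly in either form. On the
uniform square this formulation is exact (`D(q) = 2` to machine
precision).

### Scale window and grid placements

The window runs from `min_box_px` (default 10 px) to `max_box_fraction`
(default 0.6) of the smaller image dimension, with `n_scales` (12)
approximately geometrically spaced integer sizes. Two numerical guards
matter in practice:

* *Sliver-safe sizes and offsets.* A clipped edge box 1-2 px wide carries
  a tiny mass that can dominate every `q < 0` moment. Candidate sizes are
  nudged within +/-3 px so the edge remainder is either zero or at least
  a third of the box; the seeded pseudo-random grid offsets (default 4
  placements per scale: the origin plus 3 random) are drawn from the
  analogously safe set.
* *Density guards.* Placements whose coverage fraction (non-empty boxes
  over boxes intersecting the image) exceeds `max_density` (default
  0.98) are structure-blind at that scale and are set aside in favour of
  lower-coverage placements; if every placement at a scale exceeds the
  bound, the least-covered ones are kept with the QC flag
  `coverage_guard_relaxed`, so matched cases always keep identical scale
  windows. Within accepted placements, boxes with mass below
  `min_density` (default 0.1) times the placement's median box mass are
  excluded from the moment sums: a grid box grazing a 1-px contour
  tangentially holds 1-2 px at *every* scale, and those scale-free
  accidents otherwise dominate `alpha(-10)` and make `alpha_max` erratic
  across otherwise similar images. Setting the bounds to `(0, 1)`
  disables both guards — the validation fixtures with space-filling
  measures (below) are analyzed that way, because for a genuine measure
  the sparse boxes are signal, not noise. The exported `density_filter()`
  op applies the plain absolute coverage bounds for direct use.

Per-`q` sufficient statistics are averaged over accepted placements at
each scale before the regression. Monotonicity violations of `alpha(q)`
or `D(q)` beyond `tol_mono = 0.05` raise QC flags, not errors:
finite-size effects are expected on small images.

## Synthetic substrates and what they validate

`histomf` ships generators for every fixture class used in its tests; all
are bit-reproducible under a fixed seed.

* `gen_filled_square`: monofractal sanity — `D(q) = 2`, spectrum width
  ~0, `multifractality_check` false.
* `gen_sierpinski_carpet(level)`: analytic capacity dimension
  `log(8)/log(3) = 1.8928...`; level 5 (243 px) is the standard test.
* `gen_cascade_points(weights, depth, n_points)`: a quadrant
  multiplicative cascade with the closed form `alpha(q) =
  -sum(w^q log2 w)/sum(w^q)`; with weights (0.4, 0.3, 0.2, 0.1),
  `alpha(-10) = 3.3209`. Two rasterizations are offered. The binary
  support (`mode = "binary"`, the same substrate as contour analysis) is
  the default return, but finite sampling leaves isolated single-pixel
  atoms whose box mass is scale-independent, which biases `alpha(-10)`
  low by ~0.5; the count-weighted raster (`mode = "counts"`) is the
  faithful discretization of the cascade measure and is what the
  validation uses. The default canvas `2^(depth-1)` is deliberately
  coarser than the terminal cells so several cells average within one
  pixel and Poisson noise does not create such atoms in the sparse
  regions that dominate `q < 0`.
* `gen_pseudo_tumor(kappa, ...)`: a lobulated blob rendered through the
  forward stain model with Gaussian noise and ground-truth mask. The
  boundary is a radial curve carrying dyadic harmonics `2^1..2^7` whose
  amplitude scales with the irregularity knob `kappa` and whose spectral
  decay flattens with it (`H = 1 - 0.6 kappa`), so `kappa` adds boundary
  frequency content monotonically in expectation; matched seeds share
  the harmonic draws, isolating the `kappa` effect. Elliptical
  gland-like holes (centers kept >= 12 px inside, so the outline is
  untouched) emulate internal structure. The default canvas of 512 px
  (~330 um at 0.65 um/px) was chosen so the outline contour is long
  enough for stable negative-`q` statistics; at 384 px the
  `kappa`-to-`alpha_max` ordering is visibly noisier.
* `gen_cohort(...)`: a two-arm trial table (surgery alone vs adjuvant
  chemotherapy) with a continuous marker, exponential recurrence times
  under the planted log-linear hazard `bM*high + bT*treat +
  bI*high*treat`, cancer-specific death following recurrence after an
  independent exponential delay, independent exponential censoring with
  a 120-month administrative cap, and standard colon-cancer covariates
  (age, sex, site, MMR, stage, grade, border configuration, budding)
  drawn from fixed realistic marginals with no planted effect.

What passing these validations does *not* show: real sections have
staining gradients, tissue folds, blur and nuclei-scale texture that the
pseudo-tumor model does not emulate, and real tumor boundaries are not
radial graphs. The fixtures validate the *estimators* (segmentation
recovery, contour exactness, spectrum accuracy against closed forms,
effect recovery in survival models) — not the biological claim that the
metrics are prognostic, which requires a real cohort.

## Cohort statistics

All inference wraps stock routines from `stats` and `survival`; the
package adds validation, missing-data policy and tidy output. Choices the
underlying papers and manuals leave open are fixed as follows:

* Median dichotomization sends values *at* the median to "low"
  (deterministic; documented because the convention changes group sizes
  when ties exist). Degenerate all-equal input is an error.
* Spearman correlations use average ranks and the asymptotic two-tailed
  p (tie-robust); Mann-Whitney for 2 groups, Kruskal-Wallis for 3+.
* Cox models use Efron tie handling, Wald 95% intervals and p-values;
  cases with missing model columns are dropped listwise and `n_used` is
  reported. Non-convergence (separation) is an explicit error.
* The interaction test fits `marker + treatment + marker:treatment`,
  reports the Wald p of the product term (a likelihood-ratio p is
  included as a secondary diagnostic) and the treatment hazard ratio
  within each marker stratum; all four marker-by-treatment cells must be
  non-empty, and the offending cell is named otherwise.
* Alpha is 0.05 two-sided throughout and no multiple-testing correction
  is applied — the analysis reproduces a single-marker evaluation
  workflow, not a screening study.
* TTR and CSS enter as precomputed columns (months + event flag); the
  package does not process calendar dates.

## Problem sizes in the validation suite

The test and acceptance runs use the sizes that keep the suite fast
while leaving the estimators in their working regime: 243-px analytic
fixtures, cascades of 2e5 points at depth 8 (averaged over 3
replicate samplings in the acceptance script, since a single sampled
realization of `alpha(-10)` has sd ~0.15), 20 pseudo-tumors of 512 px
for segmentation and ordering checks, cohorts of n = 300 (calibration,
1000 replicates) and n = 2000 (effect recovery and interaction power,
20 replicates).

## Known limitations

* The segmentation is a functional, not bit-level, substitute for
  object-based commercial classifiers; on real slides the stain vectors
  and thresholds may need per-batch tuning (all are config keys).
* `alpha(-10)` is the noisiest exported quantity; on contours much
  shorter than ~1000 px it remains grid-sensitive even with the
  under-sampling guard. `f_alpha_max` (the capacity dimension of the
  contour) is markedly more stable.
* Whole-slide pyramid formats are out of scope; inputs are desk-scale
  TIFF/PNG regions, optionally restricted by a user-supplied ROI mask
  applied before segmentation.
* The exported `alpha_max` is the maximum of `alpha(q)` over the `q`
  grid. A per-scale reading ("the maximal local irregularity across
  scales") is also computable from the spectrum object, but the q-grid
  maximum is the documented, exported metric.
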