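---
title: "Quantifying organelle cargo enrichment and distribution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelle cargo enrichment and distribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexquant)
```

`pexquant` quantifies three readouts of motor–adaptor complex assembly on
organelles from multi-channel fluorescence z-stacks: per-cell cargo
enrichment on construct-positive organelles, cell-shape-scaled radial
distributions of organelles, and per-ROI organelle counts in neurons. This
vignette explains the underlying models, the tunable parameters, the
numerical choices, and what the synthetic-data validation does and does not
show.

## The enrichment model

The input is a z-stack with three declared channel roles: an organelle
*marker* (e.g. a peroxisome-lumen label), the membrane-anchored *construct*
(e.g. an RFP-tagged PEX3-anchored fusion) whose recruitment activity is
under study, and the *cargo* (a motor or adaptor) whose accumulation is the
readout. Overexpressed cargo is partly cytosolic, and at high expression the
construct can spill over onto other membranes, so two restrictions define
the analysis domain:

1. only marker-mask pixels are analyzed (organelle pixels), and of those
2. only pixels where the construct is also detected (the *double-positive*
   or analysis mask), mirroring the inclusion of only organelles that
   visibly carry the construct.

For each z-slice $z$ with a non-empty analysis mask,

$$\mathrm{raw}_z = \overline{C}_{\mathrm{mask},z} - \overline{C}_{\mathrm{cyto},z},
\qquad
\mathrm{cons}_z = \overline{E}_{\mathrm{mask},z},$$

where $C$ is cargo intensity, $E$ construct intensity, and the cytosol is
the cell region minus the *full* marker mask (the background is everything
in the cell that is not an organelle, not merely what is outside the
analyzed organelles). Cell-level scores are

$$\mathrm{raw} = \langle \mathrm{raw}_z \rangle_z, \qquad
\mathrm{norm} = \mathrm{raw} \, / \, \langle \mathrm{cons}_z \rangle_z .$$

Design choices that were genuinely open, and how they were fixed:

* **Unweighted slice average.** The mean over used slices is unweighted; a
  pixel-count-weighted variant is available (`sliceWeighting = "pixel"`).
  The unweighted form treats each optical section as one observation of the
  cell and is the default.
* **Ratio of averages.** Normalization divides the averaged raw signal by
  the averaged construct signal rather than averaging per-slice ratios;
  this is stable when a slice's construct mean is small. The alternative is
  `normalization = "average-of-ratios"`.
* **Mean, not integrated, intensity.** Integrated intensity would couple
  the score to organelle size; the mean measures surface density.
* **Per-slice background.** The cytosolic term is computed per slice and
  averaged, tracking focal-plane-dependent background.
* **Negative values are reported.** Cargo depletion on organelles is
  informative (e.g. inactive-state constructs) and the statistics layer
  handles it; nothing is clipped.

Degenerate inputs error loudly rather than return numbers: an empty
analysis mask on every slice ("no construct-positive organelles" — the cell
is excluded, and batch runs list it with the reason), an empty cytosol, or
zero construct intensity.

The mitochondrial variant (`mitochondrialEnrichment`) reports the per-slice
*fold ratio* of the mask mean to the cytosol mean, averaged over slices —
"relative to the cytosol" is implemented as a ratio, with a difference mode
available by flag.

## Segmentation

Masks are computed per z-slice (`segmentMarker`): the default is per-slice
Otsu thresholding with `fixed:<t>` and `quantile:<q>` overrides, and
components smaller than `minSizePx` (default 2) are removed per slice. The
applied thresholds are stored in the mask's `methodRecord`, and passing a
record back as the `method` reproduces the mask bit-exactly — every mask in
a run is auditable and reproducible. A flat (e.g. all-zero) slice yields an
empty mask for that slice, not an error.

Object identity uses the **2-D maximum projection** of the per-slice masks
with **8-connected** components: a punctum spanning 2–3 adjacent slices is
one object, which is the correct unit for counting and radial analysis.
The construct-positivity threshold defaults to a per-cell Otsu of the
construct intensities inside the marker mask — a pixel-level analog of
"visible construct signal on the organelle".

## Shape-scaled radial shells

Shell boundaries are scaled copies of the user-drawn outline about the
user-chosen center with factors $k/n$, so shells inherit the cell's shape.
The radial coordinate of an object is $r = |p - c| / B(\theta)$ with
$B(\theta)$ obtained by casting the ray from the center through the
centroid to the outline; this is equivalent to point-in-polygon tests
against every scaled boundary for star-convex outlines but needs one
geometric predicate. Numerical conventions, fixed for determinism:

* shell index $\lceil r\,n \rceil$ with half-open intervals $(\mathrm{lo},
  \mathrm{hi}]$ — a centroid exactly on a boundary goes to the *inner*
  shell;
* centroids outside the outline are excluded with a warning and counted,
  never silently dropped and never fatal (segmentation noise at the edge
  should not abort a batch);
* non-star-convex outlines are rejected with guidance to re-draw, since
  scaled boundaries would cross;
* `nShells` is configuration with default 10 — the shell count of the
  original interactive tool is not documented, so it is surfaced rather
  than asserted;
* across cells, per-shell spread is the sample SD ($n-1$); a single cell
  reports `NA` rather than a fabricated 0.

Because boundary $k$ is a similarity transform of the outline, its area is
exactly $(k/n)^2$ times the cell area; uniformly placed objects therefore
have expected shell frequencies $\propto k^2 - (k-1)^2$, which is the
calibration the test suite checks by chi-square.

## Neuron ROI counts

`roiObjectCounts` counts projected objects whose centroids fall inside each
named ROI polygon (boundary-inclusive), and reports the growth-cone/soma
ratio (NA with a warning when the soma count is zero). Centroid containment
rather than any-pixel overlap keeps membership deterministic at ROI edges.
Overlapping ROIs are permitted — an object may count in both, with a notice
— because silently dropping data when a user draws overlapping ROIs would
be worse.

## Statistics

* **Welch t** (two-tailed, unpaired) with Welch–Satterthwaite df, written
  in closed form; two zero-variance groups give $t=0, p=1$ (equal means) or
  $p=0$ with a warning (unequal means).
* **Mann–Whitney U**: exact two-tailed p for tie-free samples with
  $n_a + n_b \le 12$, otherwise the tie-corrected normal approximation; the
  `method` string records which path ran.
* **Dunnett's T3**: all pairwise Welch-type statistics; each comparison's
  adjusted p is the tail of the studentized maximum modulus (SMM)
  distribution for $k$ comparisons at that pair's own Welch–Satterthwaite
  df. The SMM has no closed form for non-integer df, so tails come from
  seeded Monte Carlo (`mcReps`, default 100{,}000) with draws nested in $k$
  — adjusted p-values are monotone in the number of comparisons at a fixed
  seed. The adjusted p is clamped below by the raw Welch p, and the Šidák
  bound is reported per pair as an independence cross-check that the SMM p
  never exceeds beyond Monte Carlo noise. The omnibus one-way ANOVA F is
  reported but gates nothing. Calibration: over 10,000 simulated 3-group
  null datasets (n = 15 per group) the family-wise error rate is ≈ 0.04–0.05
  (the procedure is mildly conservative, as expected for SMM-based
  corrections under equal variances).
* **ROUT (Q = 1%)** adapted to a one-parameter constant model for
  univariate data: robust center by iteratively reweighted least squares
  (bisquare); RSDR = 68.27th percentile of absolute residuals times
  $n/(n-1)$; two-tailed t p-values ($n-1$ df) for residual scores; an FDR
  step-up rule at rate Q tests from the most extreme residual inward, with
  at most the most extreme 30% of points eligible. On clean normal data
  (n = 15) it flags nothing in ≈ 99% of datasets, and it detects a 10σ
  contaminant essentially always.
* **Tukey box summaries** use type-7 (linear-interpolation) quartiles —
  outlier sets depend on the quartile dialect, so it is fixed and
  documented — with whiskers at the most extreme points within 1.5 IQR.

The outlier rule applied before group comparisons (`none`, `rout`,
`tukey`) is an explicit per-analysis configuration choice, since published
practice varies between datasets even within one study.

## The synthetic data generator

`simulateCos7Cell` emulates a fixed COS-7-like cell as imaged for this kind
of assay; its defaults are the package's study conditions and are not
tuned per experiment:

* stack of 6 slices, 128×128 px, 0.3 µm z-step, 0.25 µm pixels (neurons:
  4 slices, 160×320 px, 0.2 µm z-step);
* a random star-convex outline (radius function with low-order harmonics)
  around the image center;
* 40 peroxisomes rendered as 2-D Gaussian spots (σ = 2 px) spanning up to
  three adjacent slices with weights (0.5, 1, 0.5), peak marker level 150
  and per-spot brightness jitter U(0.8, 1.2);
* construct level 120 on every peroxisome, plus `mitoSpilloverFraction`
  (default 0.3) of that level painted on 6 tubular mitochondria
  (thickened random polylines) — construct only, exercising the
  double-positive restriction;
* cargo = `recruitmentFraction` × the construct's spot profile + uniform
  cytosolic background 20 inside the outline + additive Gaussian noise
  (sd 2) clipped at zero, rounded to a 16-bit integer grid;
* radial placement with CDF $F(r) = r^{1 + \mathrm{radialBias}}$ along
  uniformly random rays: bias 0 is perinuclear, larger is peripheral, and
  the expected shell frequencies $100\,[F(k/n) - F((k-1)/n)]$ are recorded
  as the analytic shell truth.

Because the cargo spot profile is exactly proportional to the construct
profile and the background is uniform, the expected normalized enrichment
of a cell equals its `recruitmentFraction` — a closed-form target for
parameter-recovery tests. The cytosolic background is rendered over the
outline plus a small halo (12% scale) so that puncta near the boundary
remain surrounded by background; this models an outline drawn just inside
the cell's cargo-filled margin, and without it boundary puncta sample empty
space and bias the null score low.

Placement separations differ by mode: COS-7 cells use a 3 px minimum
centroid separation (touching puncta occasionally merge in the projection,
which the enrichment and radial scores tolerate), while neuron placements
enforce 11 px — more than twice the segmented spot radius — because the
neuron analysis is exact object counting. Neurite puncta are placed in
evenly spaced jittered slots to guarantee the separation without rejection
stalls. Per-cell seeds in `simulateConditionPanel` are a deterministic hash
of (master seed, condition label, cell index), so panels are reproducible
and cells independent.

What the simulation does **not** emulate: optics (no PSF, no axial blur
beyond the 3-slice spot span), photobleaching, Poisson shot noise (additive
clipped Gaussian only), organelle shape variety, marker/cargo chromatic
offsets, or touching-organelle splitting. Passing the validation suite
therefore shows the *quantification machinery* is correct on data whose
ground truth is known — it does not certify segmentation quality on real
microscope images, where threshold choice and the outline placement remain
the user's responsibility.

## Validation suite and problem sizes

The acceptance tests (and `scripts/acceptance.R`) run, per fresh seed:
200 random small stacks against a brute-force per-pixel enrichment oracle
(exact agreement) plus a hand-computed 4×4 example; 50 null-recruitment
cells (mean score within 2 SEM of 0); recruitment recovery over
{0, 0.25, 0.5, 1} × 20 cells (Spearman ρ ≥ 0.9); a 15 + 15 cell
active-vs-inactive panel separated by Dunnett's T3 at p < 0.01; shell
conservation to 100 ± 1e−9, uniformity chi-square p > 0.01 at 1,000 points,
and dispersal monotonicity in the radial bias; 1,000-sample Welch and
Mann–Whitney oracle agreement at 1e−8, 10,000-simulation T3 family-wise
error in [0.04, 0.06], ROUT clean-rate ≥ 95% (10,000 datasets) and 10σ
power > 0.99 (2,000 datasets); and 9 + 9 zero-noise neurons with exact
count recovery and Welch-separated growth-cone/soma ratios. These sizes
match the per-condition n of the experimental design the generator emulates
(15 cells, 9 neurons) while keeping the full suite to a few minutes.

## Known limitations

* Otsu thresholding assumes a bimodal-enough intensity histogram per slice;
  very sparse or very dense organelle fields may need `fixed:` thresholds.
* The radial analysis is 2-D (in-plane distances), appropriate for flat
  adherent cells; it is not a 3-D radial profile.
* Pixel-wise co-localization coefficients (Pearson/Manders) and
  per-organelle enrichment distributions are out of scope; the unit of
  analysis is the cell.
* The replicate structure (cells pooled across biological replicates) is
  not modeled; the statistics treat cells as exchangeable.
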