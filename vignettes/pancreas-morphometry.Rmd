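---
title: "Methods: pancreas morphometry from MRI segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pancreas morphometry from MRI segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and numerical choices behind
`pancmorph`. The package quantifies three morphological properties of the
pancreas from abdominal MRI: its volume, the irregularity ("serration") of
its border, and its fat content, together with the cohort statistics used
in two-group (responder / non-responder), three-timepoint
diabetes-reversal designs. Because no patient images ship with the
package, every method is exercised against synthetic inputs whose ground
truth is known analytically; this document also states precisely what
those synthetic inputs do and do not emulate.

## Volumetry

A segmented organ is a binary voxel grid with physical spacing
$(h_r, h_c, h_s)$ mm (in-plane row/column spacing and slice thickness).
The volume estimator is slice summation: the delineated area per slice
(foreground-pixel count times pixel area) times slice thickness, summed
over slices, i.e. simply the foreground count times the voxel volume,
reported in cm³. No partial-volume correction is attempted; the
digitization error of a convex organ-sized body at 1 mm isotropic voxels
is below 1% (the test suite verifies < 2% for a 20 mm sphere against
$\tfrac43\pi r^3$ and that the error shrinks monotonically as the grid is
refined 2 → 1 → 0.5 mm).

Polygon ROIs (the manual-delineation workflow) are rasterized with one
fixed rule: a pixel is foreground iff its centre lies inside the polygon
under the even–odd (crossing-number) rule, with a half-open edge
convention so pixels exactly level with a vertex are resolved
deterministically. Vertices use 0-based $(x, y)$ pixel coordinates with
$x$ along columns. The rule makes ROI fixtures bit-reproducible and
orientation-independent; the 10 × 10 px axis-aligned square covering 100
pixel centres is the canonical hand-checked case. Polygons are validated
against self-intersection (exact segment-crossing test); multiple
polygons on a slice are unioned.

The pancreas volume index is the per-individual ratio volume/BMI
(cm³·m²·kg⁻¹). It is deliberately computed per individual and *then*
aggregated: the mean of per-individual ratios differs from the ratio of
group means (52.0/34.0 = 1.53 while a per-individual mean can be 1.54),
and the per-individual form is what the group comparisons need.

## Border fractal dimension

The irregularity measure is the box-counting fractal dimension (FD) of
the organ's projected outline:

1. **Projection.** Orthographic shadow of the mask along one anatomical
   axis (default anterior–posterior, recorded in provenance; the
   rendering view of the original visual protocol is not standardised, so
   the axis is configurable). The silhouette is resampled by nearest
   neighbour to isotropic pixels at the finer of the two retained
   spacings so boxes are square in physical units.
2. **Boundary.** Interior holes are filled (`EBImage::fillHull`), then
   the border is the foreground minus its erosion by the 3 × 3
   structuring element — the 8-connected outer contour. The analyzed set
   is this one-pixel border, not the filled silhouette: pancreas-border
   FDs reported in vivo (≈ 1.13–1.18) lie in the planar-curve regime
   (1, 2), which is the border's regime, and a filled set would saturate
   towards 2.
3. **Box counting.** Grids of side $s$ cover the image; $N(s)$ is the
   number of cells containing border pixels. Each size is scanned from
   `n_offsets` (default 10) random grid origins drawn uniformly in
   $[0, s)^2$, seeded; the image is implicitly padded with background.
4. **Slope.** Per offset, OLS of $\log N(s)$ on $\log(1/s)$; the FD is
   the **mean of per-offset slopes** (not a regression on mean counts),
   so the ensemble also yields a grid-placement dispersion and the
   per-offset $R^2$ diagnostics surfaced by `summary()`/`plot()`.

**Box-size ladder.** Sizes are the dyadic series 2, 4, …,
min(32, ⌊min-dimension/4⌋) px, and at least five sizes are required
(min dimension ≥ 128 px). The 32 px cap is a measured bias control, not a
convenience: with a shifted grid a set of extent $A$ occupies about
$A/s + 1$ cells per dimension, and the spurious "+1" edge cell flattens
the log–log slope once $s$ grows towards $A$. On a 512 px canvas with the
uncapped ladder (up to $s = 128$) a filled square reads FD ≈ 1.87 and a
Koch curve ≈ 1.16 — both far off their analytic dimensions — while the
capped window recovers line ≈ 0.98, circle ≈ 0.99, filled square ≈ 1.96
and Koch ≈ 1.23–1.24 (analytic $\log 4 / \log 3 = 1.2619$). A fixed 2–32
px window also makes FD values comparable across image sizes. The
remaining small negative bias on finite-iteration fixtures is the
familiar finite-range box-counting bias; it is well inside the ±0.05
calibration band the estimator is tested to.

**Replicates.** The duplicate-measurement protocol (two FD measurements
per organ, averaged) is modelled as independent re-seeded grid-offset
ensembles on the same projection. The original protocol does not state
how its two replicate images differed; re-randomising the offset ensemble
isolates pure estimator noise, which is the quantity a replicate CV can
bound from below. The replicate CV (100·SD/mean, sample SD) on a fixed
serrated phantom is ≈ 0.5–1.2% with 10 offsets — the same order as the
0.88% between-replicate CV reported for the in-vivo protocol, though the
two are not numerically comparable (ours excludes projection and
segmentation variation).

**Binarization.** Grayscale inputs (e.g. surface renders) are thresholded
by Otsu's method with a message; binary masks pass through unchanged.

## Synthetic organ phantom

The phantom digitizes the star-shaped surface
$r(\theta, \varphi) = r_0(\theta, \varphi)\,(1 + a\,s(\theta, \varphi))$,
where $r_0$ is the radial function of an ellipsoid (default semi-axes
25 × 20 × 15 mm, pancreas-scale) and $s$ is a smooth zero-mean angular
field: a real spherical-harmonic band over degrees $f$ to $3f$ with
seeded N(0, 1) coefficients and weights $f/l$, max-normalised to
$[-1, 1]$. The serration amplitude $a$ is therefore an exact fractional
radial excursion; $a = 0$ digitizes the pure ellipsoid. A voxel is
foreground iff its centre lies inside the surface (the same
centre-inclusion rule as the rasterizer).

The default dominant frequency $f = 12$ was chosen so that the
perturbation's angular scale (lobes of roughly 10–30 px at the default
0.3 mm test resolution) falls inside the 2–32 px box-counting window: a
single low degree produces borders that are smooth at those scales and an
FD flat at ≈ 1.0 regardless of amplitude, whereas the banded field yields
FD rising from ≈ 1.00 at $a = 0$ to ≈ 1.10–1.14 at $a = 0.4$ — the
magnitude range reported for real pancreas borders — and a strictly
monotone amplitude → FD dose-response in 10/10 test seeds when FD is
measured with the duplicate-and-average protocol. Dose-response tests use
a fixed generous grid (240 × 200 × 150 voxels at 0.3 mm) so every
amplitude shares one canvas.

What the phantom does *not* emulate: real pancreas anatomy (head/body/
tail lobulation, duct, neighbouring organs), partial-volume effects at
the border, segmentation error, or any MR contrast mechanism. Passing
dose-response tests therefore show that the estimator ranks border
irregularity correctly on star-shaped bodies, not that it reproduces any
particular clinical FD value.

## Three-point Dixon fat quantification

Forward model per pixel, with water and fat signals $W, F$ and
field-inhomogeneity phase $\phi$ accrued per echo spacing:
$\mathrm{IP} = W + F$, $\mathrm{OP} = (W - F)e^{i\phi}$,
$\mathrm{E3} = (W + F)e^{2i\phi}$. The reconstruction estimates
$\phi = \tfrac12 \arg(\mathrm{E3}\cdot\overline{\mathrm{IP}})$ (valid for
$|\phi| < \pi/2$; no spatial unwrapping is attempted beyond this
single-slice model), demodulates the opposed-phase image and recovers
$W = \mathrm{Re}(\mathrm{IP} + \mathrm{OP}_{corr})/2$,
$F = \mathrm{Re}(\mathrm{IP} - \mathrm{OP}_{corr})/2$,
$\mathrm{FF} = 100\,F/(W+F)$.

Real parts are used rather than magnitudes deliberately: at FF ≈ 0 the
magnitude of a noise-only fat channel has a Rayleigh-distributed positive
bias (≈ 1.25 percentage points at SNR 50), which the real-part
reconstruction avoids. Negative compartment values arising from noise are
clamped to zero and counted (`n_clamped`), keeping percent semantics with
loud accounting. The noiseless round trip against the phantom's known
fat-fraction map is exact to < 10⁻⁶ pp; at SNR 50 (see below) the
per-pixel RMSE over a 0–50% ramp is ≈ 0.82 pp.

The Dixon phantom holds the total proton signal constant per pixel
(`intensity`, split $W = I(1-f)$, $F = If$), so fat replaces water rather
than adding signal and the SNR is spatially uniform. `noise_sd` is the
standard deviation of the complex noise with power split equally across
real and imaginary channels; SNR = `intensity / noise_sd`. Magnitude-only
triplets (no phase available) are handled with $\phi = 0$ and a warning,
since scanner-reconstructed magnitude data carry no usable phase map.

ROI sampling follows the published protocol shape: three 100 mm²
circular ROIs of homogeneous tissue per slice (pixel-centre-in-disc
membership, consistent with the polygon rule), averaged per slice, then
the mean of exactly two slices — a missing slice is an error, never a
silent fallback. ROI *placement* is an input: selecting homogeneous
tissue is observer-driven in the source protocol, so the package
validates but does not choose ROIs (`find_uniform_roi()` is provided as a
clearly-labelled convenience beyond that protocol). Visceral fat at
L2–L3 partitions a binary fat mask by two nested polygons (outer/inner
subcutaneous boundary) into subcutaneous (between) and visceral (inside
inner) compartments, returning 100·visceral/(visceral + subcutaneous).

## Cohort simulation and statistics

The simulator draws one value per participant, group, timepoint and
variable from normal distributions parameterised by the published group
means and SEMs (per-individual SD = SEM·√n at the reported group sizes
12 and 17); age and duration are drawn once per participant. Normality is
an assumption of the generator, not a claim about the source data, which
are summarised only as mean ± SEM.

Two design choices deserve explanation:

* **Stratified sampling (default).** Within each cell the normal is
  sampled by stratified inversion — one uniform draw per equal-width
  probability stratum, assigned to participants in seeded random order (a
  Latin-hypercube scheme). Cell sample means then track the generating
  means to well under 1% even at n = 200 (and closely at n = 12), so
  simulated Table-1-style summaries are stable rather than dominated by
  Monte-Carlo noise; marginal distributions are exactly normal. Sample
  SDs are mildly shrunk at very small n (the price of stratification).
  `stratified = FALSE` restores plain iid draws.
* **The responder constraint.** Week-8 fasting glucose defines the
  groups: responder draws must fall strictly below 7 mmol/l,
  non-responder draws at or above. In stratified mode this uses exact
  truncated-normal inversion; in iid mode violating draws are resampled
  (capped at 1000 rounds — an infeasible cell, e.g. a mean far on the
  wrong side with tiny SD, errors loudly). Truncation changes the
  generating law: for the non-responder week-8 cell (mean 8.5, SD ≈ 3.3)
  the truncated mean is ≈ 10.25, not 8.5. `cohort_generating_means()`
  therefore reports the analytic mean of the distribution actually
  generated from — the input mean for unconstrained cells, the truncated
  mean for the two constrained cells — and consistency checks compare
  summaries against those.

Statistics mirror the source design's reporting conventions: paired
Student's t for within-group change from baseline; between groups,
Mann–Whitney U for fasting insulin, unpaired (pooled-variance) Student's
t for age, diabetes duration and the remaining variables. The published
footnote nominally assigns "the paired t test" to the between-group
columns as well, which is not computable for unequal group sizes; the
package uses the unpaired test there and records the convention here.
Welch's correction is available behind a flag but is not the default (the
named test is the classical Student's form). The Mann–Whitney p is exact
by enumeration for both n ≤ 8 without ties, otherwise the tie-corrected
normal approximation with continuity correction; correlations are Pearson
or Spearman (tie-corrected ranks) with p from the t transform. Degenerate
inputs (zero-variance differences, constant groups) yield explicit
not-computable results rather than p = 1. No multiple-testing correction
is applied anywhere, matching the source analysis; with ~30 contrasts per
summary this is a real limitation to keep in mind when reading simulated
tables.

## Pipeline, provenance, blinding

`run_pipeline()` executes volume → FD → fat → report for every record of
a JSON manifest, isolating per-record failures (a corrupt mask flags that
participant and the run continues; only an all-fail run errors). All
randomness flows from one root seed split deterministically per record,
and reruns are byte-identical — to keep that contract, the provenance
record (config echo, package version, input digests, per-record seeds)
deliberately omits wall-clock timestamps. `blind_labels()` /
`unblind_labels()` implement the observer-blinding step as a seeded
bijection that strips identity and group columns and shuffles row order.

## Problem sizes used by the test suite

Calibration fixtures are 512 px; dose-response uses 10 seeds × 5
amplitudes of 240 × 200 × 150-voxel phantoms at 0.3 mm with 2 replicates;
Dixon checks use 100 × 100 maps over 10 noise seeds; statistics oracles
use 50 random small datasets; cohort recovery uses n = 200 per group; the
determinism check runs the bundled 4-participant, 3-timepoint demo twice.
These sizes were chosen so the full suite exercises every claim at
laptop scale.

## Known limitations

* FD is measured on one 2D projection; the 3D surface dimension is out
  of scope (as it is for the source protocol, which names it as future
  work).
* The box-size window is fixed at 2–32 px; structures coarser than ~32 px
  contribute to the boundary but not to the slope.
* The Dixon model is single-peak fat, no T2* correction, single-slice
  phase model without unwrapping.
* The cohort simulator reproduces first and second moments and the
  glucose constraint only — no covariance structure between variables,
  no longitudinal correlation beyond the static age/duration columns.
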