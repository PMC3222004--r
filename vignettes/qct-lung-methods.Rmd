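---
title: "Quantitative CT densitometry of the lung: models, parameters and validation"
author: "qctlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT densitometry of the lung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctlung)
```

# The measurement model

A CT scanner reports, per voxel, the attenuation of the tissue it
contains on the Hounsfield scale, calibrated so that water reads 0 HU
and air reads -1000 HU. Because lung is, to a very good approximation, a
mixture of gas and near-water-density tissue, attenuation maps linearly
onto physical density:

$$\rho(HU) = \rho_{ref}\,\frac{HU + 1000}{1000},$$

the unique affine function with $\rho(-1000) = 0$ (pure gas) and
$\rho(0) = \rho_{ref}$ (water). `huToDensity()` implements this map;
`summarizeAeration()` applies it voxel by voxel and accumulates

* $V_{lung}$ — the number of analyzable in-mask voxels times the voxel
  volume (ml), and
* $M_{lung}$ — the sum of voxel volume times converted density (g),

over all masked voxels with HU in $[-1000, +100]$. Voxels outside that
window (typically contrast-filled vessels captured by a generous mask)
are **excluded and counted**, never clamped: clamping would silently
convert bright vessels into 100-HU "tissue" and bias $M_{lung}$ upward.
A clamp mode exists behind an explicit flag for sensitivity analyses.

$\rho_{ref}$ defaults to 1.0 g/ml. The physically exact value at 22 °C,
0.99777 g/ml, is used in the water-bottle validation, where both the
voxel-wise and the geometric method must share one density so that any
disagreement reflects the imaging, not the constant.

## Aeration compartments

Lung voxels are partitioned by HU into four aeration compartments,
using the conventional clinical ranges: nonaerated $-100$ to $+100$,
poorly aerated $-101$ to $-500$, normally aerated $-501$ to $-900$, and
hyperaerated $-901$ to $-1000$ HU. The printed ranges are worded for
integer HU; reconstructed values are real numbers, so the package
defines half-open real bins with boundaries at the integer midpoints
($-900.5$, $-500.5$, $-100.5$). Every integer HU then lands in its
printed compartment, every real HU in exactly one bin, and the bins
tile $[-1000, +100]$ without gaps. The boundary convention is a
documented choice of this implementation (the original software's
treatment of non-integer boundaries is not recorded anywhere we could
follow) and is configurable through `compartmentScheme()`.

Compartment masses are reported in grams and as percentages of
$M_{lung}$; by construction the masses sum exactly to $M_{lung}$ (the
total is defined as the sum of its parts, so conservation is exact
rather than a floating-point accident). The hyperaerated compartment is
computed but flagged scanner-dependent in reports: its value is
sensitive to the reconstruction kernel and should not be compared
between scanners.

# Boundary refinement

At the interface between aerated lung and chest wall, mediastinum,
heart or diaphragm, voxels straddle the boundary and take intermediate
HU — the partial volume effect — which inflates apparent lung density.
The clinical workflow handles this by drawing the segmentation line at
the black-white interface of a $-350/0$ HU display window.
`refineAeratedBoundary()` operationalizes that manual rule
deterministically: within the morphological boundary band of the
aerated region (the mask minus its erosion by `bandWidthVoxels`,
default 2, face-connected), voxels brighter than $-350$ HU are removed.

Removal can expose a brighter voxel to the new boundary, so the band is
recomputed and the rule reapplied until nothing changes. This fixpoint
is where a manually drawn line would come to rest, and it makes the
operation idempotent on *every* input — a single pass is not, because
the receded boundary can place previously interior bright voxels inside
the band. `maxPasses = 1` restores the literal single-pass variant for
sensitivity analyses. Opacified (consolidated) regions, identified by
mask labels, are never touched: the exclusion rule exists for aerated
boundaries only. Two design parameters are ours rather than inherited:
the band width (2 voxels, matching the 1–2-voxel reach of partial
volume effects at 5–10 mm reconstructions) and the 6-connected
erosion (with a slice-wise 2-D mode mimicking slice-based manual
editing).

# Reference intervals

With fewer than 120 reference subjects the CLSI C28-A3 guideline
recommends the robust method over nonparametric percentiles.
`robustReferenceInterval()` implements the Horn/Pesce biweight
construction: a Tukey biweight location $T_{bi}$ iterated from the
median with MAD/0.6745 standardization (tuning constant 3.7,
convergence $10^{-6}$, 100-iteration cap with an error that reports the
trace), and limits

$$T_{bi} \pm t_{(1+\gamma)/2,\,n-1}\,
  \sqrt{s_{bi}(205.6)^2 + s_{bi}(3.7)^2/n},$$

where $s_{bi}(c)$ is the biweight A-estimator of scale and $\gamma$ the
coverage. The wide constant 205.6 yields an essentially classical
spread estimate, robustified only against gross outliers; the narrow
constant contributes the uncertainty of the location estimate. The
guideline admits variants (which multiplier, which constants); all
constants here are function arguments, and the implementation is
cross-checked in the tests against two independent oracles — the normal
quantiles at $n = 10{,}000$ and the nonparametric percentiles — rather
than against any single published table. Simulated at the study
condition ($n = 74$ Gaussian samples, 500 replicates), the interval
covers on average 95.0% of its population.

For the large-sample comparison the package's nonparametric interval
uses R's default type-7 quantile interpolation (documented; the
guideline's own rank rule $(n+1)p$ is available as `type = 6`). Both
the robust and the nonparametric limit carry sampling noise even at
$n = 10{,}000$ — the 97.5th-percentile standard error is about 2.7% of
the SD — so their agreement is judged on the average discrepancy across
replicates relative to the interval width, not on a single draw.

# Method agreement

`blandAltmanPercent()` computes per-pair percent differences
$d_i = 100\,(A_i - B_i)/\bigl((A_i + B_i)/2\bigr)$, the mean difference
(bias) and limits of agreement $bias \pm 1.96\,SD(d)$. The
pairwise-mean denominator is the standard convention; a global-mean
denominator is available by flag. The companion oracle,
`geometricRoiMass()`, is the validation formula: ROI area × slice
thickness × density of water.

# Classification of posttraumatic lung dysfunction

Airless lung can be airless for two reasons: collapse (atelectasis),
which does not add mass, or filling with blood, edema or exudate
(consolidation), which does. `classifyMlung()` therefore separates
patients by total lung mass: at or below the upper reference limit
(study value 1164 g) the mass is normal and the dysfunction is most
likely atelectasis; above it the mass is increased; above a
literature-derived 1380 g it reaches the range reported for
consolidated lungs. Consolidation is a *nested* subset of
above-reference, and `buildStudyTables()` reports the above-reference
column both nested (as in the original table layout, where the counts
are 46/32/17 of 78) and disjoint, because the published layout is
ambiguous on this point. The consolidation cut is a configuration
value, not derivable from normal-lung data.

Two bedside utilities belong to this pipeline: support-free days within
a 28-day window (`freeDays()`; the death convention is selectable, with
the default counting observed support days and a flag for
zero-free-days-on-death, since the source convention is not restated)
and the estimated body weight, height in cm minus 100
(`estimatedBodyWeight()`).

# What the synthetic generators emulate

**Phantoms** (`makeThoraxPhantom()`): an air background, a soft-tissue
body at +40 HU, two ellipsoidal lungs whose voxels draw from a
configurable compartment mixture (uniform within each compartment's HU
range by default — no in-compartment distribution is recorded for real
lungs, so uniform is the least-informative choice; Gaussian and fixed
values are available), optional Gaussian HU noise, an optional
water-bottle cylinder in the air beside the body, an optional dense
lesion labeled opacified, a configurable number of out-of-window
(+250 HU) voxels, and a partial-volume rim: the outermost `rimWidth`
voxel layers blend linearly toward the neighbouring tissue (+40 HU for
lung, -1000 HU air for the bottle), reproducing the boundary artefact
that the -350 HU rule targets. Ground truth is bookkept by direct
summation over the assigned pre-noise HU field — an independent code
path from `summarizeAeration()` — so phantom tests are genuine
two-route cross-checks: 127,992-voxel phantoms reproduce ground-truth
mass to machine precision without noise and to about 0.3% at 20 HU
noise (the residual comes from noise pushing boundary-bin voxels out of
the analyzable window).

What phantoms do *not* model: anatomy (airways, fissures, hila),
scanner physics (beam hardening, reconstruction kernels), gravitational
density gradients, and contrast kinetics. Passing phantom tests
therefore demonstrates the correctness of the arithmetic and the
behaviour of the pipeline under controlled violations (noise, rims,
out-of-range voxels) — not clinical performance on real scans.

**Cohorts**: `makeReferenceCohort()` draws heights and sexes, then lung
mass from the generative regression $M_{lung} = \beta_0 + 7.2\,height
- 88.6\,[female] + \varepsilon$ with a median-zero right-skewed
(shifted lognormal, shape 0.4) or Gaussian residual; the intercept and
residual scale are calibrated once from the population targets (median
885 g, IQR 771–973 g) and the predictor spread, and every generative
parameter is recorded in an attribute. `makeAliCohort()` mixes an
atelectasis-range component (lognormal around 899 g, hard-truncated at
the reference cut) with an above-reference component (around 1398 g,
truncated above the cut) at a fixed mixture fraction (default 46/78),
with correlated lung volume, nonaerated percentage and support-free
days per component calibrated to the printed subgroup medians; true
component labels ride along for oracle comparisons. All generators are
pure functions of their parameters and seed, and they save and restore
the caller's RNG state.

# Numerical choices and degenerate inputs

* Totals are sums of parts: compartment masses sum to $M_{lung}$
  exactly, subgroup counts to the cohort size.
* Empty masks, all-out-of-window masks, constant reference samples,
  collinear regression blocks, nonpositive agreement pairs, and heights
  of at most 100 cm are all hard errors or explicit degenerate results
  (a constant sample yields the degenerate interval $(c, c)$ with a
  warning), never silent NAs.
* Zero MAD with non-constant data falls back to SD standardization
  with a warning.
* NIfTI-1 stores voxel spacing as 32-bit floats; the raw+JSON sidecar
  dialect round-trips doubles exactly and exists for that reason (and
  for dependency-free fixtures). Cohort CSVs are written at 17
  significant digits so doubles survive a round trip.
* Simulation sizes used by the test-suite checks — a ~128,000-voxel
  phantom for the mass oracle, 100 random phantoms for conservation,
  500 replicates for interval coverage, 200 for regression recovery —
  were chosen to estimate each quantity to well within the tolerance
  it is judged against while keeping the whole suite fast to run
  routinely.

# Known limitations

* The compartment boundary convention at non-integer HU is ours; an
  implementation using closed integer bins will disagree for HU in the
  half-unit gaps.
* The robust-interval constants follow the Horn/Pesce construction;
  other C28-A3-compliant software may use different multipliers, so
  limits can differ by a few percent at small $n$.
* The band width of the boundary refinement (2 voxels) has no
  counterpart in the manual procedure it replaces; how far manual
  corrections reached is unknown.
* Cohort generators approximate printed summary statistics; they make
  no claim to reproduce patient-level data, and analyses of synthetic
  cohorts validate the pipeline, not the epidemiology.
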