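---
title: "Count-based SBR quantification: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based SBR quantification: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datSBR)
```

## The quantity being estimated

In dopamine-transporter SPECT with [123I]FP-CIT, striatal voxels carry both
specific binding and the nonspecific tracer concentration present everywhere
in brain tissue. The specific binding ratio

$$\mathrm{SBR} = \frac{C_\mathrm{st} - C_\mathrm{bg}}{C_\mathrm{bg}}$$

normalises the specific striatal concentration $C_\mathrm{st}-C_\mathrm{bg}$
by the nonspecific level $C_\mathrm{bg}$, making it independent of injected
dose, scan duration and global scaling. The occipital cortex serves as the
reference region: it is nearly devoid of dopamine transporters and, being a
large cortical territory, relatively insensitive to partial-volume effects.

All concentrations in this package are per mL. The background VOI yields a
mean count per voxel, converted with the voxel volume
$v_\mathrm{mL} = \prod_i s_i / 1000$ (spacing $s_i$ in mm). This is the one
dimensionally consistent reading of the defining equation, and
`SbrResult` objects record both the per-voxel mean and the per-mL
concentration so the equivalence stays visible.

## Fixed-volume striatal VOI extraction

The estimator's central idea is to fix the striatal VOI's *size* a priori at
the average striatal volume $V_s = 11.2$ mL and let only its *position and
shape* adapt to the image:

1. `voxelCountForVolume()` converts $V_s$ to a voxel budget
   $n = \mathrm{round}(V_s \cdot 1000 / v_{\mathrm{mm}^3})$, nearest integer
   with ties away from zero. At 2.2 mm isotropic spacing,
   $11200 / 10.648 = 1051.84 \to n = 1052$.
2. The trapezoid search region `VOI_t` is split into hemisphere halves at the
   centroid of the mask along the left–right axis (`splitHalves()`); a voxel
   exactly on the midline plane goes to the right half. Which end of the axis
   is "right" is configuration (`rightIsLow`), never inferred from the data,
   because scanner orientation conventions differ.
3. For each side — right first, then left — `findPeak()` locates the maximum
   count voxel in the half, and `growFixedVolume()` grows a region from that
   seed by repeatedly admitting the highest-valued voxel of the half that
   neighbours the current region, until exactly $n$ voxels are included. The
   result is connected by construction and nested in any larger budget grown
   from the same seed.

### Interpretation of "consecutive high-intensity voxels"

The growth rule is the package's operational reading of extracting a
*connected cluster of the top-$n$ voxels around the peak*. A plausible
alternative — the global top-$n$ voxels of the half with no adjacency
constraint — is available as `mode = "top_n_unconstrained"` for comparison,
but it can fragment across noise spikes and is not the default.

Growth is confined to the side's half of `VOI_t`. In lateralized low-uptake
cases the affected side's residual contrast is small, and growth allowed to
roam the whole search region will creep toward the brighter contralateral
striatum; confinement keeps the mask centred on its own striatum (the
phantom tests quantify this: centroid drift stays well under 2 voxels up to
12 mm FWHM). With `allowOverlap = FALSE` (default) any voxel already claimed
by the right mask is additionally removed from the left search region.

### Determinism

Every tie — peak selection, growth order, equal-valued frontier voxels —
breaks lexicographically by $(k, j, i)$, smallest first, which in
column-major storage is simply the smallest linear index. Identical inputs
therefore give bit-identical masks on every run and machine: the package's
operationalization of inter-operator reproducibility. The growth kernel is
implemented in C++ with a priority queue; an independent best-first oracle
written in plain R (recomputing adjacency from scratch each step) checks it
exhaustively on small grids in the test suite.

### Error handling

If fewer than $n$ voxels are reachable from the seed, extraction fails with
the reachable count rather than returning a smaller mask — a silently
truncated mask would change the meaning of the fixed-$V_s$ denominator.
Misaligned mask/volume pairs are refused everywhere; nothing is resampled.

## The two SBR estimators

**Count-based** (`sbrCountBased()`):
$C_\mathrm{st} = (\text{total VOI}_\mathrm{st}\ \text{count}) / 11.2$ per mL.
The divisor is the nominal 11.2 mL, not the realized mask volume
($1052 \times 0.010648 = 11.2017$ mL); the difference is a fixed factor of
$\le 0.02\%$ and is documented rather than corrected.

**Tossici-Bolt** (`sbrTossiciBolt()`): with a large fixed-geometry VOI
(default: elliptical cylinder, in-plane radii 26 × 36 mm, 44 mm axial
thickness — only the thickness is canonical; any geometry that captures all
striatal counts satisfies the method's assumption),

$$\mathrm{SBR}_\mathrm{Bolt} = \frac{Q_\mathrm{voi}/C_r - V_\mathrm{voi}}{V_s}
 = R\left[\frac{C_\mathrm{voi}}{C_r} - 1\right], \quad R = \frac{V_\mathrm{voi}}{V_s}.$$

`tbIdentity()` evaluates both printed forms; they agree to $10^{-10}$
relative tolerance (they are the same expression algebraically; the check
guards the implementation, and the test suite sweeps it over random
volumes). Because the method is count-conserving it is nearly insensitive to
resolution — and because $R$ is large (≈11 at the default geometry), any
error in the reference concentration is amplified $R$-fold, which is the
mechanistic source of its larger dispersion.

Per-study summaries: `bilateral_mean` is the arithmetic mean of the side
SBRs; `dominant` is the *lower* side SBR, i.e. the more affected hemisphere.
The latter is an interpretation — "dominant side" has no standard
operational definition — chosen because disease severity tracks the larger
deficit.

## The phantom generator

`generatePhantom()` emulates a reconstructed DaT study, not the acquisition:

* **Striata**: one ellipsoid per side, semi-axes (10, 20, 13.37) mm — the
  continuous volume is $\tfrac{4}{3}\pi \cdot 10 \cdot 20 \cdot 13.37 =
  11.2$ mL, and at 2.2 mm spacing the discrete support is 1052 voxels at the
  default centres, matching the standard volume. Centres sit ±25 mm from
  the grid midline, a typical inter-striatal separation.
* **Activity**: background $B$ everywhere, $B(1+\mathrm{SBR})$ inside the
  pre-blur supports. Default $B = 30$ counts/voxel, a realistic occipital
  count density for a clinical-length acquisition on a 2.2 mm grid.
* **Resolution**: separable Gaussian PSF, default 10 mm FWHM
  ($\sigma = \mathrm{FWHM}/2.3548$), typical for [123I] brain SPECT with
  parallel-hole collimators; kernels truncated at $4\sigma$ with
  row-renormalised borders so a constant field is preserved exactly and
  sources $\ge 3\sigma$ from the grid edge conserve their counts to
  within 0.1%.
* **Noise**: Poisson at the image level, applied after the blur (resolution
  is a detector/reconstruction property; counts are treated as Poisson in
  image space). This is a simplification relative to projection-domain noise
  plus reconstruction: real reconstructed noise is spatially correlated,
  which the phantom does not reproduce. The generator saves and restores the
  global RNG state, so phantom creation never perturbs a caller's random
  stream.

`generateCohort()` draws ground-truth SBRs uniformly from per-group
intervals (defaults: abnormal 0.5–1.5, normal 2.5–3.5, bracketing typical
patient and control ranges) with per-subject seeds derived from one master
seed; `rightScale < 1` produces lateralized, "dot pattern"-like cases.

What passing phantom tests do **not** show: robustness to scatter and
attenuation residuals, correlated reconstruction noise, anatomical
variability (caudate/putamen substructure, atrophy, ventricular
enlargement), or head tilt. The phantom validates the *estimator logic*, not
the imaging chain.

## Evaluation statistics

`cvValue()` (sd/mean, $n-1$ denominator), `varianceRatioTest()` (two-sided F
test via `var.test`; sidedness is a documented choice),
`rocAnalysis()` (empirical ROC via pROC; AUC equals the Mann–Whitney
statistic, kept as an explicit test oracle; cutoff by the Youden index,
which is one defensible reading of "determined by ROC analysis"), and
`methodAgreement()` (OLS of Tossici-Bolt on count-based values plus Pearson
r). Formal AUC comparison between methods uses a paired subject-level
bootstrap (`aucDiffTest()`) rather than a χ² statistic, whose exact recipe
is not standardised. Routine group-difference ANOVA is deliberately out of
scope — base R provides it.

## Numerical conventions, in one place

* Voxel indices are 1-based $(i, j, k)$, `i` the hemisphere axis by default.
* Geometry membership is voxel-centre inclusion, boundary inclusive
  (trapezoids, ellipsoids, cylinders alike); rasterization is checked
  against an independent triangle-area oracle in the tests.
* Voxel-budget rounding: nearest integer, ties away from zero.
* All tie-breaks: lexicographic $(k, j, i)$.
* Background box default: 2 slices thick, placed ≈48 mm posterior of the
  striatal centres — far enough that a ≤12 mm FWHM PSF cannot carry
  striatal counts into it.
* NIfTI pixdim is float32; spacings are snapped to 7 significant digits on
  read so that write/read round trips preserve typical mm spacings exactly.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run phantoms on 64×64×32 grids at
2.2 mm — the striata, their blur margins and the background box all fit with
room to spare, and the physics is scale-free in grid extent. Monte-Carlo
checks use 50 noise realizations; the mixed cohort uses 24 subjects. The
`PhantomSpec` default remains the clinical-format 128×128×64 grid.

## Known limitations

* The greedy reading of "consecutive high-intensity voxels" is one of two
  defensible interpretations; both are implemented, only greedy is default.
* SBR values from the count-based method compress toward zero with
  increasing PSF width (spill-out from the fixed small VOI); comparisons
  across scanners with different resolution need harmonised reconstruction.
* No partial-volume correction, no atrophy/CSF correction, no alternative
  reference regions beyond "any user-supplied mask".
* The phantom's single-ellipsoid striata cannot reproduce selective
  putaminal loss within one side's mask; lateralized cohorts approximate the
  dot-pattern regime instead.
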