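---
title: "Detection limits for radiolabeled-cell PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection limits for radiolabeled-cell PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petlimit)
```

## The problem

Directly labeling therapeutic cells (e.g. T cells) with zirconium-89 via
[⁸⁹Zr]Zr(oxinate)₄ makes them visible on clinical PET for days — ⁸⁹Zr has a
78.4 h half-life and residualizes inside cells. Whether a given dose of
cells is *detectable*, and how faithfully the image *quantifies* the
activity they carry, depends on the interplay of cell number, per-cell
label loading (specific activity, SA, kBq per 10⁶ cells), local cell
density (CD, 10⁶ cells/mL), scanner resolution, and background. This
package implements the well-plate analysis of those questions end to end:
a synthetic-phantom generator plays the role of the scanned plates, and
the same quantification and inference code runs on simulated or real
(NIfTI + CSV) inputs.

## Phantom and image-formation model

A plate is a set of wells at fixed layout coordinates: 6-well plates with
cylindrical wells (34 mm diameter, 5 mm suspension depth) and a 3 × 3
plate of 1 cm³ cubic wells. Each well carries
`truth_kBq = cell_number × SA / 10⁶`.

Ground truth is rasterized on a 1 mm isotropic grid by uniform fill:
a voxel belongs to a shape iff its center lies inside, axial and cube
extents are half-open `[lo, hi)` (so a 10 mm cube on a 1 mm grid always
covers exactly 1000 voxels), and the circular cross-section uses a strict
inequality on the squared radius. Each well's activity is divided equally
over its member voxels, making conservation exact by construction.

Image formation is deliberately minimal — it reproduces only the
statistical structure the downstream analysis relies on:

1. **Blur**: separable Gaussian PSF, applied in continuous kBq/mL space.
   The discrete kernel is truncated at 3.5 σ and renormalized, so its
   columns sum to exactly 1 away from the array edge; with the default
   18 mm grid padding (≥ 3 FWHM) total activity is conserved to well
   within 0.1%.
2. **Background**: a uniform concentration added inside the plate support
   (the plate's bounding box plus a 6 mm axial margin), zero outside,
   mimicking air around the plate.
3. **Noise**: expected counts per voxel = concentration × `noise_scale`,
   one Poisson draw, conversion back to kBq/mL. This yields the
   variance-proportional-to-mean property that the background analysis
   assumes, without modeling randoms, scatter, attenuation or
   reconstruction.

All stochastic steps are pure functions of (inputs, seed).

## Quantification

Wells are quantified with VOIs matching the experimental convention:
cylinders of the well diameter whose height is the fill depth plus a 6 mm
margin (a deterministic stand-in for selecting all contiguous slices that
contain signal), or 1 cm³ cubes. Background VOIs are auto-placed at the
empty well positions (6-well) or between the well grid and the case
(cubic plate). Total activity is the VOI mean concentration times the VOI
volume; the detectability statistic is

$$\mathrm{CNR} = \frac{\mu_\mathrm{well} - \mu_\mathrm{background}}{\sigma_\mathrm{background}},$$

with one pooled background SD per plate (pooling, rather than averaging
per-VOI SDs, is the convention adopted because the statistic is defined
over "the background VOIs" jointly). Negative CNRs are retained; a
`clip_cnr_at_zero` flag reproduces the convention of reporting ranges that
start at 0. If the background is perfectly flat (σ = 0, possible only in
noiseless phantoms) CNR is reported as `NA` rather than failing, so exact
conservation checks can still run.

## Lower limit of detection

`estimate_lld()` follows a two-regression procedure: (1) ordinary least
squares of CNR on SA over all unexcluded wells; (2) the detection
threshold is the upper bound of the two-sided 95% confidence interval of
the *mean response* at SA = 0 — the largest CNR plausibly produced at
vanishing label, the most conservative reading of an "upper 95% CI limit
on CNR". (3) That threshold is inverted through the CNR-vs-cell-number
regression to give the LLD in cells, and (4) through the CNR-vs-SA
regression to give the SA at the limit. The Rose rule variant replaces the
threshold with CNR = 5 (inclusive boundary).

Two choices here were genuinely open and are exposed as arguments:

* the CI evaluation point (`lld_ci_at`, default 0), since "the upper CI
  limit on CNR" does not pin down where along the regression it is read;
* the regression direction is CNR-as-response throughout; the alternative
  readings are supported simply by passing swapped columns.

A mean-response CI (not a prediction interval) is used: the threshold is
meant to bound the *expected* CNR of an unlabeled well, not a single
realization.

## Detection probability and non-specific background

Detection flags (Rose criterion) feed a binomial logistic regression on
cell number. Cell numbers are internally standardized for stable
optimization, and complete separation — common when nearly every well is
detected — is caught (glm warning, non-convergence, or saturated
coefficients) and refitted with a small ridge penalty (10⁻⁴ on the
standardized scale), flagged `separation = TRUE` rather than failing
silently.

Tissue background from label leakage is modeled by re-evaluating each
included well at background fractions f = 0.10, …, 0.80 of its own
(background-corrected) concentration, with
$\sigma_b = \sqrt{k\, f\, \mu_\mathrm{well}}$ from the Poisson noise model.
The calibration constant k (image-unit variance per unit mean) defaults to
1, treating image values as count-rate equivalents; when measured
background statistics are available, `estimate_poisson_k()` estimates
k = σ²/μ from them, which keeps the simulated noise consistent with the
images the wells came from. With 31 included wells this yields
31 × 8 = 248 synthetic datasets; per-well CNR over f follows
$\mu(1-f)/\sqrt{k f \mu}$ exactly and is strictly decreasing. One logistic
curve is fitted per fraction (single-class fractions are flagged
inestimable), and the cell number at 90% detection probability summarizes
each. The underlying 90%-point is monotone in f; the *fitted* per-fraction
estimates on ~31 wells can wiggle, which is why the package's own checks
assert the exact per-well monotonicity plus a strong rank trend of the
fitted 90%-points, rather than strict sample-path monotonicity.

## Recovery-coefficient model

For cubic wells, RC = (measured − measured background) / known activity.
The model

$$RC_{ij} = a\,\ln(CD_{ij}\cdot SA_{ij}) + \gamma_0 + u_i + \varepsilon_{ij}$$

is fitted by maximum likelihood (`lme4`), with a shared slope and scanner
random intercepts $u_i$. The log is **natural**: inverting the reported
two-digit fit (a = 0.11, γ₀ = 0.57) at RC = 1 and SA = 5.3 gives
≈ 9.4 × 10⁶ cells/mL, consistent with the ≈ 8.8 × 10⁶ obtained before
coefficient rounding, whereas a base-10 reading gives ≈ 1.5 × 10⁹ — three
orders too high to be meaningful. With only two scanner groups the
random-intercept variance frequently collapses to zero; the documented
fallback then estimates $u_i$ as per-scanner intercept deviations from a
fixed-effects fit, shrunk by an empirical-Bayes factor
$\max(0,\,1 - \hat\sigma^2 \overline{1/n_g} / \overline{d^2})$, and flags
`method = "shrunk"`. RC predictions are never clipped to [0, 1]; noisy
measurements legitimately exceed those bounds and out-of-range predictions
carry a flag instead.

`density_for_rc()` inverts the fit exactly:
$CD = \exp((RC^\ast - \gamma_0 - u_i)/a)\,/\,SA$.

## Generator defaults and what they emulate

The default `study_config()` reproduces the design of the in vitro study
this analysis targets:

| Parameter | Default | Why |
|---|---|---|
| experiments / plates | 6 experiments, 12 six-well plates per arm | 36 loaded wells per scanner arm |
| nominal cell levels | medians 1.08 × 10⁶ / 1.45 × 10⁵ / 8.5 × 10⁴ | reported level medians |
| level jitter | log-normal, sdlog 0.75 | reproduces the reported per-well activity span (≈ 0.02–16 kBq) and the observed within-level spread |
| specific activity | log-uniform 0.43–31.91 kBq/10⁶ cells | studied SA range |
| QC exclusions | 5 wells | reported exclusions (pipetting/counting failures) |
| well counter CV | 2% | typical gamma-counter repeatability |
| PSF FWHM | 6 mm (PET/CT), 5 mm (PET/MRI) | plausible clinical reconstructions; placeholders, surfaced in config |
| background | 0.002 kBq/mL inside the plate support | near-empty field of view |
| noise scale | 1000 counts per (kBq/mL·voxel) | places CNRs in the observed 0–~2000 range |
| cubic plate | 9 wells spanning CD ≈ 0.03–1.1, SA ≈ 0.14–31 | reference loading pattern |

Reconstructed resolution and noise level of the real scanners are not
public; FWHM and `noise_scale` are explicit configuration values, not
claims about the hardware.

**What the generator does *not* emulate.** The formation model is linear
and unbiased, so the expected recovery coefficient does not depend on
CD·SA — the empirically observed improvement of RC with activity
concentration arises from reconstruction physics (non-negativity,
low-count bias, scatter handling) that is deliberately out of scope.
Likewise the synthetic images are perfectly registered, have no
attenuation or randoms, and produce cleaner image-vs-counter correlations
(r ≈ 1) than physical scans (r ≈ 0.85). Passing tests therefore validate
the *analysis chain*, not scanner physics: RC dependence on resolution is
reproduced (recovery falls with increasing FWHM), RC dependence on count
density is not.

## Numerical choices

* Voxel membership: center-in-shape; half-open box extents; strict
  circular boundary. World coordinates are in mm and refer to voxel
  centers.
* Blur kernel: truncation at 3.5 σ, renormalized; exact column sums inside
  the padded margin.
* Degenerate inputs: σ_b = 0 gives CNR `NA` (quantification still
  returns activities); single-class detection data is an explicit
  "inestimable" error (or flag, per fraction); CD·SA ≤ 0 is a domain
  error; non-positive regression slopes give a "no finite LLD" error
  rather than a negative limit.
* Logistic separation: ridge 10⁻⁴ on the standardized scale; saturation
  detected at |η| ≥ 15.
* Problem sizes in the package's own checks: the full default study
  (12 plates × 2 scanners on ~165 × 122 × 42 voxel grids) for end-to-end
  properties; 200 seeded replicates at n = 5000 (logistic) and n = 120
  (recovery model) for parameter-recovery bias; 50 random tables for the
  LLD oracle equivalence. These sizes make the Monte-Carlo bounds tight
  while keeping a full run in tens of seconds.

## Known limitations

* Empirical RC trends with CD·SA require a nonlinear reconstruction model
  (see above); the package models empirical RC only.
* The LLD depends on the CI evaluation point and regression direction
  where the procedure is ambiguous; both are configurable, and the
  defaults are the conservative readings.
* Background VOI placement for the cubic plate (between grid and case)
  assumes the support region receives the same background level as the
  wells; a spatially varying background would require a measured map.
* The decay helpers use the exact exponential for ⁸⁹Zr
  (`decay_factor(168)` ≈ 0.226 remaining after 7 days); activities are
  compared at a common reference time that must be chosen explicitly.
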