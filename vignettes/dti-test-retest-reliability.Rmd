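---
title: "Quantifying test-retest reliability of DTI metrics with dtiretest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying test-retest reliability of DTI metrics with dtiretest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiretest)
```

## The problem

Diffusion tensor imaging (DTI) summarises water diffusion in each voxel by
a symmetric positive-definite 3×3 tensor $D$, from which four scalar
metrics are derived: fractional anisotropy (FA), mean diffusivity (MD),
axial diffusivity (AD) and radial diffusivity (RD). Longitudinal studies of
neurodegeneration — for example in early Huntington's disease, where DTI is
a candidate progression biomarker — can only detect within-subject change
if the scan-rescan (within-subject) variability of these metrics is small
relative to between-subject variability. The ratio of those two variance
components is the intraclass correlation coefficient (ICC), the standard
reliability index.

`dtiretest` implements the complete repeated-measures reliability analysis
as a tested pipeline: it simulates paired diffusion-weighted cohorts with
*known* reliability structure, fits the diffusion tensor per voxel, derives
the four scalar metrics, extracts region means, and estimates reliability
per region and per voxel via variance components, ICCs with delta-method
confidence intervals, and Bland-Altman agreement statistics. Because the
simulator's ground truth is known analytically, every statistical stage can
be validated by parameter recovery rather than by eye.

## The signal and measurement model

A diffusion-weighted acquisition measures, per voxel and gradient direction
$g_i$ (unit vector) with weighting $b_i$ (s/mm²),

$$ S_i = S_0 \exp(-b_i\, g_i^{T} D\, g_i), $$

the mono-exponential Stejskal–Tanner model. The default scheme is 42
directions at $b = 1000$ s/mm² plus 7 $b = 0$ volumes, a clinically typical
3T protocol; directions are placed deterministically by a spherical
Fibonacci lattice (minimum pairwise separation ≈ 27° at 42 directions).
Magnitude MR noise is Rician: the recorded value is
$|(S + n_1) + i\,n_2|$ with $n_1, n_2 \sim N(0, \sigma^2)$, which
positively biases low-SNR magnitudes — visible in the phantom as a small
upward FA bias in isotropic regions.

Tensor estimation follows the standard two-stage chain. A log-linear
ordinary least-squares fit of $\ln S$ on the 7-column design
$[1, -b g_x^2, -2b g_x g_y, -2b g_x g_z, -b g_y^2, -2b g_y g_z, -b g_z^2]$
initialises a Levenberg–Marquardt nonlinear least-squares fit of the
signal-domain objective $\sum_i (S_i - S_0 e^{-b_i g_i^T D g_i})^2$,
jointly over the six tensor components and $S_0$. From the sorted
eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$:

$$ \mathrm{AD} = \lambda_1,\quad
   \mathrm{RD} = \tfrac{1}{2}(\lambda_2 + \lambda_3),\quad
   \mathrm{MD} = \tfrac{1}{3}(\mathrm{AD} + 2\,\mathrm{RD}),\quad
   \mathrm{FA} = \sqrt{\tfrac{3}{2}}
     \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}
          {\sqrt{\sum_i \lambda_i^2}}. $$

FA is 0 for an isotropic tensor and 1 in the single-eigenvalue limit; MD is
computed as $(\mathrm{AD} + 2\,\mathrm{RD})/3$ so that identity holds to
the last bit.

## The reliability statistics

For a region (or voxel) measured twice in $n$ subjects, the one-way
random-effects model $x_{ij} = \mu + a_i + e_{ij}$ gives the ANOVA
estimators

$$ \hat\sigma^2_w = \mathrm{MSW}, \qquad
   \hat\sigma^2_b = \max\!\big(0, (\mathrm{MSB} - \mathrm{MSW})/k\big),
   \qquad
   \widehat{\mathrm{ICC}} =
   \frac{\hat\sigma^2_b}{\hat\sigma^2_b + \hat\sigma^2_w}, $$

with $k = 2$ repeats. This is ICC(1,1) — one-way random effects, absolute
agreement, single measurement — appropriate because back-to-back scans are
exchangeable repeats with no rater structure. Negative between-subject
estimates are truncated at zero, so the ICC lies in $[0, 1]$; a cell with
zero total variance is reported as an explicit *undefined* flag (written
`NA`, never 0 or 1). Groups (control vs disease) are analysed separately
for ICC; Bland-Altman agreement (bias, SD of differences, limits of
agreement $\pm 1.96\,\mathrm{SD}$) pools groups.

### Confidence intervals

The large-sample (delta-method) variance of the one-way ICC estimator at
the point estimate $\rho$ is

$$ V = \frac{2 (1-\rho)^2 \, (1 + (k-1)\rho)^2}{k (k-1) (n-1)}. $$

The package's default interval applies the delta method on the
variance-stabilizing scale $z = \operatorname{atanh}(\rho)$, where for
$k = 2$ the transformed variance collapses to $1/(n-1)$; limits are
back-transformed and truncated to $[0, 1]$. This choice was made by
coverage simulation: at $n = 12$ and true ICC 0.8 the plain Wald interval
$\rho \pm z_{1-\alpha/2}\sqrt{V}$ covers only ≈ 90.5% (20,000 replicates,
under both the package's generative kernel and the pure normal one-way
model), while the variance-stabilized interval reaches ≈ 94.5% of its
nominal 95%. The Wald form remains available as
`icc_ci_delta(..., scale = "linear")`. With fewer than 3 subjects the
interval is omitted and flagged.

Design choices worth stating explicitly: ICCs are not adjusted for age or
sex; no multiple-testing correction is applied (estimates and intervals
are reported, not hypothesis tests); the mean ICC across regions in
`reliability_summary()` is unweighted by region size.

## The synthetic cohort: what it emulates

`generate_cohort()` builds a two-group repeated-measures cohort — by
default 12 controls and 10 disease subjects, each with two back-to-back
49-volume acquisitions — on a small voxel grid (20×20×10) holding six
regions: bilateral caudate and putamen (near-isotropic grey matter), a
cerebral white-matter slab and a corpus callosum block (strongly
anisotropic, principal axes along y and x respectively). Eigenvalues are
physiological (e.g. corpus callosum (1.70, 0.30, 0.25)·10⁻³ mm²/s,
FA ≈ 0.84; grey matter (0.85, 0.65, 0.60)·10⁻³ mm²/s, FA ≈ 0.17).

Variability enters in four places, all multiplicative and unit-mean
log-normal so positive-definiteness is preserved by construction:

* **Between-subject** — one eigenvalue scaling per subject and region,
  CV `between_subject_cv` (default 0.10, a typical biological spread for
  regional diffusivities).
* **Within-subject** — one scan-level scaling per acquisition, CV
  `within_subject_cv` (default 0.02; scanner/physiological drift between
  back-to-back scans is small, which is what makes diffusivity ICCs high).
  The magnitude of this component is deliberately a free parameter: how
  much scan-rescan drift is physiological versus instrumental is not
  established, so the simulator exposes it rather than asserting a value.
* **Anisotropy (shape)** — a common scaling of all three eigenvalues leaves
  FA *exactly* unchanged, so the two CVs above generate no FA variability
  at all. Shape factors therefore stretch the eigenvalues about their mean,
  $\lambda \mapsto \bar\lambda + (\lambda - \bar\lambda) F$, with unit-mean
  log-normal $F$ per subject (CV `anisotropy_between_cv`) and per scan
  (CV `anisotropy_within_cv`), defaulting to half the corresponding main
  CV. This transform preserves the trace, hence MD, *bitwise* — so the MD
  variance calibration below is untouched — while giving FA a realistic
  reliability structure. Near-isotropic regions are barely affected, which
  reproduces the empirically lower FA reliability of grey matter.
* **Rician noise** — per-voxel, per-volume, scale `rician_sigma` (default
  2 at $S_0 = 100$, i.e. SNR 50 in the non-diffusion-weighted volumes).

The disease group's mean eigenvalues are raised by `hd_md_shift` (+10%
diffusivity), flattened towards isotropy by `hd_fa_shift` (−10%) in
white-matter regions, and its between-subject CV is multiplied by
`hd_between_scale` (1.5), reflecting the greater heterogeneity of patient
cohorts.

### Exact reliability calibration

For a region-mean measurement $x_{ij} = \mu A_i E_{ij}$ with unit-mean
log-normal factors, $\sigma^2_b = \mu^2 c_b^2$ and
$\sigma^2_w = \mu^2 (1 + c_b^2) c_w^2$, so the population ICC is

$$ \mathrm{ICC} = \frac{c_b^2}{c_b^2 + (1 + c_b^2)\, c_w^2} $$

(`implied_retest_icc()`); `cv_within_for_icc()` inverts this to hit a
target ICC exactly. At the defaults-adjacent calibration $c_b = 0.10$,
$c_w = 0.05$ this gives ICC $= 0.798$. `simulate_retest_series()` exposes
this kernel directly — the same draws the image simulator uses — so
large-$n$ recovery and coverage experiments run in milliseconds instead of
simulating volumes.

### Reproducibility structure

One global seed; every subject, scan, noise realisation and pipeline stage
derives its own sub-stream seed by hashing the global seed with string
labels (subject id, repeat index, stage name). Consequences: identical
configurations are bit-identical, and *adding subjects never changes the
data of existing subjects*. Stream assignment likewise keys on the subject
id, so permuting subject order changes nothing.

### What the phantom does not emulate

No motion, eddy currents, susceptibility distortion or ghosting; no image
registration (the phantom is generated in voxelwise correspondence, so the
statistical machinery downstream of registration is exercised without it);
no realistic brain geometry, partial-volume mixing at region borders, or
crossing fibres; no T1 segmentation (labels are simulator-provided).
Passing tests therefore validate the *statistical* pipeline — tensor
estimation, region extraction, variance components, intervals — not the
registration-dependent steps of a scanner study, and reliability estimates
on real data will additionally reflect registration error and artefact
variability that the phantom deliberately omits.

## The two-stream study design

`run_study()` reproduces the full study logic: each subject's two scans
are randomly split (seeded per-subject fair coin) into two independent
analysis streams so that acquisition order cannot influence results; all
procedures — tensor fitting, the per-stream mean-FA template, region
extraction — are carried out per stream; the reliability layer then
compares stream A against stream B. White-matter atlas-style regions are
averaged only over voxels where the *stream's own* FA template strictly
exceeds 0.2 (partial-volume guard; the template is recomputed per stream,
consistent with the streams being fully independent); grey-matter
T1-segmentation-style regions are never thresholded. A configurable subset
of controls can be excluded from the T1-style regions to reproduce
reduced-sample analyses. Voxelwise ICC maps are produced for all four
metrics in each group, over the labelled foreground.

## Numerical choices

* **Signal flooring**: magnitude signals ≤ 0 (possible under noise) are
  floored at $10^{-6}$ × mean $b_0$ signal before the log transform.
* **Negative eigenvalues** from noisy fits are clamped to 0 for metric
  derivation only; the stored tensor field keeps the unclamped estimates.
* **Default mask**: voxels whose mean $b_0$ signal exceeds 10% of the
  volume's 99th-percentile mean $b_0$ signal — deterministic background
  removal without an anatomical mask.
* **Optimizer**: Levenberg–Marquardt (minpack.lm) with analytic Jacobian,
  tolerances $10^{-10}$, 200 iterations maximum; non-convergence returns
  the best iterate flagged `converged = FALSE` (never an error), and the
  refined objective is guaranteed never to exceed the initializer's.
* **Eigenvector determinism**: eigenvalues sorted descending; each
  eigenvector's first non-zero component is made non-negative.
* **Undefined ICCs** (zero total variance): carried as an explicit flag,
  written `NA` in tables; set to 0 and counted in voxelwise maps.
* **Voxelwise ICC** is computed by the identical scalar code path per
  voxel, so map values agree bitwise with a per-voxel loop.

## Problem sizes

The package's own experiments are sized for a desk run: the default study
(22 subjects × 2 scans × 49 volumes on a 20×20×10 grid, ~620 foreground
voxels) completes in well under a minute; recovery experiments use the
region-mean kernel at $n$ up to 500 subjects × 200 replicates; coverage
experiments use 1,000 simulated cohorts of $n = 12$. Tensor-fit round-trip
validation covers 1,000 random positive-definite tensors under the full
49-volume scheme.

## Known limitations

* ICC(1,1) is the only reliability model; no between-scanner or multi-site
  designs, and no two-way (rater) models.
* The delta-method interval is evaluated at the point estimate; exact
  F-based intervals are not implemented.
* The phantom's regions are homogeneous boxes and spheres; partial-volume
  and registration effects — prominent contributors to real-data
  unreliability, especially near ventricles — are out of scope.
* $S_0$ is estimated jointly with the tensor in the nonlinear fit (not
  fixed at the $b_0$ mean); comparisons with pipelines that fix $S_0$
  should keep this in mind.
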