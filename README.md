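# dtiretest

Test-retest (scan-rescan) reliability analysis for diffusion tensor
imaging (DTI), for imaging statisticians and neuroimaging methodologists
who need to know whether a DTI protocol is reliable enough to measure
longitudinal change — e.g. in progressive disorders such as Huntington's
disease, where diffusion metrics are candidate progression biomarkers.

The package provides, as one tested pipeline:

* a **synthetic cohort simulator**: two-group repeated-measures
  diffusion-weighted cohorts (NIfTI-1 volumes + FSL `bvals`/`bvecs`) with
  known ground-truth tensors, configurable between-subject and
  within-subject (scan-rescan) variance, and Rician noise;
* **tensor fitting**: per-voxel log-linear initialisation refined by
  Levenberg–Marquardt nonlinear least squares on the Stejskal–Tanner model
  S = S₀·exp(−b·gᵀDg), with FA/MD/AD/RD scalar maps;
* **region statistics**: label-region means with strict template-FA > 0.2
  thresholding of white-matter atlas regions;
* the **reliability layer**: one-way random-effects variance components
  (σ²_b, σ²_w), ICC(1,1) = σ²_b/(σ²_b + σ²_w) with delta-method 95%
  confidence intervals, Bland-Altman agreement, voxelwise ICC maps, and
  leave-one-out outlier sensitivity;
* a **two-stream study pipeline** (`run_study()` and a CLI in
  `inst/cli/dtiretest.R`): each subject's two back-to-back scans are
  randomly split into two independent processing streams, analysed
  separately, and compared — with seeded, byte-reproducible outputs.

## Worked example

```r
library(dtiretest)

# Scalar metrics from a white-matter-like eigenvalue triple (mm^2/s):
m <- scalar_metrics(c(1.7e-3, 0.3e-3, 0.2e-3))
#> FA 0.836  MD 7.333e-04  AD 1.7e-03  RD 2.5e-04

# Full desk-scale study: 12 controls + 10 HD subjects, two 49-volume
# scans each, simulated, fitted, split into streams and analysed (~20 s).
res <- run_study(study_config(seed = 42), "study_out")
res$summary
#>   metric   group n_regions n_icc_ge_0.8 pct_icc_ge_0.8 mean_icc
#> 1     FA control         6            6          100.0    0.936
#> 2     FA      hd         6            5           83.3    0.915
#> 3     MD control         6            6          100.0    0.971
#> 4     MD      hd         6            6          100.0    0.953
#> 5     AD control         6            6          100.0    0.970
#> 6     AD      hd         6            6          100.0    0.952
#> 7     RD control         6            6          100.0    0.968
#> 8     RD      hd         6            6          100.0    0.954

subset(res$reliability, metric == "MD" & group == "control")[, 1:7]
#>                   region metric   group  n   icc ci_low ci_high
#>             caudate_left     MD control 12 0.982  0.942   0.994
#>            caudate_right     MD control 12 0.966  0.895   0.990
#>             putamen_left     MD control 12 0.963  0.883   0.988
#>            putamen_right     MD control 12 0.975  0.921   0.992
#>    cerebral_white_matter     MD control 12 0.966  0.892   0.989
#>          corpus_callosum     MD control 12 0.973  0.914   0.992
```

Reading the output: `mean_icc` is the unweighted mean ICC across the six
phantom regions; `n_icc_ge_0.8` counts regions at or above the
conventional 0.8 reliability threshold. An ICC of 0.97 for control MD
says within-subject (scan-rescan) variance is ~3% of total variance —
the regime in which longitudinal change detection is feasible. FA
reliability is lower in the near-isotropic grey-matter regions, where
between-subject anisotropy differences are intrinsically small.

Per-region agreement on the measurement scale comes from the pooled-group
Bland-Altman table (`res$bland_altman$table`): for corpus callosum MD the
bias is −7.1·10⁻⁶ mm²/s with limits of agreement
[−5.4·10⁻⁵, 4.0·10⁻⁵] — scan-rescan differences are an order of
magnitude below between-subject spread.

The methods vignette
(`vignettes/dti-test-retest-reliability.Rmd`) documents the generative
model, the ICC(1,1)/delta-method choices and all numerical conventions.

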