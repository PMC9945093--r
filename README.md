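# petsuvr

Reference-tissue kinetic modeling and static-window SUVR validation for
preclinical brain PET.

## What problem this solves

Quantifying radiotracer binding in the mouse brain — for example SV2A
tracers used as synaptic-density markers in APP/PS1 Alzheimer's-model mice —
usually has to work without arterial blood sampling. The standard answer is
reference-tissue modeling of regional time-activity curves (TACs) from a
90-minute dynamic scan, with a low-binding pseudo-reference region (brain
stem). Because dynamic scans are costly, a second question follows
immediately: over which late static window does the simple standardized
uptake value ratio (SUVR) best agree with the dynamic distribution volume
ratio (DVR), so that future studies can use a short static scan instead?

`petsuvr` implements that full workflow for researchers running (or
planning) small-animal PET studies:

* **Kinetics.** `fit_srtm()` fits the simplified reference tissue model
  C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·C_R ⊗ exp(−k2a·t), k2a = k2/(1+BP_ND),
  by the basis-function method (200-point log-spaced k2a grid, linear
  subproblems) with optional nonlinear refinement, returning DVR = 1 + BP_ND
  as a classed model object with `print`, `coef`, `fitted`, `residuals`,
  `predict` and `plot` methods. `fit_ref_logan()` is the reference Logan
  graphical analysis (late-time slope = DVR), with the optional C_R/k2′
  term.
* **Windows.** `compute_suvr()`, `suvr_dvr_agreement()` and
  `select_window()` quantify SUVR-DVR agreement (regression and percent
  differences) per candidate window and pick the optimal static window.
* **Group statistics.** `compare_groups()` (pooled-variance unpaired
  t-tests, WT-referenced percent differences) and an exact noncentral-t
  power solver: `required_n()` finds the minimal per-group sample size for
  a target power from Cohen's d = |Δmean| / sqrt((s1²+s2²)/2).
* **Simulation.** `simulate_cohort()` generates two-genotype cohorts of
  one-tissue-compartment TACs with realistic plasma input, frame noise and
  between-animal variability, calibrated so the wild-type hippocampal
  SUVR(60-90 min) distribution matches published values (1.47 ± 0.04).
* **Orchestration.** `run_study()` chains simulate → fit → window
  selection → group comparison → power analysis deterministically under one
  seed; `scripts/run_study.R` is a command-line wrapper.

TACs travel as plain CSV tables (`frame_start_min,frame_end_min,<region>…`)
with a JSON metadata sidecar; `extract_roi_tacs()` also pulls regional TACs
directly from a 4D NIfTI volume plus an integer label atlas.

## Worked example

```r
library(petsuvr)
report <- run_study(run_config(seed = 42L), quiet = TRUE)
print(report)
```

```
Synthetic study report (seed 42, 9 + 9 animals)
Selected static window: 60-90 min
  window slope intercept r_squared mean_pct_diff sd_pct_diff
1  60-90 0.438     0.790     0.549         -3.21        6.64
2  50-80 0.350     0.882     0.443         -5.83        7.26
3  40-70 0.281     0.940     0.382         -8.81        7.43

Group comparisons at 60-90 min (SUVR, BS reference):
   region mean_WT mean_TG pct_difference  p_value significance
...
4      HC    1.49    1.37           8.14 2.50e-04          ***
...

Power analysis (HC, d = 2.207):
  tails power n_per_group achieved_power
1     1   0.8           4          0.864
2     1   0.9           5          0.937
3     2   0.8           5          0.862
4     2   0.9           6          0.930

SUV ~ injected mass (n = 18): slope = 0.3837, r = 0.277, p = 0.265
```

Reading this: SUVRs from all three candidate windows underestimate the
dynamic DVRs (negative mean percent differences), the bias shrinks as the
window moves later, and 60-90 min is selected. At the selected window the
hippocampus shows an 8.1% lower SUVR in the transgenic group (p ≈ 2.5e-4),
and the sample-size grid says such an effect needs 5-6 animals per group at
90% power. The injected-mass check finds no association between dose mass
and brain uptake, as expected for tracer-dose injections. (The SUVR-on-DVR
slopes are attenuated below 1 by DVR estimation noise; the window ranking
uses the percent difference.)

From summary statistics alone, the power table for a published comparison:

```r
power_grid(1.47, 0.04, 1.36, 0.08)   # WT mean/sd, APP/PS1 mean/sd
#>   tails power n_per_group achieved_power
#> 1     1   0.8           5      0.8058118
#> 2     1   0.9           7      0.9218705
#> 3     2   0.8           7      0.8473119
#> 4     2   0.9           9      0.9332461
```

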