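---
title: "Reference-tissue quantification of preclinical SV2A PET: models, simulator and design choices"
author: "petsuvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-tissue quantification of preclinical SV2A PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petsuvr)
```

# The quantification problem

Synaptic vesicle glycoprotein 2A (SV2A) PET is used as an in-vivo proxy for
synaptic density. In mouse models of Alzheimer's disease (APP/PS1 versus
wild-type littermates), the quantity of interest is the regional binding of
an SV2A radiotracer, summarized as a distribution volume ratio (DVR)
relative to a pseudo-reference region. Mouse studies rarely have an arterial
input function, so quantification must rest on reference-tissue methods; and
because 90-minute dynamic scans are expensive, a central practical question
is whether a short static scan — summarized as a standardized uptake value
ratio (SUVR) over a late time window — can stand in for the dynamic DVR.

`petsuvr` implements that whole chain: reference-tissue kinetic modeling
(SRTM and reference Logan), SUVR computation and SUVR-versus-DVR agreement
across candidate windows, genotype group comparison, and exact
noncentral-*t* power analysis. A compartment-model simulator generates
realistic two-genotype cohorts so every step can be validated against a
known ground truth.

# Models

## Simplified reference tissue model

The simplified reference tissue model (SRTM) expresses a target-region
time-activity curve (TAC) $C_T(t)$ in terms of the reference-region curve
$C_R(t)$ with three parameters — relative delivery $R_1$, target efflux
$k_2$ and binding potential $BP_{ND}$:

$$
C_T(t) \;=\; R_1\,C_R(t) \;+\;
\Bigl(k_2 - \tfrac{R_1 k_2}{1+BP_{ND}}\Bigr)\,
C_R(t) \otimes e^{-k_{2a}t},
\qquad k_{2a}=\frac{k_2}{1+BP_{ND}},
$$

and $\mathrm{DVR} = 1 + BP_{ND}$. SRTM assumes one-tissue-compartment (1TC)
kinetics in both target and reference regions and a common nondisplaceable
distribution volume.

`fit_srtm()` estimates the parameters by the basis-function method (BFM):
for each candidate $k_{2a}$ on a 200-point log-spaced grid spanning
0.006-0.6 min$^{-1}$, the basis $B(t) = C_R \otimes e^{-k_{2a}t}$ is
computed by trapezoidal convolution on a fine grid and averaged within each
frame, the linear two-parameter problem
$C_T \approx \theta_1 C_R + \theta_2 B$ is solved by least squares, and the
grid point with minimal residual sum of squares wins (exact ties go to the
smallest $k_{2a}$, a deterministic rule). `method = "nls"` refines that
solution with Levenberg-Marquardt on $(R_1, k_2, BP_{ND})$ directly. BFM is
the default because the grid search cannot diverge on noisy data; the grid
quantization limits its DVR resolution to roughly $10^{-3}$ relative on
clean curves, which the NLS refinement removes. A fit whose optimum sits on
the grid edge is flagged (`boundary`) and warned about.

Least squares is unweighted by default. A duration-proportional weighting is
available (`weights = "duration"`), but under the package's frame-noise
model it performs slightly worse than unweighted fitting, because late
frames carry both long durations and decay-inflated variance.

## Reference Logan graphical analysis

For a 1TC target and reference the running-integral transform obeys the
exact identity

$$
\frac{\int_0^T C_T\,dt}{C_T(T)} \;=\;
\mathrm{DVR}\cdot
\frac{\int_0^T C_R\,dt + C_R(T)/k_2'}{C_T(T)} \;-\; \frac{1}{k_2},
$$

where $k_2'$ is the reference-region efflux rate. `fit_ref_logan()`
regresses $y(T)$ on $x(T)$ over frames with mid-time $\ge t^*$ and reports
the slope as DVR. Two points deserve emphasis:

* **The $C_R/k_2'$ term matters for slow tracers.** By default the term is
  omitted (`k2prime = NULL`), which is the form many reference-Logan
  implementations use. For tracers near equilibrium the omission is benign;
  for the slow kinetics simulated here ($k_2' = 0.04$ min$^{-1}$), the
  omitted term is a large fraction of $x$ and the slope underestimates DVR
  substantially. All internal cross-validation therefore supplies
  `k2prime`, estimated per subject as the median of $k_2/R_1$ over that
  subject's SRTM fits (`ref_k2prime()`). With the correct $k_2'$ the
  identity above is exact at any $t^*$, which the tests exploit.
* **Degenerate frames** with near-zero target activity are dropped with a
  warning; fewer than three surviving points is an error.

## SUVR and static-window agreement

`window_suv()` averages frame values over a static window, weighting each
frame by the length of its intersection with the window, so windows need
not align with frame boundaries and behave continuously as they move.
`compute_suvr()` divides by the reference region's windowed SUV; the
reference SUVR is exactly 1 and the ratio is invariant to global rescaling
(hence identical for kBq/mL and SUV inputs).

`suvr_dvr_agreement()` pools (subject, region) pairs — excluding the
reference region, where both quantities are identically 1 — and reports the
ordinary-least-squares line of SUVR on DVR together with the mean and SD of
the percent difference $100(\mathrm{SUVR}-\mathrm{DVR})/\mathrm{DVR}$.
`select_window()` ranks candidate windows by $|\text{mean percent
difference}|$, breaking ties by higher $R^2$ and then toward the later
window (later windows are closer to equilibrium, so a tie should not
prefer the earlier one). For a slow tracer the transient bias makes early
windows underestimate DVR, and the bias shrinks as the window moves later —
this is the mechanism behind choosing 60-90 min over 40-70 and 50-80 min.

One caveat the simulations make visible: the pooled SUVR-on-DVR regression
slope is attenuated by estimation noise in the DVRs (errors-in-variables),
so slopes well below 1 can coexist with a clean percent-difference
ordering. The window ranking therefore keys on the percent difference, not
the slope.

## Group comparison and power

`compare_groups()`/`compare_from_summary()` run the unpaired pooled-variance
(Student) *t*-test, two-tailed, with no multiple-comparison correction;
Welch's test sits behind `welch = TRUE`. Pooled variance is the default
because it makes summary-statistic comparisons exact and reproduces the
published group statistics. Percent differences are WT-referenced and
computed from group means.

The power machinery is exact rather than approximate: for effect size
$d = |\mu_1-\mu_2| / \sqrt{(s_1^2+s_2^2)/2}$ (the a-priori two-independent-
means convention), the power of the two-sample *t*-test at $n$ per group is
evaluated from the noncentral *t* distribution with $2n-2$ degrees of
freedom and noncentrality $d\sqrt{n/2}$, and `required_n()` returns the
smallest integer $n$ reaching the target power by increment-and-test,
certifying minimality (power at $n-1$ is below target). From the published
hippocampal SUVR moments of the three SV2A tracers this reproduces all
twelve published per-group sample sizes exactly, and Monte-Carlo *t*-tests
agree with the analytic power within sampling error.

# The synthetic cohort generator

No raw scan data accompany the study this package models, so the simulator
is the package's ground-truth source. It emulates:

* **Plasma input.** A tri-exponential bolus curve with linear rise,
  $C_p(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
  A_3 e^{-\lambda_3 t}$, with $C_p(0)=0$. Defaults
  $A = (12.6, 0.294, 0.21)$ (SUV-equivalent units),
  $\lambda = (3.5, 0.35, 0.009)$ min$^{-1}$.
* **Tissue kinetics.** Each region follows the 1TC model
  $C(t) = K_1\,C_p \otimes e^{-k_2 t}$ with shared delivery
  $K_1 = 0.45$ mL/cm$^3$/min and region-specific $k_2$; the brain stem
  (pseudo-reference) has $k_2 = 0.04$ min$^{-1}$ and true regional DVRs
  span 1.32 (cerebellum) to 1.80 (inferior colliculi), hippocampus 1.513.
  With these defaults high-binding regions peak near SUV 2.4 between 30 and
  60 min, rise through 30-60 min and wash out slowly; the brain stem is the
  lowest-uptake region. Between-animal variability and the genotype effect
  act on DVR through $k_2$ at fixed $K_1$ — a binding difference, not a
  delivery difference.
* **Cohort structure.** Nine animals per genotype by default. Each animal
  draws one lognormal DVR multiplier (mean 1) applied to every
  non-reference region; APP/PS1 animals additionally receive per-region
  multiplicative DVR reductions (hippocampus 0.087, scaled for other
  regions from the published per-region percent differences). The
  multiplier CV is genotype-specific (WT 0.0315, APP/PS1 0.067) because the
  published table shows clearly unequal dispersions (SD 0.04 versus 0.08 at
  similar means); a single shared CV cannot reproduce both.
* **Frame noise.** Independent Gaussian noise per frame with variance
  $\sigma^2_i = \alpha\,C_i\,e^{\lambda_{phys} t_i}/\Delta t_i$ — the
  standard decay- and duration-scaled model for ROI-averaged PET data.
  The default $\alpha = 0.0015$ yields roughly 2-3% noise on late 5-minute
  frames and 4-5% on the early half-minute frames.
* **Whole brain.** The WB curve is the unweighted mean of the regional
  curves, mirroring extraction from a union mask; its effective DVR is
  recorded as the mean regional DVR, which holds at late-time
  pseudo-equilibrium.

The hippocampal DVR (1.513) and the APP/PS1 reduction (0.087) were inverted
noiselessly so that the wild-type and transgenic hippocampal SUVR(60-90)
means sit at 1.47 and 1.36; the genotype CVs were then fitted so the total
SDs (biological plus frame noise) land at 0.04 and 0.08. Measured at 360
animals per group the cohorts deliver WT 1.469 ± 0.042 and APP/PS1
1.362 ± 0.083.

**What the simulator does not emulate** — and hence what passing tests do
not establish about real data: image-space effects (partial-volume
spill-over, registration error, reconstruction bias), non-1TC kinetics
(plasma metabolites, vascular fraction), genotype differences in delivery
or in the reference region itself, and attenuation/scatter residuals.
Noise is Gaussian at the TAC level, not Poisson at the sinogram level. The
simulator's kinetic rate constants are calibrated to reproduce published
summary statistics, not measured rate constants (none are published for
this tracer in mouse).

# Numerical choices

* **Time grid.** All convolutions run on a uniform grid with 0.025-min
  step; forward curves are averaged within frames through one cumulative
  trapezoid integral. At 0.025 min the 1TC forward model agrees with a
  stiff ODE solver to better than 0.2% per frame (the first half-minute
  frame, which straddles the plasma peak, is the worst case).
* **Frame convention.** Frames are half-open `[start, end)` intervals in
  minutes; all kinetic computations use frame mid-times. Schedules must be
  sorted, non-overlapping, with at least two frames. The default simulator
  schedule is 6 × 0.5, 3 × 1, 2 × 2, 16 × 5 min — 27 frames, exactly 90
  minutes, with uniform 5-min frames across all candidate windows.
* **Logan integrals** are trapezoidal over (0, frame mid-times), with the
  origin prepended.
* **Degenerate inputs.** Zero reference TACs, non-positive dose or weight,
  windows that miss the schedule, reductions outside [0, 1), and mismatched
  subject/region keys all raise informative errors; a failing region in
  `fit_subject()` is dropped with a warning instead of aborting the
  subject.
* **Reproducibility.** `simulate_cohort()` and `add_frame_noise()` restore
  the caller's RNG state and are bit-reproducible under a fixed seed.

# Problem sizes used in the validation suite

The test suite validates parameter recovery with 100-replicate noisy
refits, cross-validates SRTM against reference Logan on three pooled
default cohorts (540 region-subject pairs), checks the window-bias ordering
and 60-90 min selection over 20 independently seeded cohorts, verifies the
Monte-Carlo power agreement with $10^5$ replicated *t*-tests per table
cell, and calibrates the injected-mass null with 1000 simulated cohorts.
These sizes give each stochastic check a comfortable margin over its
acceptance threshold while keeping a full run in a few minutes.

# Known limitations

* SRTM estimates on noisy slow-kinetics data are heavy-tailed: a noisy
  reference curve can shift all of a subject's DVRs coherently by several
  percent. Pooling subjects, the NLS refinement, and the Logan
  cross-check mitigate but do not remove this.
* The reference Logan default (no $k_2'$ term) underestimates DVR for slow
  tracers; supply `k2prime` (e.g. via `ref_k2prime()`) whenever absolute
  DVR accuracy matters.
* `required_n()` assumes equal allocation and normality; it reproduces
  a-priori power-calculator conventions rather than simulating the actual
  SUVR estimator's sampling distribution.
* The whole-brain region is a TAC-level mean, so its "true" DVR is exact
  only at pseudo-equilibrium; exact-recovery tests use the elementary
  regions.
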