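---
title: "Methods: quantifying HbA1c and glucose from skin Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying HbA1c and glucose from skin Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In vivo skin Raman spectra contain weak vibrational bands of circulating
analytes — glycated hemoglobin (HbA1c) and glucose — superimposed on a
tissue autofluorescence background that is typically one to two orders of
magnitude larger, plus Poisson-like shot noise. The calibration task is to
map a 788-point spectrum (200–1800 cm⁻¹) to a reference laboratory value:
HbA1c in percent or glucose in mg/dL. A companion classification task
assigns each spectrum to a diagnostic class from the HbA1c cut-offs
(healthy < 5.7 %, prediabetes 5.7 % to < 6.5 %, T2D ≥ 6.5 %).

This vignette documents the modelling choices, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
and the numerical decisions a maintainer would want to know.

# Synthetic cohort generator

The generator (`cohort_spec()`, `generate_cohort()`) reproduces the
structure the analysis assumes rather than the physics of skin:

* **Design.** 46 subjects × 3 body sites (forearm, wrist, index finger) ×
  9 replicates; HbA1c uniform within each diagnostic class band
  intersected with 5.2–14 % (class mix 32 T2D / 10 prediabetes / 4
  healthy); glucose coupled to HbA1c by a Gaussian copula (default
  correlation 0.7, a realistic strength for fasting cohorts where both
  biomarkers reflect glycemic control) with uniform margin on 56–400
  mg/dL.
* **Grid.** Piecewise-uniform 788-point grid: 512 evenly spaced points on
  [600, 1600] plus 184 and 92 filler points on the flanks. Both window
  counts (788 and 512) are therefore exact by construction; spacing is a
  modelling choice since only the counts are fixed by the instrument
  configuration.
* **Signal model.** `intensity = baseline + Σ amplitude·G(ν; center, σ) +
  noise`, Gaussian bands with σ = 12 cm⁻¹ (typical tissue Raman width).
  HbA1c-coupled bands sit at 1536, 1230, 1114, 969, 665 and 1308 cm⁻¹,
  glucose-coupled bands at 544, 837, 1060 and 1106 cm⁻¹, and six
  concentration-independent background bands (including the 1004 cm⁻¹
  phenylalanine reference) elsewhere. Analyte band amplitude is
  `slope × concentration × site factor` — a linear response, which is an
  assumption, not an observation; in vivo responses need not be linear.
  Slopes default to values that give both analytes comparable
  signal-to-spread so that neither analyte is trivially easy nor
  hopeless at the default noise level.
* **Baseline.** A positive random degree-5 Chebyshev-basis curve per
  subject and site, amplitude 5–20× a nominal 100-count band (doubled on
  the index finger, whose collagen-rich tissue fluoresces more), with
  small per-replicate jitter. Fluorescence dominating the Raman signal by
  roughly an order of magnitude matches what skin measurements show.
* **Noise.** `sd = noise_scale · sqrt(signal)` (Poisson-like), default
  scale 2, chosen so the replicate SNR at the 1230 cm⁻¹ band lands in the
  single-digit-to-teens range, comfortably above the SNR ≥ 3 quantitation
  floor. Noise draws are consumed at every noise level (including zero)
  so cohorts at different `noise_scale` share common random numbers —
  this is what makes the monotone-degradation test well-posed.

Not emulated: skin-layer optics, instrument response, cosmic-ray spikes,
wavelength-dependent detector efficiency, or any nonlinear
concentration–intensity relationship. Passing tests on this generator
therefore demonstrate that the pipeline recovers the structure it assumes;
they do not certify performance on real tissue spectra.

# Preprocessing

**Baseline removal.** Zernike polynomials are natively two-dimensional;
for 1-D spectra we use the radial parts `R_n^m(r)` with `m = n mod 2`
(the lowest order for which they exist), n = 0..6 by default, on the
wavenumber axis mapped to [0, 1]. The baseline is the expansion minimizing
an asymmetric squared cost in which points where the baseline exceeds the
spectrum cost β = 10 times more — the standard lower-envelope heuristic
for fluorescence. Coefficients are found by a real-coded genetic
algorithm (population 60, 150 generations, tournament size 3,
single-point crossover 0.8, per-gene Gaussian mutation 0.1, elitism 1 —
sized to well under a second per spectrum). Two numerical choices matter:

* the chromosome lives in the *orthonormalized* (QR) span of the basis —
  the raw polynomial columns are strongly collinear, and searching the
  raw coefficients leaves the GA crawling a needle-shaped valley; in the
  orthonormal parameterization the same search converges to the convex
  cost's optimum (the tests verify agreement with a direct IRLS solve);
* the population is seeded around the ordinary least-squares expansion
  and shrunk copies of it, since the lower envelope lies below the OLS
  curve whenever bands are present.

Elitism makes the best fitness non-increasing by construction; the
recorded trace enforces it. The corrected spectrum is clipped at zero.

A caveat the tests document: on band-crowded spectra the *optimum* of the
asymmetric cost still rides a few counts into small bands near the
spectrum edges (a smoothness bias of any 7-degree-of-freedom polynomial
baseline, verified against the direct solve, not a GA artifact). Ratios of
strong bands — e.g. an analyte band against the 1004 cm⁻¹ reference —
are preserved to about 1 %; weak edge bands can shift by several percent.

**Smoothing.** The "filter" paired with shot-noise reduction is read as
the Whittaker–Eilers penalized smoother, the standard interpretation;
`whittaker_smooth()` solves the banded system `(I + λ DᵀD) z = y` exactly
(sparse Cholesky via Matrix). Defaults λ = 10, d = 2 — a light smoothing
role, since the baseline step handles fluorescence. Order of operations
(baseline first, then smoothing) is this package's choice; the division of
labor between the two steps is stated at the level of intent only.

**SNR.** Replicate SNR at a band is the mean intensity at the nearest
grid point across the nine replicates divided by the sample standard
deviation (n − 1) there; HbA1c is evaluated at 1230 cm⁻¹ and glucose at
1106 cm⁻¹. Identical replicates give an infinite, flagged result.

# Feature engineering

The combined recipe is **SOM first, RReliefF second**: the
self-organizing map's output keeps all features (each spectrum is
replaced by its best-matching prototype — vector quantization), and
RReliefF then reduces them. This is the only order consistent with the
representation keeping the input dimension while the selector reduces it;
the alternative readings remain available by calling the pieces directly.

* **SOM** (`som_fit`): 8×8 grid, 100 batch epochs, Gaussian neighborhood
  with radius decaying exponentially from max(dims)/2 to 0.5,
  initialization by random sample draw. An epoch whose batch update would
  increase the quantization error is rolled back, making the error trace
  monotone — a safeguard, since plain batch SOM does not guarantee
  monotonicity while the radius decays.
* **RReliefF** (`rrelieff`): the regression Relief estimator with
  Euclidean neighbors in min-max-scaled feature space, exponential
  distance-rank weights (σ = 20 ranks), and `m = n` (every instance, in
  index order) by default — deterministic and appropriate at cohort
  scale, since the instance count (414 per site) is modest. Weights lie
  in [−1, 1]; constant features get exactly 0; ties in `select_top()`
  break toward the lower wavenumber.
* The in vivo grid search explored feature counts {50, 100, 150, 200,
  512} and k from 5 to 40; `featsel_presets()` ships the reported
  per-site best settings. The pipeline default (count 50, k = 13) is a
  mid-grid setting at which, on the default synthetic cohort, both
  analytes' selections recover their own true bands. Note that k in the
  teens-to-twenties matters here: with nine near-identical replicates per
  subject, smaller k exhausts the neighbor list with same-subject
  replicates whose encodings are identical after quantization, starving
  the weight update of informative differences.

# Calibration models

The network has exactly one hidden tanh layer (5–20 units searched;
`ffnn_hidden_search` breaks ties toward the smaller network) and a linear
output for regression or softmax for classification. Inputs are min-max
scaled to [−1, 1] and targets standardized, both learned on training data
only (tanh saturation otherwise dominates); predictions are clipped at
zero, since concentrations are non-negative.

* **Levenberg–Marquardt** (regression): damped Gauss–Newton on the SSE
  with the standard Marquardt schedule — λ₀ = 10⁻³, ×10 on a rejected
  step (weights untouched), ÷10 on acceptance, stop beyond 10¹⁰. Accepted
  steps never increase the SSE, which the tests assert.
* **Scaled conjugate gradient** (Møller's algorithm): used for regression
  as an alternative trainer and exclusively for classification
  (softmax + cross-entropy), mirroring the fitting vs pattern-recognition
  toolbox split.
* **Early stopping**: an inner 15 % validation split with patience 6 —
  how validation data relate to the 3-fold scheme is not specified
  anywhere, so this package carves the split from each training fold.
* Comparison models: ε-SVR with radial kernel (e1071; hyperparameters by
  a small holdout grid; predictions reproduced from the stored support
  vectors so saved models round-trip bitwise), OLS with ridge fallback on
  rank deficiency, and PLS1 (NIPALS) including the 10-interval iPLS
  variant with per-interval component choice by cross-validation.
* Model files are versioned JSON with weights at 17 significant digits —
  enough for bitwise-identical predictions after reload.

Classification runs 20 independent 70/15/15 splits with fresh
initialization (SCG), redrawing any split that lacks a class in training,
and aggregates accuracy and one-vs-rest sensitivity/specificity.

# Evaluation

* **RMSE-CV** (`kfold_rmsecv`): random partition into near-equal folds;
  with the 414 replicate spectra of one site and k = 3 this yields the
  276-train/138-test arithmetic exactly. The reported value is the mean
  of per-fold RMSEs with their between-fold SD (not pooled residuals),
  matching how "SD between folds" is defined. Folds are replicate-level
  by default, which reproduces that arithmetic but lets subject identity
  leak across folds (replicates of one subject appear in train and test);
  grouped subject-level folds are available via the `groups` argument and
  are the right choice when generalization to new subjects is the
  question.
* **Clarke error grid** (`clarke_zone`): the canonical 1987 boundaries,
  evaluated in the order A, E, C, D, else B (inequalities documented in
  the function help). The same inequality set drives both zone assignment
  and the plot background — a single source of truth. The zone set tiles
  the positive quadrant exhaustively and exclusively, and the diagonal is
  always zone A.
* **Diagnostic metrics** (`dx_metrics`, `regression_to_dx`): one-vs-rest
  sensitivity/specificity per class in percent; a class absent from the
  truth yields NA (undefined), never 0. The HbA1c boundary band is
  resolved as prediabetes = [5.7, 6.5), T2D = [6.5, ∞) following the ADA
  "≥ 6.5 %" convention.
* Regression uses single-seed 3-fold CV with the seed exposed; whether a
  20-run protocol also applied to regression is not stated, so repetition
  is reserved for classification where it is explicit.

# Pipeline, problem sizes and limitations

`run_pipeline()` executes simulate → preprocess → SOM/RReliefF → train →
evaluate from one config with one global seed and writes every numeric
result to JSON before rendering the Markdown report, so reports are pure
functions of run artifacts and re-runs are bitwise reproducible. The
SOM + RReliefF recipe is fitted once per site and analyte on the
preprocessed spectra and the cross-validation then scores the network on
the selected features — feature engineering is treated as part of the
fixed representation, as grid-search-style protocols do; selecting inside
every fold would be stricter and is possible with the exported pieces.

Test and acceptance runs use the full 46-subject design for the wrist
site (414 spectra through preprocessing, feature engineering and 3-fold
network training, a few minutes on one CPU) and reduced designs (6–16
subjects, trimmed GA budgets) for property tests where the full scale
adds nothing.

Known limitations: linear concentration response by construction;
replicate-level folds flatter generalization estimates (see above); the
polynomial baseline's smoothness bias on weak edge bands; SOM quantization
can bury an analyte whose bands contribute little Euclidean mass when the
neighbor count is small; and none of the synthetic results transfer
quantitatively to instrument data — the deposited study data are the
benchmark for that.
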