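---
title: "Person-specific decoding of mental rotation reaction times from EEG band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-specific decoding of mental rotation reaction times from EEG band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spocridge)
```

## The modelling problem

In a mental rotation task, a participant judges whether two 3-D figures are
rotationally invariant (unmirrored) at one of several angular disparities
(0°, 50°, 100°, 150°); reaction time (RT) grows with the rotation angle.
`spocridge` implements a person-specific decoding pipeline that predicts the
single-trial RT of correct responses from the multichannel EEG recorded
between stimulus onset and the response, together with a synthetic-data
generator that plants known structure so every stage of the pipeline can be
verified by parameter recovery.

The pipeline is, per participant:

1. **Artifact removal.** An ICA decomposition is fitted on a one-minute
   eyes-open resting-state recording (after 1 Hz high-pass filtering a copy);
   artifact components — most prominently ocular blinks — are rejected by
   zeroing their rows in the unmixing step, and the cleaned channels are
   reconstructed from the raw, unfiltered task recording.
2. **Filter bank.** Ten 4 Hz-wide, Hamming-windowed, linear-phase FIR
   band-pass filters with centres 2, 6, …, 38 Hz, applied zero-phase in one
   pass with group-delay compensation.
3. **Epoching and retention.** One epoch per presentation phase (fixation
   and stimulus). Fixation epochs, incorrect or missing responses, and
   trials with RT < 700 ms are removed; the rest are cropped to the initial
   500 ms after stimulus onset. Because responses of retained trials arrive
   at ≥ 700 ms, the retained window always ends at least 200 ms before the
   response, excluding motor-preparation activity.
4. **Labels.** RTs are log-transformed (their distribution is positively
   skewed) and standardized per angle with training-set statistics, so that
   "slow for an easy stimulus" and "fast for a hard one" are comparable.
   Training epochs whose log-RT deviates from the angle's median by more
   than 2.5 × MAD are discarded before any fitting.
5. **Spatial filtering (SPoC).** Per band, the filter `w` solves the
   generalized eigenproblem `Cz w = λ C w`, where `C` is the mean epoch
   covariance and `Cz` the label-weighted mean; the eigenvector with the
   largest `|λ|` maximizes the covariance between per-epoch band power
   `w'C_e w` and the standardized label. Only this one component is kept —
   with roughly a hundred training epochs, more would overfit. Its forward
   model `a = C w / (w'C w)` is the interpretable scalp pattern.
6. **Features and regression.** The feature of band *b* and epoch *e* is the
   log variance of the spatially filtered 500-sample epoch — a band-power
   estimate on an approximately Gaussian scale; ten features per epoch.
   A ridge regression with unpenalized intercept is fitted in closed form on
   standardized features.
7. **Hyperparameter tuning.** The penalty λ is selected on the
   chronological training prefix (first 75% of epochs) by a sliding-window
   cross-validation: three equal-length overlapping windows, each split
   55%/45% into train and validation parts, validation sets pairwise
   disjoint and strictly after their train part. The λ (25-point
   exponential grid on 10⁻¹…10⁴) with the lowest mean validation MAE wins;
   ties go to the smaller λ. Chronological validation respects the
   nonstationarity of EEG; re-using earlier validation samples for later
   training windows is allowed, re-using them for validation is not.
8. **Evaluation.** On the held-out last 25% of epochs, the *EEG model* is
   compared against the *RT baseline* that predicts the training-mean
   standardized RT per angle — i.e. the constant 0. MAEs are reported in
   standardized units and, after inverting the label transform, in
   milliseconds. Inter-individual transfer applies one participant's ridge
   coefficients to another participant's hold-out epochs, extracting
   features either with the *train* participant's pre-processor bundle
   (label scaler, SPoC filters, feature scaler) or with the *test*
   participant's own bundle. Paired model comparisons use a percentile
   bootstrap of the mean difference (9999 iterations) with a small-sample
   `+1` correction of the two-sided p-value.
9. **Interpretation.** For the linear model, SHAP attributions under the
   independent-features value function are exact and closed-form:
   `φ_b(x) = β_b (x_b − mean of background)`, with the training features as
   background. Global importance is the mean |φ| per band; cohort summaries
   use the median and MAD across participants, a 10 × 10 mean absolute
   pairwise difference table, and sign-aligned averages of the forward-model
   patterns.

## The synthetic-data generator

The generator emulates the study conditions end to end, with defaults fixed
at the task's dimensions: 192 trials stratified over 4 angles × 2 mirror
conditions (24 per cell) sampled without replacement from a 384-pair pool,
fixation 1000–3000 ms, stimulus up to 7500 ms, 32 channels at 1 kHz, and a
one-minute resting state.

* **Behaviour.** `log(RT) ~ Normal(baseline + slope·angle, sd)`, truncated
  to [1, 7500] ms with draws beyond the timeout flagged as missing
  responses; accuracy is Bernoulli per angle, monotone non-increasing in
  angle. The published task reports no numeric RT distribution parameters,
  so the defaults — baseline `log(1400 ms)`, slope 0.004 per degree,
  `sd_log` 0.35, accuracies 0.96/0.93/0.89/0.84 — were chosen once as
  typical of mental rotation studies (mean RTs growing from ≈1.4 s at 0° to
  ≈2.6 s at 150°, with a few percent of early and timeout responses); they
  are configurable but deliberately not calibrated against any test result.
* **EEG sources.** Each planted cortical source is band-limited Gaussian
  noise (FIR-filtered white noise) rescaled piecewise so that its variance
  inside each stimulus window [onset, onset + 500 ms) equals exactly
  `exp(baseline_log_variance + α·z)`, where `z` is the trial's standardized
  log RT; between epochs it has baseline variance. The rescaling guarantees
  the planted power–behaviour comodulation instead of approximating it, at
  the cost of small variance discontinuities at window edges (irrelevant
  after band-pass filtering, and recorded per-epoch in the ground-truth
  sidecar). Defaults plant an alpha (10 Hz) source with α = −0.8 — an
  event-related-desynchronization-like negative power–RT relation — a beta
  (22 Hz) source with α = 0.5, and an uninformative 6 Hz source. Broadband
  background sources, white sensor noise, and stereotyped frontal blink
  transients (Poisson, 12/min) complete the recording.
* **What it does not emulate.** Volume conduction from a realistic head
  model, 1/f spectra, non-stationary drifts, muscle artifacts, or
  behaviourally silent state changes. Passing parameter-recovery tests
  therefore demonstrates the *estimators* are correct and the pipeline is
  leak-free; it does not certify performance on real recordings.

One global seed is expanded arithmetically into independent per-stage,
per-participant substreams (schedule, behaviour, source noise, background,
sensor noise, artifacts, ICA initialization, bootstrap), so regenerating one
stage never perturbs another and whole cohort reports are byte-identical
under a fixed seed.

## Numerical choices

* **FIR design.** 501 Hamming taps at 1 kHz. The measured response passes a
  centre-frequency sinusoid with gain 1.000 (the design scales the passband
  centre to unity) and attenuates a tone 6 Hz outside the band by more than
  40 dB, comfortably beyond the 20 dB contract, while keeping the
  filter-and-epoch step three times cheaper than the ≈1650 taps a 2 Hz
  transition band would need. The lowest band (centre 2 Hz) runs its lower
  edge into 0 Hz and is designed as a low-pass at 4 Hz. Nine centre
  frequencies follow the printed arithmetic progression 2…34 Hz; the tenth
  filter continues it at 38 Hz (configurable). Zero-phase application uses
  the symmetric taps in a single pass with group-delay compensation and
  reflect-padding by one filter length.
* **Fast filter-and-epoch path.** The pipeline evaluates the band-pass
  output only on the 500-sample epoch windows via a banded-Toeplitz matrix
  product per band — numerically identical (to ~1e-12) to filtering the full
  session and slicing, which the test suite asserts.
* **ICA.** Symmetric FastICA (tanh contrast) on a PCA-whitened, 1 Hz
  high-passed, 4× decimated copy of the resting state; one component per
  channel; at most 100 iterations. Gaussian subspaces are
  rotation-indeterminate for ICA, so strict convergence is not expected on
  largely Gaussian data; identifiable non-Gaussian components (blinks)
  stabilize within tens of iterations, and the capped, seeded iteration
  keeps results deterministic. Component rejection is config-first; the
  automatic fallback flags components whose resting time course correlates
  (|r| ≥ 0.8) with a low-frequency frontal-channel reference. Visual
  inspection, as used in interactive practice, is not reproducible and is
  deliberately out of scope.
* **Label handling order.** Log-transform → per-angle 2.5 × MAD outlier
  removal on the training prefix → scaler fit on the retained epochs →
  standardization everywhere. The alternative (fitting the scaler before
  outlier removal) differs only in the scaler's second decimal; removal
  before any fitting keeps every downstream statistic outlier-free. The MAD
  is unscaled (no 1.4826 consistency factor), and a degenerate angle group
  with MAD = 0 removes nothing. Standard deviations use the population
  (n) denominator throughout for reproducibility.
* **Window arithmetic.** Window length `floor(n/1.9)`, stride
  `floor(0.45·L)`, train share `ceil(0.55·L)`; the last validation window is
  anchored to `n` so rounding remainders are absorbed chronologically.
  Epsilon guards keep `floor`/`ceil` exact where the real-valued expression
  is an integer (`190/1.9` must give 100). SPoC filters, label scaler and
  feature scaler are fitted once on the full training prefix and the CV
  tunes λ only — matching a pipeline whose pseudo-code extracts features
  before the λ loop; re-fitting SPoC per window would triple the cost for a
  hyperparameter whose optimum barely moves.
* **SPoC.** Per-epoch channel means are removed before covariance
  estimation (DC offsets from filtering edges would otherwise leak into the
  power estimates); the grand-average covariance is shrunk by `γ = 1e-6`
  towards a scaled identity for numerical invertibility; the component with
  the largest *absolute* eigenvalue is selected — a negative λ of larger
  magnitude carries more label information than a smaller positive one, and
  the sign only flips the regression coefficient. Patterns are sign-fixed
  (largest-magnitude entry positive) and filters normalized to `w'Cw = 1`.
* **Bootstrap.** Percentile CI and the `+1`-corrected two-sided p-value;
  with a constant difference the p-value is exactly `2/(B+1)`. Type-I error
  at nominal 0.05 is verified to lie in [0.02, 0.08] over 500 null
  replications at n = 40.

## Problem sizes used in the test suite

Structural checks, the parameter-recovery participant and the acceptance
script's headline cohort run at the full study dimensions (32 channels, 192
trials). Cohort-level experiments inside the test suite — the 20-participant
headline-direction cohort and the ten replicate cohorts of 20 participants
for planted-band SHAP recovery — run at 16 channels and 96 trials per
participant: the package's estimators are dimension-agnostic, and these
sizes keep the whole suite comfortably repeatable while leaving every
directional conclusion unchanged. The homogeneous-population transfer
control uses 4 participants at 16 channels / 192 trials.

## Known limitations

* The generator's linear mixing with unit-norm random topographies is a
  favourable regime for SPoC; realistic volume conduction produces more
  correlated topographies and lower recovery scores.
* Exact variance planting makes the ground-truth epoch variance a
  deterministic function of the label; tests that probe comodulation
  strength therefore measure it through the mixed sensor signal.
* With shared topographies and RT parameters across participants,
  inter-individual transfer still trails intra-individual prediction by a
  small margin (≈0.1 standardized MAE in our controls): person-specific
  pre-processors are estimated, not known, and their estimation noise
  favours self-prediction. The transfer experiments should be read
  directionally.
* The one-way repeated-measures ANOVA over angles reported alongside the
  original evaluation design is a standard off-the-shelf test over the
  per-angle MAE table; the table is computed and exported, the test itself
  is out of scope.
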