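---
title: "Methods: computable ICU acuity phenotyping and selective state-space prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computable ICU acuity phenotyping and selective state-space prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the phenotyping and
prediction procedure, the assumptions behind each stage, the tunable
parameters with their defaults and units, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
made where the problem left them open.

## 1. The prediction problem

ICU patients move between acuity states on the scale of hours. We discretize
each admission into consecutive 4-hour *prediction windows* and attach to
each window one of four states:

* `unstable` — at least one life-sustaining therapy is present during the
  window: invasive mechanical ventilation (MV), intravenous vasopressors
  (VP, continuous infusion or one-time push), continuous renal replacement
  therapy (CRRT), or massive blood transfusion (BT, defined as >= 10 units
  of blood product within the trailing 24 hours);
* `deceased` / `discharge` — terminal states carried by the final window of
  the stay, death taking precedence over any concurrent therapy;
* `stable` — everything else.

Nine binary outcomes are defined per window: the four states (one-hot), the
two transitions stable→unstable and unstable→stable (undefined — masked, not
zero — on a stay's first prediction window, which has no predecessor state),
and onsets of MV, VP, and CRRT. A therapy *onset* means an interval of that
therapy starts inside the window and the therapy was inactive throughout the
preceding 4 hours. BT has no onset head: its definition is retrospective
over 24 h, so the therapy has already happened by prediction time.

The model input for a prediction window is the *observation window*: all
clinical events of the preceding 4 hours, plus static admission features.

### Admission filters

Stays shorter than 8 h (cannot host one observation + one prediction window)
or longer than 30 days (would dominate the window population) are excluded,
as are stays missing any of the six routine vitals (HR, RR, SBP, DBP, Temp,
SpO2) or any static field. Each exclusion carries a machine-readable reason
code so cohort accounting is reproducible.

### Conventions the problem statement leaves open

* **Half-open windows `[start, end)`**, 0-based window indices, fractional
  hours. An event at exactly t = 8 h belongs to the window starting at 8.
* **The final partial window is kept** (when the stay length is not a
  multiple of 4 h) and carries the terminal state; otherwise deaths in the
  last partial window would be unlabeled.
* **BT threshold is inclusive** (>= 10 units), configurable
  (`bt_unit_threshold`); the trailing window is the half-open interval
  `(t - 24 h, t]`.
* **One-time vasopressor pushes** are zero-length intervals expanded to
  their enclosing window, so they mark that window unstable and can count
  as an onset.
* **Onset requires inactivity during the entire preceding window**, not
  merely at its end — a strict, testable definition. The first prediction
  window is eligible: its preceding 4 hours are inside the stay.

## 2. Triplet encoding without imputation

Irregularly sampled EHR data are usually tabularized by resampling and
imputation. Here every observation window is instead encoded as the raw
sequence of its events, each event the triplet *(scaled time, scaled value,
variable code)*:

* **Vocabulary.** Variables appearing in fewer than 5% of stays are removed
  (the boundary is inclusive: exactly 5% is retained). Codes are assigned by
  order of first appearance; code 0 is reserved for padding and its
  embedding row is fixed at zero.
* **Outliers.** Values outside optional hard physiologic bounds, or outside
  the development cohort's 1st–99th percentiles (inclusive), are dropped.
  Counts are logged per variable.
* **Scaling.** Min–max scaling with ranges frozen on the development
  cohort; out-of-range validation values clip to [0, 1]; constant variables
  map to 0.5. Times are divided by a fixed 720 h (30-day) horizon so the
  encoding is invertible.
* **Sequence assembly.** Events sort by (time, code) — the deterministic
  resolution of simultaneous measurements — and pad to length `L`
  (default 256). When a window holds more than `L` events, the most recent
  `L` are kept, on the view that recency is most predictive. No value is
  ever imputed; padding is identifiable from the mask alone.

## 3. The sequence model

Dimensions: batch `N`, sequence length `L`, model width `D = 64`, block
expansion 2 (inner width 128), state size 16 per channel, two blocks, top-k
pool size `k = 8`, post-pooling MLP width 4096. None of these sizes is
dictated by the problem; they are package defaults, chosen so the default
model lands at ~0.6 M parameters — the intended "about a million, mostly
cheap" scale: the wide MLP runs once per window, while the per-token blocks
stay thin so CPU training is practical.

**Embedding.** `conv(time) + conv(value) + lookup(code) + positional
encoding`, where both convolutions are causal (left-padded, width 3) so no
position sees later events, and the positional encoding is the standard
sinusoid (channel 2i carries `sin(p / 10000^(2i/D))` at 0-based position p).
It is parameter-free and deterministic. Padded positions are zeroed before
the trunk.

**Selective state-space block.** RMSNorm → linear projection to an expanded
pair (x, z) → depthwise causal convolution and SiLU on x → input-conditioned
step sizes `dt = softplus(low-rank(x))` and projections `B(x)`, `C(x)` →
the scan

$$\bar A_t = (1 - \Delta_t A)^{-1},\qquad
  h_t = \bar A_t\,(h_{t-1} + \Delta_t B_t x_t),\qquad
  y_t = C_t h_t + D_{skip}\,x_t,$$

with `A = -exp(A_log)` diagonal per (channel, state) — a backward-Euler
discretization of `h' = A h + B x`, unconditionally stable for `A < 0` and
divisor-cheap on CPUs — followed by a multiplicative SiLU gate on `z`, an
output projection, and a residual connection. The block's contract, not its
kernel, defines correctness: causality (future inputs cannot change past
outputs), agreement between the compiled scan and a sequential pure-R
reference within 1e-5, and reduction to a direct convolution with the
implied impulse response when the parameters are frozen and the gate is off.

**Head.** Top-k pooling averages the k unmasked positions with the largest
L2 norm (the package's definition of "most important states"; a learned
scorer was considered and rejected to keep pooling parameter-free and
deterministic — positions with large hidden-state norm are the ones the
blocks chose to amplify). The pooled vector passes through the MLP back to
width D, is added to a two-layer embedding of the f static features, and
feeds nine independent sigmoid heads. There is no cross-head normalization:
the heads answer nine separate questions.

**Training.** Sum over heads of class-weighted binary cross-entropy
(positive-class weight `N_neg/N_pos` per head, capped at 100, computed on
the training split; masked labels contribute nothing; heads with no positive
training labels are frozen with a warning). Adam (lr 1e-3, batch 128,
default 5 epochs), minibatches bucketed by event count so batches have
homogeneous lengths, the split always by stay. All gradients are
hand-derived; the test suite checks them against central finite differences
parameter-by-parameter. Training is bit-for-bit reproducible under a fixed
seed; the checkpoint with the lowest validation loss is returned.

**Thresholds.** Per head, the Youden index `J = sensitivity + specificity -
1` is maximized over all observed probability values (predict positive iff
`p >= threshold`), ties resolved toward the lower threshold (the more
sensitive operating point).

**Decision logic.** `deceased` if its head fires; else `unstable` if any of
{unstable, stable→unstable, MV, VP, CRRT} fires; else `discharge` if that
head fires; else `stable`. The unstable→stable head is evaluated but takes
no part in the decision. The full 2^7 truth table is locked as a golden
file.

## 4. Evaluation

* **Step level** (per window): AUROC with midrank tie handling, AUPRC by
  step integration over descending unique thresholds, and
  sensitivity/specificity/PPV/NPV at a supplied threshold.
* **Episode level** (per admission): each stay is scored by its maximum
  predicted probability over the windows strictly before outcome onset
  (first positive window), or over all windows when the outcome is absent.
  Stays whose outcome occupies their first eligible window have no
  pre-onset window and are excluded with a log entry. Episode onset for
  instability is the first unstable window; for mortality, the terminal
  window.
* **Precision-targeted alerting**: the smallest threshold whose
  episode-level PPV reaches a target (default 0.33) — the most sensitive
  operating point at that precision; lead time is the gap between the first
  super-threshold pre-onset window and onset, in hours; the alert count is
  the number of super-threshold pre-onset windows. The same threshold is
  shared between episode and step reporting.
* **Uncertainty**: 100-iteration bootstrap resampling *stays* (not windows,
  preserving within-stay correlation), reporting the 2.5/50/97.5
  percentiles; undefined resamples (e.g. single-class) are redrawn at most
  10 times. Models are compared by a two-sided Wilcoxon rank-sum test on
  their bootstrap metric distributions.

## 5. Calibration

Isotonic regression by pool-adjacent-violators, fit on a seeded stay-level
10% subsample: observations are pooled at tied raw probabilities, then
adjacent violating blocks merge until the fitted outcome frequencies are
non-decreasing — the least-squares monotone fit. Application is a step
function over the fitted knots; raw probabilities outside the fitted range
clamp to the nearest knot, since an isotonic model is undefined beyond its
support. Calibration preserves ranking up to ties introduced by flat
segments, so AUROC is unchanged up to those ties. Brier score (mean squared
error of the probability) and an equal-width 10-bin reliability curve
quantify the effect; a single-class calibration sample is an error. The
fitted step functions serialize to JSON with 17 significant digits so
round-trips are exact.

## 6. SOFA baselines

Two standard clinical comparators consume a precomputed SOFA series
(computing SOFA from raw organ components is out of scope; the last
measurement is carried forward onto each window): the raw score scaled to
[0, 1] (`sofa / 24`) as a continuous predictor, and the binary criterion
`current - baseline >= 2` where baseline is the admission score.

## 7. Integrated gradients

Attributions are computed at the embedding layer against the natural "no
information" reference of an imputation-free encoder: an all-padding
sequence plus a zero static vector. The temporal embedding and the static
features are interpolated linearly toward the input (the padding mask held
fixed), head-probability gradients are averaged at `n_steps` midpoints
(midpoint Riemann rule), and the path derivative is taken channel-summed per
event. Two numerical choices matter:

* **Frozen pooling selection.** The top-k selection is computed once at the
  actual input and reused along the whole path. Selection switches are jump
  discontinuities; integrating through them breaks the completeness axiom
  by a step-count-independent offset, while freezing them (the standard
  treatment of max-pooling switches in path attributions) restores
  completeness up to Riemann error.
* **Zero padding attribution.** Padded positions are identical in input and
  baseline and are masked out of the trunk, so their attributions are
  exactly zero by construction.

Completeness (`sum of attributions = F(x) - F(baseline)`) is checked
numerically in the tests: below 1% relative gap at 256 steps, exact on a
linear surrogate.

Feature importance aggregates per variable by first *summing* a variable's
event attributions within each window and then averaging the magnitudes of
those per-window totals over the windows where the variable occurs, finally
averaging across the six increased-acuity heads (unstable, stable→unstable,
MV, VP, CRRT, deceased) and reporting the top 15. Two alternatives were
tried and rejected on planted-signal cohorts. A per-event mean systematically
favors *rare* variables: a sparse noise lab's single event can carry a large
share of a window's representation shift, while a frequently charted
predictive variable divides its contribution across many events — on a
cohort with a single planted predictive variable the per-event mean ranked
noise labs above the planted signal. Signed averaging of the per-window
totals lets a genuinely predictive variable cancel itself (its low values
legitimately push risk down, its high values up), again understating it.
Per-window summation with magnitude averaging — the convention of the
standard attribution libraries — ranks the planted variable first by a
factor above two; `absolute = FALSE` exposes the signed average.

## 8. The synthetic cohort generator

Every downstream stage is exercised on seeded synthetic cohorts with known
ground truth, generated as follows:

* **Latent risk**: per stay, a bounded random walk on hourly knots
  (clamped to [0, 1], Gaussian steps of sd 0.03) with a per-stay drift —
  25% of stays deteriorate (+0.004 to +0.03 per hour), 15% improve, the
  rest are neutral. The piecewise-linear interpolation of the knots is the
  stay's ground-truth trajectory, stored in a sidecar table that no
  pipeline stage reads.
* **Lengths of stay**: log-normal with median 48 h and sdlog 0.8 (a typical
  mixed-ICU distribution), truncated by default to the 8 h–30 d admission
  window; a flag disables truncation to exercise the filters.
* **Events**: per variable an independent Poisson process — vitals at about
  1/h, labs at 0.15–0.25/h — thinned by a per-variable missingness
  probability. Values are Gaussian around catalogue means; the designated
  *deteriorating* variables (HR, RR, SBP, SpO2, GCS, lactate by default)
  shift by `signal_strength` standard deviations per unit latent risk, in
  their clinically sensible directions. A small artifact rate (0.2%)
  produces impossible values for the outlier filter to catch.
* **Therapies**: per 4-hour interval a Bernoulli initiation with a steep
  logistic link on latent risk (slope 10; intercepts set for roughly 26% MV,
  24% VP, 8% CRRT incidence at unit hazard scale); durations log-normal
  (median 24/12/36 h), ended early when the patient's risk recovers below
  0.15 (weaning); 15% of VP initiations are one-time pushes (zero-length
  intervals). The steep coupling is deliberate: it makes window-level
  instability recoverable from the planted vitals by a plain logistic
  readout (AUROC >= 0.9 at signal strength 3), which is the sanity floor the
  model tests rest on.
* **Transfusions**: 8% of stays receive 1–2 bursts of ~13 single-unit
  transfusions over ~6 h, so the rolling 24 h / 10-unit rule triggers
  occasionally.
* **Death**: a discrete-time hazard per 4-hour interval,
  `plogis(-9.5 + 6·risk)`, giving ~6% ICU mortality; death truncates the
  stay inside the interval.
* **SOFA**: `round(18·risk + N(0, 1.2))` clamped to [0, 24] every 4 h, so
  the baseline predictors have a correlated but noisy score to work with.
* **Statics**: age, sex, race, BMI and binary comorbidities are
  *non-predictive* noise by design — the planted signal lives entirely in
  the temporal variables, which gives attribution tests an unambiguous
  expected ranking.

Zero-hazard limits are exact: `therapy_hazard_scale = 0` produces a
therapy-free cohort, `mortality_hazard_scale = 0` an all-survivor cohort,
and `signal_strength = 0` decouples all measurements from risk.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: inter-variable physiologic correlation beyond the
shared latent risk, medication–vital feedback, measurement batching
(real labs arrive in panels), informative missingness, inter-site coding
differences, and any realistic pharmacology. Performance numbers on
synthetic cohorts characterize the implementation, not clinical utility.

## 9. Problem sizes used in the shipped tests

The test suite trains three models: the planted-signal recovery experiment
on 2,000 stays (~31,000 windows, 4 epochs, the default model), its
within-stay label-permutation null at the same scale, and a 400-stay
single-planted-variable cohort for the attribution ranking check. Unit and
property tests use cohorts of 5–1,000 stays and tiny model configurations
(D = 8) whose gradients are finite-difference-checked. The acceptance script
runs the full pipeline on 600 stays. These sizes are the package's choices
for a reproducible desk-scale study; all of them scale up by changing a
single argument.

## 10. Known limitations

* The within-stay label-permutation null retains between-stay signal (a
  permuted cohort still has sicker and healthier stays), so its AUROC sits
  well above 0.5 whenever stays are heterogeneous; see the discussion in
  the test suite.
* The scan kernel is single-threaded; training throughput is adequate for
  desk-scale studies (roughly a minute per epoch per 25,000 windows) but
  not for full-registry cohorts.
* Isotonic calibration is the only recalibration offered; Platt and
  temperature scaling are deliberate non-goals.
* SOFA is consumed, never computed, and carried forward between
  measurements by convention.
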