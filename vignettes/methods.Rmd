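---
title: "Modeling daily readmission risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling daily readmission risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmitrisk)
```

This vignette explains the model the package implements, the assumptions
behind it, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. The label model

No ground-truth "daily readmission probability" exists, so the framework
*constructs* one from information hospitals already produce. The LACE index
(0–19) and HOSPITAL score (0–15) are mapped linearly onto $[0,1]$ — a LACE
of 10 becomes $10/19 \approx 0.53$ — and averaged when both are used. That
initial probability $p_1$ anchors a daily sequence $p_1,\dots,p_{60}$:

* non-readmitted patients decay from $p_1$ to exactly 0 on day 60
  (follow-up studies and the original cohort both indicate surgical
  readmission risk is negligible beyond 60 days);
* readmitted patients rise to exactly 1 on the readmission day $k$, and
  after the second discharge day decay to 0 — either from 1
  (`continue_from_one`) or after first falling back to $p_1$ during the
  readmission stay (`reset_to_initial`).

Each monotone segment is drawn from one of four families fitted to its two
endpoints: linear $p_n = an+b$, exponential $p_n = a^n + b$, logarithmic
$p_n = \log_a n + b$, and the weighted linear recursion
$p_n = w_n l_n + (1-w_n)p_{n-1}$ with the parabolic weight
$w_n = \tfrac{4}{(d_1-d_2)^2}\bigl(n - \tfrac{d_1+d_2}{2}\bigr)^2$.
Because $w_{d_1} = w_{d_2} = 1$, the recursion needs no $p_{d_1 - 1}$ and
pins both endpoints exactly; in the middle of the segment the weight
approaches 0 and the value is carried mostly by its own history, giving a
plateau-then-drop shape.

Numerical choices:

* **Local re-indexing.** Exponential and logarithmic segments are fitted in
  a local index $n' = n - d_1 + 1 \in 1..m$. The sources define $p_n$ in
  the absolute day index but give no rule for segments that start past
  day 1, where $\log_a n$ would otherwise be anchored at interior days; the
  local index keeps every fit well-posed and $\log$ away from 0.
* **Exponential solve.** The falling-segment equation $a - a^m = \Delta p$
  has *two* roots in $(0,1)$: a fast-decay root near $\Delta p$ (probability
  collapses within days) and a slow root near 1 (gentle decay over the
  horizon). The gentle branch is the one the framework depicts, so the
  solver brackets $(\arg\max_a (a - a^m),\, 1)$ where the root is unique,
  and solves with `stats::uniroot` at tolerance $10^{-14}$. Rising segments
  solve $a^m - a = \Delta p$ on $a > 1$, which is monotone past its minimum.
* **Infeasible exponential drops.** The family's maximum achievable drop
  over $m$ days is $\max_a (a - a^m) < 1$; the short in-hospital reset
  segment (1 down to $p_1$ over ~4–8 days) can exceed it, in which case no
  parameters exist. Such segments fall back to the linear family and record
  `fallback_from = "exponential"` in the segment parameters.
* **Degenerate segments** ($p_{start} = p_{end}$) return a constant rather
  than erroring; **clamping** to $[0,1]$ (never rescaling) repairs marginal
  float excursions without disturbing the endpoints; the final day is set
  to exactly 0.
* The rising readmitted segment uses the same configured family as the
  falling ones: nothing in the sources suggests an asymmetric choice, and
  the depicted readmitted trajectories are consistent with a symmetric one.

## 2. The feature pipeline

Inputs are per-patient daily feature tables (sensor features, 0–10 symptom
reports). The pipeline:

1. **Deviation features** (window 7): today's value minus the mean of the
   *strictly prior* 7 days, observed values only. "Past-window" is read as
   excluding the current day; including it would leak the value into its
   own baseline. With panels that start at discharge, day 1 has an empty
   window, so day-1 deviations are structurally missing.
2. **Filters**: drop features missing in > 80% of pooled patient-days, with
   observed-value variance < 0.3 (computed on raw, pre-normalization values
   — the filter is listed before scaling in the processing order), or
   missing on day 1 for *any* patient. The day-1 rule exists because the
   first day initializes the recurrent state; a feature absent there acts
   as noise. Deviation columns are exempt from the day-1 rule: their day-1
   missingness is structural (see above), not a data-quality signal, and a
   literal application would delete the entire deviation block. The
   missingness threshold is pooled over all patients (a per-patient variant
   would drop a column for everyone because of one bad logger; nothing in
   the sources requires it), and all filters apply uniformly to sensor and
   symptom columns.
3. **Imputation**: each missing cell becomes the mean of up to $k=2$
   previous *observed* values of that patient/feature (imputed values never
   feed later imputations, so a long gap decays to the constant rather than
   compounding its own guesses); cells with no observed predecessor get the
   constant −1, deliberately outside every normalized feature range so the
   model can recognize "unknown".
4. **Min–max normalization** to $[0,1]$, fitted pooling all patients and
   days. Constant-filled (−1) cells are excluded from the fit and stay at
   −1; constant features map to 0 rather than erroring. Pooling across
   patients reproduces the original protocol, which leaks the held-out
   patient's range into training folds; `normalize_minmax(panel, params =)`
   supports a leakage-safe per-fold variant, off by default (fidelity
   first).

Auxiliary model inputs are appended last: the day index normalized by the
horizon (the same $[0,1]$ convention as every other input), and the
previous day's probability, with day 1 carrying the initial probability —
legitimately known at discharge from the administrative scores.

## 3. The sequence model

A stacked LSTM (1 or 2 layers, tanh recurrent activations) with a single
sigmoid output unit predicts $p_{t+1}$ from the day-$t$ input; inputs are
days $1..59$, targets days $2..60$. Width defaults to the input feature
count. Training minimizes MAE with Adam at learning rate 0.01, full-batch:
every patient's sequence is one sample and all sequences advance in
lockstep (shorter sequences are prefix-masked out of the loss, which is
equivalent to packing — masked steps contribute no gradient). "Trained for
multiple rounds" is read as multiple epochs to early stopping, not
restarts; early stopping monitors the *training* loss (no validation split
is named in the sources) with minimum-delta 0 and patience 50, and the
weights of the best epoch are restored. Initialization is Glorot-uniform
drawn from R's RNG, forget-gate biases at 1, so a seed pins the entire
train/predict cycle; full-batch training makes the cycle deterministic
given the seed.

**Injection.** Three modes: `none`; `actual_prev`, where the true
previous-day label enters as an input feature (an oracle setting — it
presumes the label is recomputable at test time, which holds when scores
and readmission status are known); and `predicted_prev`, where the model's
own previous output is fed back. For `predicted_prev` the model is
teacher-forced during training (the true label occupies the injected
column) and rolled out autoregressively only at inference, the standard
stable choice for autoregressive sequence models. Day 1's injected value is
the initial probability in every mode. Reported trajectories set day 1 to
the initial probability (known at discharge) and days 2–60 to the model's
next-day outputs, which stay in $(0,1)$ by construction of the sigmoid.

Leave-one-patient-out: one model per held-out patient, trained on everyone
else, seeded as `seed + fold`. This mirrors deployment on a new patient and
is the only defensible split at $n \approx 50$.

## 4. Evaluation and ranking

MSE and sample covariance (denominator $n-1$, actual risk as the
independent variable) are computed over pooled patient-days on six slices:
{all, readmitted, non-readmitted} × {first $k=20$ days, all $K=60$ days}.
The early window exists because readmissions cluster in the first days
after discharge; $k$ is configurable. "Number of data points" in the
covariance is resolved as pooled patient-days (the only reading consistent
with the covariance formula itself). A stratum with no patients yields
`NA` submetrics, which ranking accepts only if absent for every model.

Ranking: per metric, models are ranked (MSE ascending, covariance
descending), ties receiving the average of the tied positions — fractional
Points in thirds observed in the reference ranking tables are consistent
with averaged ties and with ranks computed on unrounded values. Each model
earns $(n_m - \mathrm{Rank})/(n_m - 1)$ per metric; Points sum over the 12
metrics and the final rank orders Points from largest to smallest (rank 1 =
largest Point). Points are invariant under order-preserving transforms of
any metric column and sum to $n_m \cdot 12/2$ across models.

Baselines (MLR, CART, RBF ε-SVR) see the same processed rows one day at a
time, never the injected probability; the date-index column is optional and
off by default, reflecting that classic models "use the data on a day by
day basis". Their raw outputs may leave $[0,1]$ and are clipped for
evaluation, with raw values logged. No SVM or tree package is available in
the target environment, so CART is implemented directly (variance-reduction
splits; defaults: unlimited depth, minimum split 2 — under which it
interpolates training data) and ε-SVR is solved exactly as its dual
quadratic program via `quadprog` (defaults C = 1, ε = 0.1,
γ = 1/(d·Var X)); beyond 600 training rows a seeded subsample caps the
cubic kernel cost, and the pinned defaults are recorded with every fit.

## 5. The synthetic cohort generator

The original 49-patient dataset is private, so the generator emulates its
*statistical shape*, with defaults chosen once as the stated world:

* 34% readmitted (the study's rate), readmission days drawn early-weighted
  over days 5–45, second discharge 3–7 days later;
* integer LACE/HOSPITAL scores drawn so initial probabilities spread over
  $[0.2, 0.8]$, with ±1-point noise (`score_noise`) decoupling the two
  scores;
* latent risk = the label module's trajectory (so every label invariant
  holds by construction);
* symptoms = $\mathrm{round}(\mathrm{clip}(10\cdot\mathrm{latent}\cdot
  \gamma_s + \mathrm{transient} + \mathrm{peak} + \varepsilon, 0, 10))$:
  a per-symptom gain $\gamma_s \in [0.6, 1.2]$, a post-operative transient
  decaying at 0.05/day, a 2-point Gaussian bump around the readmission day
  for readmitted patients, and noise with SD `score_noise`. This reproduces
  the qualitative pattern of the study — symptoms decay for recovering
  patients and peak near readmission;
* sensor features: half *signal* (affine in the latent risk with
  per-feature scale spanning ~2.5 decades, so normalization is exercised),
  half *distractors* (pure noise), enabling data-source ablations. The
  `sensor_encoding` switch selects whether signal features carry the risk
  *level* (one day's row suffices to read the label — the world where
  per-day regressors are competitive) or the day-to-day risk *increment*
  (e.g. activity drops as a patient deteriorates; the level is only
  recoverable by integrating the sequence — the world where sequence models
  have their claimed edge). Comparisons between the LSTM and per-day
  baselines use the increment world, because only it actually contains a
  sequential signal;
* missingness at `missing_rate`, half scattered cells and half one
  contiguous block per patient/feature (device outages), with day 1
  retained by default — without that, the first-day filter would discard
  nearly every column at realistic cohort sizes.

What the generator does **not** emulate: real sensor noise distributions,
cross-feature correlation structure, informative missingness (sicker
patients logging less), or any calibrated effect size from the study. A
green recovery test therefore establishes that the pipeline recovers the
trajectories *its own generative model* encodes — a software and
identifiability check, not a clinical validation; the study's absolute
error tables cannot be reproduced without the private cohort.

## 6. Scaling and budgets

Model-level checks are scaled to a single CPU: training caps at 120 epochs
(patience 50 still governs; most folds plateau earlier), recovery runs use
8 sensor features, and the paired-injection and baseline-comparison cohorts
use 16 and 12 patients. The n = 50 recovery check keeps the full cohort
size. Seeds are fixed in every test; stochastic claims are asserted as
repeated-seed majorities.

## 7. Known limitations

* The label trajectories are a modeling construction, not observed risk;
  all error metrics are relative to that construction.
* `actual_prev` injection assumes the previous day's label is available at
  prediction time — reporting it alongside `predicted_prev` is deliberate
  (oracle vs deployable).
* Pooled normalization and pooled filter statistics leak across LOPO folds,
  faithfully to the original protocol; leakage-safe variants exist but are
  not the defaults.
* The composite Point is rank-based: it orders models but its magnitude has
  no calibrated meaning, and adding or removing models changes every
  model's Point (only relative order against a fixed field is stable).
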