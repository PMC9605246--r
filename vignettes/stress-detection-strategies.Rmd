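---
title: "Comparing individual, centralized and federated learning for smartwatch stress detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing individual, centralized and federated learning for smartwatch stress detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressfl)
```

## The problem

Wrist-worn devices expose four physiological channels that react to acute
psychological stress: skin temperature (ST), 3-axis acceleration (ACC),
electrodermal activity (EDA) and blood volume pulse (BVP).  Given a lab
session in which each wearer passes through a long neutral block, a
stress-induction block and an amusement block, the task is binary
classification of 60-second windows into stress vs. non-stress (neutral
and amusement both count as non-stress).

The interesting question is not the classifier — a regularized logistic
regression does well — but *where the training data live*:

* **individual** learning fits one model per wearer on their own windows;
* **centralized** learning pools every wearer's windows on a server and
  fits one global model;
* **federated** learning keeps raw windows on each device and builds a
  global model by FederatedAveraging (FedAvg): each round, every client
  takes local gradient steps from the current global model and uploads
  only its updated weights and example count; the server replaces the
  global model with the count-weighted mean
  \(w \leftarrow \sum_k \frac{n_k}{\sum_j n_j} w_k\).

Because wearers respond to stressors with different intensity — and a
minority respond atypically (e.g. electrodermal activity that *drops*
under pressure) — the per-client data distributions are non-IID.  That
heterogeneity is exactly what separates the three topologies: a personal
model can adapt to an atypical responder, while a single global model
must compromise, and a federated model additionally pays for averaging
across conflicting gradients.

## The synthetic cohort generator

Everything in this package is testable without any external download
because the cohort is synthesized.  The generator is deliberately
minimal: every stress response is analytically checkable at zero noise,
while still giving the classifier genuine signal.

The default session plan is 1200 s neutral, 600 s stress, 390 s
amusement (2190 s total), with per-second condition labels.  Channels
use the device-export rates ST 4 Hz, EDA 4 Hz, ACC 32 Hz, BVP 64 Hz;
these divide the 4/2/1 Hz wavelet targets evenly, so every Haar cascade
has an integer level count.

Per channel (all "+ Gaussian noise", per-channel standard deviations
ST 0.05 °C, ACC 0.05 g, EDA 0.05 µS, BVP 0.1):

* **ST** — baseline (≈33 °C) + slow linear drift (−0.3 °C over the
  session) + a smoothed −0.2 °C stress decrement.
* **EDA** — a tonic level (≈2 µS) elevated by +1.5 µS under stress
  (first-order smoothing, τ = 10 s), plus phasic skin-conductance
  responses arriving as a Poisson process (3 events/min neutral,
  +5 events/min under stress), each a fast-rise (0.7 s) exponential-decay
  (3 s) bump of amplitude 0.2–0.8 µS.
* **BVP** — a unit sinusoid at the instantaneous heart rate (≈70 bpm,
  +20 bpm under stress, smoothed with τ = 15 s, clamped to 40–200 bpm).
* **ACC** — gravity-offset constants with ~1/min movement bursts whose
  rate is condition-independent, so acceleration carries no class
  signal by design.

Response magnitudes are multiplied by a per-participant
`stress_effect_scale`; `responder_type` halves them (`weak`) or flips
their sign (`atypical`).  Amusement carries no systematic offset by
default (`amusement_effect = 0`), which keeps the binary task well
posed; it is a configurable fraction of the stress response.  Cohort
heterogeneity draws baselines and the effect scale from Gaussian spreads
(ST 33 ± 0.5 °C, EDA 2 ± 0.5 µS, HR 70 ± 6 bpm, scale 1 ± 0.3) and
samples responder types with a 20% atypical fraction by default — enough
spread that a pooled model visibly underperforms personal models, which
is the regime the comparison is about.

What the generator does **not** emulate: realistic pulse morphology,
motion artifacts correlated with condition, sensor drift/detachment,
multi-session variability, or the empirical distributions of any real
dataset.  Passing tests therefore demonstrate that the *pipeline and the
topology comparison* behave correctly on data with the assumed
structure, not that the classifier would reach any particular accuracy
on real recordings.

## The 420-column feature pipeline

Each of the 7 base streams (the six channels plus the accelerometer
magnitude `ACCnorm` \(= \sqrt{a_x^2+a_y^2+a_z^2}\)) expands into 6
signals: the original, its first and second derivatives, and Haar
wavelet approximations at 4, 2 and 1 Hz — 42 derived signals,
partitioned 6 ST / 24 ACC / 6 EDA / 6 BVP.  Windows of 60 s slide in
0.25 s steps; each window × signal pair yields 10 statistics, giving
42 × 10 = 420 features.

Choices the construction leaves open, and how this package resolves
them:

* **"Haar wavelet at X Hz"** is read as the cascade of single-level Haar
  approximation coefficients, \((a,b) \mapsto (a+b)/\sqrt2\) on adjacent
  pairs, applied \(\log_2(\text{native}/X)\) times; each level halves
  the length and the effective rate.  Zero levels is the identity (the
  4 Hz variant of the 4 Hz streams).  This is the only reading that
  makes a target *frequency* well defined across channels with
  different native rates.  Coefficients carry the \((\sqrt2)^L\) gain of
  the analysis filter rather than being rescaled to local averages;
  the per-level convention is pinned by tests against an independent
  wavelet library's coefficients.
* **Derivatives** are length-preserving central differences scaled by
  the sampling interval, with one-sided differences at the endpoints,
  computed at the stream's native rate before any wavelet coarsening.
  Length preservation keeps all 42 signals aligned to the same window
  clock without trimming.
* **The 10 statistics** are mean, min, max, median, maximum amplitude
  (read as \(\max_i |x_i|\)), variance, standard deviation, absolute
  deviation (read as mean absolute deviation about the mean), kurtosis
  and skewness.  Moments use population normalization and Fisher
  *excess* kurtosis, the defaults of the numerical libraries this style
  of pipeline is normally built on; zero-variance windows define
  skewness and kurtosis as 0 rather than NaN so feature matrices are
  always complete.
* **Windows** are half-open \([t, t+60)\) so no sample is counted twice;
  a window's samples for a derived signal are those whose
  effective-rate timestamps fall inside the interval.  A window is
  labelled stress when *strictly* more than half of the seconds it
  covers are stress seconds; ties go to non-stress, the larger class.
  Stress-window count is then monotone in the planned stress duration.

The inner statistics loop is compiled (Rcpp): a default session
produces 8521 windows × 42 signals, and the kernel additionally reuses
results for consecutive windows whose sample ranges coincide (sub-sample
steps at the 1–2 Hz effective rates).

## The learner

A single binary logistic regression is used everywhere, written out in
full because the federated path needs direct access to weights and
gradients.  The batch objective is the L2-penalized negative
log-likelihood (intercept unpenalized, penalty λ = 1 by default,
matching the common unit-inverse-regularization library default, since
no hyperparameters are prescribed by the protocol being modelled),
minimized by damped Newton iteration with step-halving — the recorded
loss history is monotone — to a 10⁻⁶ mean-gradient tolerance.

Features are standardized (center/population-sd from the training pool,
zero-spread columns get scale 1) and the standardizer is stored in the
model; this is necessary for stable gradient training on features whose
scales differ by orders of magnitude.  In the federated path no raw
rows may leave a client, so the global standardizer is pooled from
per-client first and second moments weighted by client counts, then
broadcast.

`fit_local_sgd()` implements the client-side update: shuffled
mini-batch gradient descent (defaults: rate 0.1, batch 32, one epoch)
on the per-example-mean of the same objective, which shares its
stationary point with the batch objective — with a decaying rate and
full batches it converges to the batch optimum, a property the test
suite checks.  Predicted probabilities are clamped to
\([10^{-15}, 1-10^{-15}]\) so extreme logits cannot produce infinite
log-loss.

## Splits and the three strategies

Each participant's windows are split 80:20 *before* any pooling, so all
three strategies are evaluated on identical per-participant test rows.
The default mode is seed-deterministic stratified random allocation
(`round(0.2 · n_class)` test rows per class).  A chronological mode
(final 20% of windows by start time) is also provided: 60 s windows
0.25 s apart overlap by 99.6%, so random splits place near-duplicates of
training windows in the test set and yield optimistic scores — the
near-perfect individual-learning numbers this design reproduces should
be read with that in mind.

FedAvg defaults are 20 rounds, 1 local epoch, all clients every round,
zero-weight initialization — canonical small-cohort settings, all
configurable.  The client interface exposes only feature moments (for
the broadcast scaler) and `(model, n)` payloads; a test observes every
round's payloads to assert nothing else crosses the boundary.

## Evaluation

With stress as the positive class, each participant's test predictions
give a confusion matrix and Acc = (TP+TN)/total, P = TP/(TP+FP),
R = TP/(TP+FN), F1 = 2PR/(P+R).  Any 0/0 ratio returns 0 carrying a
`degenerate` attribute instead of erroring, which keeps macro averages
total.  The report appends an `Average` row that is the *unweighted*
mean of the participant rows; display tables round half-up to 4
decimals while full precision is kept internally.  The suite asserts
the imbalance pathology exactly: a model predicting all-non-stress on a
90:10 test set scores 0.9 accuracy and 0 F1, which is why F1 is the
headline metric.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 6-minute sessions
(200/100/60 s) for the 15-participant strategy comparison and 5-minute
sessions for unit fixtures; these sizes keep full runs comfortable on a
laptop while leaving every structural property (window arithmetic,
feature counts, class imbalance, heterogeneity effects) intact.  The
qualitative finding — macro-F1 ordering individual ≥ centralized ≥
federated on heterogeneous cohorts — is checked across 5 cohort seeds
and required in at least 4; with the default generator it holds in all
5.  All randomness flows through explicit seeds: the same seed
reproduces cohorts, splits, SGD shuffles and therefore reports
bit-for-bit.

## Known limitations

* The generator's simplicity means classifier scores here say nothing
  about attainable accuracy on real wrist data; only relative topology
  behaviour transfers, and only to the extent real heterogeneity
  resembles the modelled kind.
* Stratified random splitting of overlapping windows leaks information;
  the chronological mode exists for leakage-free comparisons but is not
  the default, to match the protocol being modelled.
* The federated simulation is synchronous and lossless: no client
  dropout, stragglers, secure aggregation or differential privacy.
* Binary labels only; the amusement condition is folded into non-stress
  rather than treated as a third class.

## A worked run

```{r example, eval = FALSE}
plan <- session_plan(data.frame(
  condition = c("neutral", "stress", "amusement"),
  duration = c(150, 90, 60)))
cohort <- generate_cohort(3, atypical_fraction = 0, seed = 7, plan = plan)
fms <- lapply(cohort, build_feature_matrix)

reports <- list(
  evaluate_strategy(run_individual(fms)),
  evaluate_strategy(run_centralized(fms)),
  evaluate_strategy(run_federated(fms)))
compare_strategies(reports)
```

The same pipeline is scriptable end-to-end from a YAML experiment
config via `run_experiment()` / `run_experiment_cli()`; see the
packaged `inst/extdata/demo-experiment.yaml`.
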