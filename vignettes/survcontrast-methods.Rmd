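---
title: "Contrastive survival embeddings: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive survival embeddings: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `survcontrast`, the
training protocol, the synthetic-data generator used by the test suite, and
the design decisions taken where the method left genuine freedom.

## The two-stage model

Stage one learns an embedding. Training samples are sorted by
progression-free interval (PFI) and cut into `m = max(2, round(n/15))`
contiguous rank bins, so each bin holds roughly fifteen patients with
similar outcomes; ties in PFI are broken by original sample index so the
labeling is deterministic. Remainder samples are assigned to the
earliest (shortest-PFI) bins, giving bin sizes of `floor(n/m)` or
`floor(n/m)+1` exactly. An MLP encoder — sigmoid hidden layers, linear
output — is trained with the supervised contrastive loss over mini-batches:
for each anchor, same-bin members of the batch act as positives and all
other members form the denominator of a temperature-scaled softmax
(`tau = 0.07`). Anchors without positives contribute zero. Inner products
are taken on the **raw** embeddings; projecting to the unit sphere first is
available (`normalize = TRUE` in `encoder_spec()`) but off by default,
following the loss as written with plain `z_j' z_p` products. The gradient
is computed analytically (a softmax-minus-indicator matrix symmetrized
through the Gram bilinearity) and checked against finite differences in the
test suite.

Stage two fits a prognostic head on the embedded features: a Cox
proportional-hazards model `h(t,x) = h0(t) exp(f(x))` fit by minimizing the
negative log partial likelihood (elastic-net linear via glmnet, boosted
trees via xgboost's Cox objective, or a one-hidden-layer network trained on
the analytic score gradient), or a binary classifier of 3-year recurrence
risk. Risk sets use `t_j >= t_i` (censored-at-event-time individuals
included) and tied event times share the full risk set (Breslow; Efron is
exposed as an option on the unpenalized linear fit). The Breslow estimator
of the cumulative baseline hazard converts scores into survival curves
`S(t|x) = exp(-H0(t) exp(f(x)))` for Brier-score evaluation.

## Training protocol

One eighth of the training rows, stratified by bin, is held out as a
validation set. After every epoch the mean per-anchor validation loss is
computed and a running minimum maintained. Once 50 epochs have passed,
training stops the first time either (a) the validation loss exceeds the
minimum plus 0.01, or (b) 1500 consecutive epochs have stayed within 0.01
of the minimum without improving it; a hard cap of 5000 epochs always
applies. The returned weights are those of the minimum-loss epoch. The
plateau counter resets on every new minimum. This state machine lives in
`early_stop_monitor()` and is testable in isolation by replaying scripted
loss sequences (`replay_early_stopping()`); the same harness drives the
neural Cox head.

Model selection follows a two-level cross-validation scheme:
`select_encoders_cv()` scores encoder specifications by the mean (across
k folds) of the trained encoder's minimum validation loss and refits the
best; `select_head_cv()` then searches jointly over encoders, embedding
taps (any hidden layer or the output) and head hyperparameters. Heads are
selected by **held-out partial likelihood**, not by c-index: selecting on
the reporting metric would bias the reported metric upward, so the
concordance is logged but not optimized. For classifiers the selection
criterion is cross-validated AUC, which is also the reported metric there —
the single metric the classification pathway uses.

Hyperparameter defaults are desk-scale: hidden widths of tens to hundreds
of units rather than thousands, learning rates of 1e-6 to 1e-4 (small rates
paired with the 0.01 early-stopping tolerance keep epoch-to-epoch validation
noise below the stopping threshold), L2 weights around 1e-3, batch size 64,
and a few hundred epochs. The tests and the acceptance script state the
exact problem sizes they use (cohorts of 100-600 samples, 4-2000 genes);
these were chosen so the full suite retrains every model from scratch in a
few minutes.

## The synthetic generator

`simulate_cohort()` emulates the statistical structure the method assumes:
`k` standard-normal latent factors per sample; a fixed unit coefficient
vector on them defining the true log-hazard score `s = effect_size * b'L`;
expression built as `L %*% W + noise` with a sparse loading matrix (each
factor loads on ~10% of genes) and iid Gaussian gene noise, passed through
a softplus so values are nonnegative like normalized expression; event
times drawn from an exponential baseline scaled by `exp(s)` (the simplest
proportional-hazards-consistent choice — a Weibull shape parameter is a
natural extension hook); and independent exponential censoring whose rate
is calibrated by root-finding on the analytic two-exponential censoring
probability so the realized censored fraction matches the target. The
defaults (n = 300, p = 500, k = 5, effect 1.5, 30% censoring) mirror a
mid-sized tumor cohort with a moderate prognostic signal.

What the generator does **not** model, deliberately: RNA-seq count
distributions (the pipeline consumes normalized continuous values),
co-expression correlation structure, batch effects, and nonlinear
genotype-outcome links. Two consequences for interpreting test results.
First, passing tests show the machinery is correct and that the pipeline
recovers a planted signal; they do not certify performance on real tumors.
Second, because the planted signal is *linear and dense* in the genes, a
directly-fitted elastic-net Cox model is close to the oracle on this
generator, and the contrastive embedding — whose bin labels inherit the
full exponential noise of observed event times — has no headroom to beat
it. The package's own Monte-Carlo comparison therefore shows the
contrastive arms at or slightly below the raw arms *on simulated data*,
even though the embedding demonstrably carries the signal (it beats an
untrained encoder of identical architecture by a wide margin). On real
transcriptomes, where the signal is nonlinear and spread across strongly
correlated genes, the embedding-first strategy is reported to help; that
regime is outside what this generator produces, and we chose not to bend
the generator's simple, analyzable design toward it.

## Numerical choices and edge cases

* All log-sum-exp computations (contrastive denominator, risk-set sums) are
  max-stabilized.
* Day-to-year conversion uses 365.25; times are stored in years throughout.
* Expression orientation in delimited files is auto-detected as the axis
  whose labels overlap the clinical sample ids; an exact tie is an error
  rather than a guess.
* Housekeeping normalization divides each sample by the geometric mean of
  (1 + housekeeping counts), then applies log2(1 + x). The +1 offsets keep
  zero counts finite; the housekeeping gene list is a configuration input
  with no hardcoded default.
* `assign_risk_labels()` closes the boundary on the low-risk side: a PFI of
  exactly the cutoff is low risk.
* Hazard-ratio stratification computes thresholds on *training* hazard
  ratios only (median, or the 51st/73rd percentiles for three groups,
  linear-interpolation quantiles, ties to the lower group) and applies them
  to evaluation samples.
* The IBS grid defaults to 20 equally spaced times between the 5th and 95th
  percentiles of observed event times; grids beyond follow-up are truncated
  with a warning. Censoring weights come from the Kaplan-Meier estimate of
  the censoring distribution, by default on the training split.
* Harrell's c-index restricts comparable pairs to `t_i < t_j` with an event
  at `t_i`; exactly tied observed times are not comparable. Tied scores
  credit 0.5.
* The time-dependent AUC is the cumulative-case / dynamic-control IPCW
  estimand; without censoring it reduces exactly to the plain AUC on
  thresholded labels, and the suite asserts that identity to 1e-9.
* A mini-batch in which every anchor lacks positives yields a zero
  gradient; this is counted and logged, not fatal. A non-finite validation
  loss aborts training with diagnostics.
* Monte-Carlo cross-validation derives the seed of repeat `r` as
  `base_seed + r`; every fitting routine records the sample ids it was
  trained on while the harness's leakage guard is active, and the run
  aborts if a held-out id ever reached a training call.

## Pooling and model transfer

`pool_cohorts()` row-concatenates cohorts of transcriptionally similar
cancer types on their shared gene set; PFI bins are recomputed on the
pooled sample (per-cancer binning is available as an option) and the
per-sample cancer type is retained so the downstream head can be trained on
the target cohort alone while the encoder sees the pool. Applying a saved
model to an external cohort aligns the new expression matrix to the
training gene order, zero-filling genes the cohort lacks (with a warning
stating the count) — the convention for transferring a fixed-input model
across platforms.

## Known limitations

The encoder is plain SGD without momentum or adaptive steps, which is
faithful to the protocol but slow at large widths; widths in the thousands
are impractical in pure R. Only right censoring is supported — no competing
risks, time-varying covariates or stratified baselines. The generator's
independent-censoring assumption matches the IPCW metrics' assumption, so
those metrics are exactly calibrated on simulated data but only
approximately on real cohorts with informative censoring.
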