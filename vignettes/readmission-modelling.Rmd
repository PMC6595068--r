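---
title: "Timeline-aware modelling of 30-day readmission after heart-failure hospitalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timeline-aware modelling of 30-day readmission after heart-failure hospitalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thirty-day all-cause readmission after a heart-failure (HF) hospitalization
is a standard quality indicator: roughly a quarter of HF admissions in US
all-payer claims data are followed by another admission within 30 days of
discharge. `readmitr` implements a complete study pipeline for comparing
*timeline-aware* predictive models (which read a patient's whole ordered
admission history) against *event-view* baselines (which see only the most
recent admission) on this outcome. Because the national claims databases
that motivate this design are access-restricted, the package ships a
synthetic claims generator with a controllable, fully known readmission
mechanism; every downstream component is exercised against that ground
truth.

The pipeline has five layers:

1. **Claims simulation** (`sim_config()`, `generate_claims()`),
2. **Timeline construction and labeling** (`build_timelines()`),
3. **Feature encoding** (`fit_schema()`, `encode_batch()`,
   `event_view_features()`),
4. **Models and objectives** (`model_config()`, `fit_model()`,
   `predict_proba()`, `loss_spec()`, the chain-CRF layer),
5. **Evaluation and interpretation** (`make_folds()`, `cv_auc_ci()`,
   `youden_cutoff()`, `lasso_importance()`, `perturb_importance()`),

orchestrated end to end by `run_study()` and by the numbered scripts under
`analysis/`.

## The synthetic claims generator

Each patient receives an admission count drawn as
`1 + Poisson(mean_events - 1)`, static demographics (age ~ Normal(73, 14)
rounded and clamped, 49% female, a Medicare-dominated payer mix), a set of
comorbidity flags, and per-admission diagnosis/procedure code sets with an
HF-primary indicator (probability `p_hf_primary = 0.669`). Dates are
integer day offsets inside one observation window; stays never overlap.

The readmission mechanism is the part the analysis must recover. After
*every* admission `t` a short-gap indicator `s_t` is drawn with probability

```
p_t = sigmoid( qlogis(base_readmit_rate)
             + beta_history . h_t        # standardized (prior events, prior short gaps)
             + beta_event   . x_t )      # standardized (HF flag, length of stay, comorbidity count)
```

A short gap places the next admission 1-30 days after discharge; a long gap
31-`long_gap_max` days. Standardization uses the closed-form moments of the
configuration (Poisson moments for the prior-event count, a
binomial-mixture approximation for the prior-short-gap count), never
empirical moments, so the mechanism is identical at every cohort size.

Two design points deserve emphasis:

* **Labels are never stored.** The generator records the drawn `s_t`
  (as `attr(claims, "mechanism")`, used by tests) but the analysis labels
  come exclusively from `build_timelines()`. When the *final* admission of
  a patient draws a short gap, the generator materializes that readmission
  as one extra non-HF admission, so the 30-day rule applied downstream
  recovers the drawn indicator exactly; with all betas zero the labeled
  HF-event readmission rate is therefore calibrated to
  `base_readmit_rate` (0.236 by default) rather than being diluted by
  final events, which would otherwise all be forced to label 0.
* **The inter-admission gap mixture is a modelling choice.** Real claims
  data do not reveal a parametric gap law; uniform short (1-30) and long
  (31-75) components keep the label rule exact and the boundary at 30 days
  well exercised. Nothing downstream depends on the specific long-gap
  shape.

What the generator deliberately does *not* emulate: seasonal admission
patterns, hospital/state structure, survey weights, code co-occurrence
structure, mortality, or transfers. Passing tests on this cohort therefore
demonstrate correctness of the pipeline and the *relative* behaviour of
model classes under a known mechanism - not clinical performance on real
claims.

One structural consequence worth knowing: `p_hf_primary = 0.669` is the
per-admission probability for mechanism events, but two processing steps
move the observed shares away from it. The materialized final readmissions
are always non-HF, so the raw claims table shows ~59% HF-primary; and
cohort timelines are truncated at the last labelable HF event, so every
retained timeline *ends* in an HF admission, which pushes the HF share
among retained events up to ~0.85 at mean length 1.9. The ~67% target is a
property of the admission process, not of either derived table.

## Timelines and the 30-day label

Events are sorted per patient by admission day (ties: discharge day, then
input order). A patient enters the cohort if some admission has HF as
primary diagnosis (CCS code 108), at age >= 18, early enough in the window
for a full 30-day lookahead (`admit_day <= window_end - 30`, the
fixed-window analogue of a January-November index period). For every event
with a successor, `y_t = 1` iff the next admission starts within 30 days of
discharge, *inclusive at 30*. A final observed event is labeled 0 only when
at least 30 days of observation remain after its discharge; otherwise it is
censored and removed. The timeline is then truncated at the last labelable
HF event and patients without one are dropped. Labels are computed for all
events (HF and non-HF alike) because the `Convex_HF_NonHF` objective needs
non-HF losses; the objectives select which events contribute.

Events occurring after the last labelable HF event are dropped, and a
non-HF final event cannot end a retained timeline; both choices follow from
making the last HF event the prediction target.

## Encoding

A `feature_schema` is fitted on the training fold only: lexicographically
sorted vocabularies with an explicit UNK slot per categorical block
(primary diagnosis, sex, pay source one-hot; secondary diagnoses,
procedures, comorbidities multi-hot) and train-fold mean/SD for the numeric
fields (age, length of stay, event index). A constant numeric field falls
back to SD 1 with a message. Sequence batches are padded to `t_max` (default:
the 95th percentile of training timeline lengths, capped at 20 - mean
length is ~1.9, so large padding is waste); longer timelines keep their
most recent `t_max` events with original event indices. Event-view models
see the last HF event's vector; for LR (and only LR by default) two
standardized timeline-summary features - prior admission count and prior HF
count - are appended, mirroring the augmentation that makes the baseline
face-off fair.

Class imbalance is handled by inverse-frequency weights
`w_c = N / (2 N_c)`, so the weighted class frequencies average to 1.

## Objectives

The per-step loss is weighted cross-entropy. Four sequence-level
definitions are supported (`loss_spec()`): the loss of the last HF event
(`LastHF`); the uniform average over HF events (`Uniform_HF`); and two
convex combinations, `alpha * mean(HF) + (1 - alpha) * lastHF` and
`alpha * mean(HF) + (1 - alpha) * mean(nonHF)`. The direction of `alpha`
is a pure relabeling; this package fixes `alpha` as the weight of the
HF-average term and pins that orientation with endpoint tests
(`alpha = 1` reduces to `Uniform_HF`, `alpha = 0` to `LastHF`). When a
timeline has no non-HF events the non-HF average is defined as zero, so
`Convex_HF_NonHF` on a single-event timeline equals `alpha` times the
last-event loss. `alpha` is a validation-set choice; a grid of
0.1, ..., 0.9 through `random_search()` is the intended selection route. The
total objective is the mean per-sequence loss plus `lambda/2 ||theta||^2`
with biases excluded; dropout (`p_dropout`) is available for all hidden
layers.

## The model zoo

All models share one contract: `fit_model(config, train, valid)` returns a
deterministic fitted model (given `config$seed`) whose
`predict_proba()` is the readmission probability of the last HF event.
Gradient-trained families run minibatch SGD (plain, momentum or Adam),
with global gradient-norm clipping (default 5) and per-epoch validation
AUC; the returned parameters are the best-validation-epoch checkpoint.
Plain SGD is the default optimizer; the adaptive variants are config
options, and the analysis scripts use Adam for speed at small epoch
budgets.

* **RNN**: GRU (default) or LSTM over the padded sequence, per-step
  softmax, back-propagation through time. All four loss kinds apply.
* **RNNSS**: the same network with scheduled sampling - the previous
  step's label, one-hot, is concatenated to the input; with probability
  `eps` the true label is fed, otherwise a label sampled from the model's
  previous prediction. `eps` starts at 1 and decays per epoch (linear,
  exponential, or inverse-sigmoid schedules; `ss_probability()`). At
  prediction time the model greedily feeds its own previous predictions;
  step 1 receives a neutral (0.5, 0.5) token. Because the feedback channel
  changes the input dimension, a scheduled-sampling network with `eps = 1`
  is teacher forcing, not literally the plain RNN; the shared machinery is
  what the two families have in common.
* **CRF layer**: an exact first-order linear chain over the binary labels
  (`chain_potentials()`, `log_partition()`, `crf_marginals()`,
  `crf_viterbi()`), open at both ends, all inference in log-space. Two
  potential variants: `Unary` (per-step unary scores plus one static
  transition matrix A) and `Pairwise` (input-dependent per-step 2x2
  transition scores that replace A and subsume the unaries for t >= 2,
  step 1 keeping a unary term - the parsimonious reading of an
  input-dependent pairwise parameterization). Viterbi ties break toward
  label 0.
* **CRF_only / NeuralCRF / RNNCRF**: chain CRFs whose potentials come from
  an affine map of the raw features, a one-hidden-layer tanh transform, or
  the recurrent feature stream. Training minimizes the exact negative
  conditional log-likelihood (gradient = marginals minus indicators,
  verified against finite differences); each sequence is weighted by the
  class weight of its last-HF label. The readmission score is the
  forward-backward marginal `p(y_T = 1)`.
* **CNN / CNN_Wide**: sequence-classification views of the padded
  timeline matrix. The square-kernel network stacks two conv(3x3, same
  padding) + relu + maxpool(2x2, ceiling) blocks before a fully-connected
  layer; the wide network uses full-width kernels of heights {2, 3, 5}
  with max-over-time pooling to one scalar per kernel. Both use the
  last-HF loss only.
* **MLP / LR**: event-view baselines. LR is fitted by penalized maximum
  likelihood (glmnet coordinate descent, threshold 1e-10) with l1 (LASSO)
  or l2 penalty and inverse-frequency observation weights; when several
  penalty strengths are offered the validation AUC picks one.

## Evaluation protocol

Stratified 5-fold cross-validation on the last-HF-event label, each
training set carrying a nested stratified 10% validation split (epoch and
hyperparameter selection only). The AUC is the rank/U-statistic form with
half-credit ties. The cross-validated AUC interval follows the
influence-function approach for cross-validated AUCs: fold-wise influence
curves are pooled and the normal interval uses `Var(IC)/N`; whether to pool
observations or average fold AUCs is a known fork - this package averages
fold AUCs and pools influence curves, and a 2,000-resample bootstrap is
provided as an independent cross-check (the two agree to well within 20%
relative width in the coverage simulation, which attains ~0.94 empirical
coverage at the nominal 0.95). Operating cutoffs maximize the Youden index
(sensitivity + specificity - 1) on the probability scale, ties toward the
smallest cutoff; per-fold cutoffs are averaged with their SD. "Cumulative"
AUC-by-timeline-length pools patients with length <= L (the `== L` variant
is available by flag).

Hyperparameter search is uniform random sampling over a discrete space,
trained on 90% of a 30% subsample of one fold's training patients and
scored on the remaining 10% - a deliberate economy matching how such
searches are run when full-cohort search is infeasible (default budget: 20
trials).

## The history-signal experiment

The central scientific claim the pipeline can test on synthetic data:
*timeline history improves prediction exactly when the mechanism has a
history channel.* Two named conditions (`history_cohort_config()`) share
longer timelines (mean 4 admissions; a 540-day window, since histories
must fit inside the window to exist) and a strong current-event
length-of-stay effect (`beta_event = (0, 3, 0)`). The history-driven
condition adds `beta_history = (0, 3)`: the last label depends on the
standardized *prior short-gap count*, which is latent - but because past
lengths of stay strongly predicted past short gaps, a sequence model can
reconstruct it from the event stream, while an event-view model cannot
(the prior-*event* count channel is deliberately left at zero because the
event-index feature makes it visible to both views). Design calibration
against the generator's own Bayes oracles puts the reachable AUC gap near
0.08; the acceptance suite requires a mean gap >= 0.05 over three seeds
on the history-driven cohort and <= 0.02 on the memoryless one, and the
trained GRU in fact approaches the observable-history oracle.

## Numerical choices and degenerate inputs

* Chain inference is exact and runs entirely in log-space; scores up to
  +-1e3 are safe (tested at 100x random scale).
* Probabilities inside cross-entropy are clamped at 1e-12.
* Finite-difference gradient checks cover every family; relu/max-pool tie
  points are jittered away in those checks because two-sided differences
  are undefined exactly at a kink.
* Training aborts with the epoch and step size when the loss turns
  non-finite; `epochs = 0` returns the initialization flagged untrained.
* Empty cohorts, single-class folds/labels, unsorted event lists, schema
  mismatches and test-tagged training batches all raise early, named
  errors.
* Seeds: one master seed per study; every stage derives its own stream by
  stable string hashing, so adding a stage never perturbs another stage's
  draws, and all derived seeds stay below 2^31.

## Problem sizes used in the shipped runs

The test suite and analysis scripts run cohorts of 4,000-40,000 patients
(40,000 for generator calibration, where the binomial SE at ~50,000 HF
events is ~0.002; 16,000-20,000 for the history experiment; 6,000 for the
model face-off with 5-fold CV), GRU/MLP widths of 16-24, and 6-8 training
epochs with Adam. These sizes were chosen so the full study reruns in
minutes on one CPU while keeping every statistical check comfortably
powered; they are package defaults, not limits - every size is a config
field.

## Known limitations

* The synthetic cohort is far simpler than national claims data; absolute
  AUCs here say nothing about real-world performance.
* The CRF label space is binary by design; the exact-inference layer would
  generalize but is not exposed for |V| > 2.
* Scheduled sampling treats the fed label as a constant input (no gradient
  through the sampling decision), the standard estimator.
* LR hyperparameter selection sees the full training fold, mirroring the
  asymmetry the original face-off acknowledged between LR and the
  subsample-searched neural models.
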