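---
title: "Estimating fine-motor impairment from keystroke dynamics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fine-motor impairment from keystroke dynamics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fmikeys` estimates the severity of Parkinsonian fine-motor impairment (FMI)
from the timing of natural touchscreen typing. This vignette is the
package's own account of the science: the models, their assumptions, the
parameters that matter, what the synthetic cohort does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## From keystrokes to model inputs

A typing session is an ordered list of press/release timestamp pairs. Two
sequences summarise the motor content of a session:

* **hold time** `HT[n] = t_r[n] − t_p[n]` (seconds): dominated by the
  down-phase of a single finger tap; rigidity and bradykinesia lengthen it
  and make it more variable;
* **flight time** `FT[n] = t_p[n+1] − t_r[n]` (seconds): the between-key
  transition, reflecting movement speed and planning.

Three element-wise filters clean the sequences before modelling, each with a
configurable threshold (`filter_config()`):

| parameter | default | why |
|---|---|---|
| `ht_longpress_cutoff` | 0.5 s | mobile keyboards use long-presses for special actions (accented characters); these are deliberate, not motor-impaired, taps. The capture format does not record key identity, so the cutoff is the only way to recognise them. 0.5 s is the common mobile-OS long-press delay. |
| `ft_upper_bound` | 3 s | longer gaps are pauses (reading, thinking), not fluent typing; they are removed, not clipped, because a clipped value would still be a fabricated observation. |
| negative FT | always removed | a press before the previous release (rollover typing) makes the transition time physically meaningless for a sequential-tap model. |
| `min_keystrokes` | 40 | sessions shorter than this carry too little signal to score; this is the validity floor used throughout. |

Filtering removes single elements and leaves neighbours untouched — we do
not re-derive an FT across a removed element, because splicing two
non-adjacent keystrokes would fabricate a transition that never happened.
Filtering is therefore idempotent, which the test suite checks.

Valid sessions become `2 × 100` matrices (HT, FT channels), zero-padded on
the right. Sessions longer than 100 keystrokes are split into consecutive
non-overlapping 100-sample windows; a trailing window is kept only if it
alone satisfies `min_keystrokes`. Overlapping windows were rejected because
they would duplicate keystrokes across inputs and silently overweight long
sessions.

## The hybrid model

The estimator is trained in two stages because labelled data are the scarce
resource: clinically scored cohorts are small, while unlabelled typing is
abundant.

**Stage 1 — representation learning.** A 1D convolutional autoencoder is
trained on unlabelled inputs to reproduce them (mean squared error). The
default encoder has three same-padded conv layers, filters (32, 16, 8),
kernels (5, 3, 3), ReLU, with 2× max-pooling after the first two layers,
compressing `2 × 100` to an `8 × 25` bottleneck (200 features); the decoder
mirrors it with nearest-neighbour upsampling and a linear output layer. The
architecture grid is constrained to kernels {3, 5} and filters in [8, 32]
(`autoencoder_config()` enforces this). Training: RMSprop, learning rate
1e−3, 50 epochs, mini-batches of 64, on a seeded 80/20 train/held-out split
of the input pool. The split is by input (segment), not stratified by
subject — pretraining is unsupervised and subject identity is irrelevant to
the reconstruction objective.

**Stage 2 — fine-tuning.** A two-layer fully-connected head — one rectified
hidden layer (default 50 nodes; 10/20/50/100 is the intended grid) and a
linear scalar output — maps the bottleneck to one UPDRS Part III item score
(22, 23 or 31, each on the raw 0–4 scale; no target normalization, since
the loss is MSE against the clinical score itself). Training: RMSprop, 50
epochs, mini-batches of 32. Evaluation uses leave-one-subject-out
cross-validation: every prediction is made by a model that never saw that
subject.

`n_frozen_conv_layers` controls how much of the pretrained encoder is
updated during fine-tuning. The package default freezes **all** conv layers
(pure feature-extraction transfer). Rationale: the frozen depth is a search
dimension of the method, not a fixed commitment; freezing everything makes
the encoder a fixed feature map, so LOSO folds share one encoding pass and
the full recovery experiments stay tractable on a single CPU; and at the
cohort sizes the package targets, end-to-end updates of the conv stack on a
few hundred labelled inputs mostly re-learn what pretraining already
provides. End-to-end training (`n_frozen_conv_layers = 0`) is fully
implemented — it is exactly how the no-pretraining baseline is trained in
the ablation.

**Stage 3 — subject-level indices.** Per-session estimates (segments of one
session are averaged first) are aggregated per subject. In-the-clinic
sessions follow a controlled protocol with similar per-session
distributions, so the mean is used. In-the-wild contributions are
heterogeneous, so the three quartiles (linear interpolation between order
statistics, R's type-7 rule) summarise a subject, and the scalar index
defaults to the median — the robust middle of the three; all three
quartiles are always reported (`q25_*`, `q50_*`, `q75_*` columns) because
the choice of combiner is a genuinely open question. The indices are named
dRSi (item 22), dAFSi (item 23), dBSi (item 31).

The neural-network engine is authored in the package (vectorized R with the
conv im2col/GEMM hot loops in C++ via Rcpp/RcppArmadillo): layers, exact
backpropagation, and RMSprop (ρ = 0.9, ε = 1e−8). The backward pass is
verified against central-difference gradients in the test suite. All
randomness — initialization, batch order, splits, fold seeds — derives from
one integer seed through fixed sub-streams, so every fitted object and
artifact is reproducible from its config.

## The synthetic cohort

Clinical keystroke corpora are not publicly available, so the package ships
a generator (`sample_cohort()`) whose defaults define the study conditions
used by the tests and the acceptance script.

Each subject carries three latent item severities on the continuous 0–4
scale, pairwise correlated 0.7 via a Gaussian copula (the three FMI items
co-vary clinically but are not identical); recorded item scores are the
latents rounded to integers, modelling the quantization the clinical scale
imposes. Healthy controls draw latents in [0, 0.8]; patients in [0.3, 4].
The *mean* of the three latents drives typing:

* `HT ~ lognormal(median 0.10 s + 0.02 s × severity, sdlog 0.25 × (1 + 0.10 × severity))`
* `FT ~ lognormal(median 0.25 s + 0.05 s × severity, sdlog 0.60 × (1 + 0.10 × severity))`

i.e. location grows linearly and dispersion multiplicatively with severity —
the simplest mechanism that makes impaired typists both slower and less
rhythmic, and that leaves a monotone, recoverable signal. Sessions have
negative-binomial length (mean 80, size 12, floor 1), so with the default
mean well above the 40-keystroke floor, over 90 % of sessions are valid.
Typing artifacts are planted so the filters are exercised: 2 % deliberate
long-presses (0.6–1.5 s), 1 % pauses (3–10 s), 1 % rollover taps (small
negative FT). The default cohort shape is 17 HC / 22 PD with 9 de novo
(drug-naive, assigned to the mildest patients). Per-subject randomness uses
sub-streams keyed by subject index, so enlarging a cohort does not
reshuffle existing subjects. Where the literature offers no quantitative
effect sizes for PD vs HC keystroke distributions, these values were chosen
once as clinically plausible and are all configurable.

What the generator does **not** emulate: key identities and language
content, device and keyboard-layout heterogeneity, pressure, learning
effects over weeks, diurnal rhythm outside the ON/OFF mechanism, and
comorbidities that also slow typing (arthritis, depression, sleepiness).
Passing recovery tests on this cohort therefore shows that the pipeline
recovers a planted monotone severity signal through the full stack — not
that clinical effect sizes of that magnitude exist in real typing data.

Medication state is simulated by `sample_onoff_day()`: each intake opens an
ON phase (default 180 min) with 30-minute linear transitions before and
after; during OFF the subject's effective severity is multiplied by 1.6
(configurable, > 1). The analysis side (`build_onoff_ground_truth()`,
`hourly_median_index()`, `onoff_correlation()`) mirrors this: a 0/1
trapezoid reference over the 08:00–22:00 window, hourly medians of the
absolute index (hours without sessions are marked missing, never
zero-filled), and a Pearson correlation on the overlapping hours after
averaging the trapezoid within each hour to match resolutions. Severity
rises when medication wears off, so recovered correlations are negative.

## Evaluation battery

* **Correlation**: `pearson_correlation()` wraps the standard t-transform
  test.
* **ROC/AUC**: the AUC is computed as the pairwise concordance probability
  with ties counted ½ (the Mann–Whitney identity) — an explicit convention
  the tests pin against a brute-force pair count and against an independent
  ROC implementation.
* **Bootstrap CIs**: percentile 2.5/97.5 over 1,000 seeded resamples.
  The resampling unit is the subject, because the indices are per-subject
  quantities; resamples that lose one class entirely leave the AUC
  undefined and are redrawn (and counted). The percentile method was chosen
  over BCa as the simplest defensible interval; the report records the
  method.
* **Sensitivity at specificity**: for targets 70/80/90 %, the threshold is
  the one whose specificity is the *smallest value still ≥ the target* — no
  interpolation, exactly reproducible. Thresholds are searched over the
  observed scores plus the all-positive endpoint; the degenerate
  call-nobody-positive rule is not an admissible operating point, so a
  target can be genuinely unattainable, which yields a flagged row rather
  than an error.
* **Scenarios**: `scenario_report()` reproduces the three screening
  structures — T1 (clinically scored cohort: correlations + ROC), T2 (de
  novo patients vs controls), T3 (self-reported labels, ROC only).

### A note on the zero-effect control

With the severity→dynamics effects set to zero, index-vs-severity
correlations should vanish. Computing that control from LOSO predictions is
misleading: when features carry no signal, each fold's model predicts its
own training-label mean, which is systematically *anti*-correlated with the
held-out subject's score (leaving a high-score subject out lowers the
training mean). This is an evaluation artifact of LOSO with uninformative
features, not information leakage. The package's recovery experiments
therefore train on a development cohort and score a *disjoint* test cohort
— the same structure a deployed screening model faces — where the null
control behaves as pure noise. LOSO remains the protocol for fine-tuning
evaluation and the ablation, where real signal dominates the artifact.

## Explanation maps

`saliency_map()` computes the gradient of the scalar severity output with
respect to the `2 × 100` input, takes absolute values and max-normalizes the
map per session to [0, 1]. Plain input-gradients were chosen over smoothed
or integrated variants to keep the attribution directly interpretable as
local sensitivity and free of extra hyperparameters. Attribution mass on
the zero-padded tail is reported but flagged (`padded` column in the tidy
form): gradients there reflect the network's treatment of padding, not
typing behaviour.

## Problem sizes and numerical choices

The experiments the package runs by default were sized once for a
single-CPU workflow and are stated here as the package's choices: pretraining
pools of roughly 1,000 inputs for 12–15 epochs; recovery experiments with a
20-subject development cohort (60 sessions each) and a 40-subject test
cohort (200 sessions each) with 50-epoch heads; the pretraining ablation on
a 10-subject cohort across 5 random states at 10–12 epochs; ON/OFF
case-studies of 10 simulated days with 60 sessions per day. Weight
initialization is He-normal; RMSprop uses ρ = 0.9, ε = 1e−8; quantiles are
type 7 everywhere; session JSON is written with 17 significant digits so
round trips are bit-exact; max-pooling breaks ties toward the earlier
sample.

## Known limitations

* The generator's effect sizes are plausible but invented; absolute
  performance numbers on synthetic cohorts say nothing about clinical
  effect sizes.
* The severity signal is driven by a single latent per subject, so the
  three indices are more inter-correlated than clinical items may be.
* A session's segments and sessions are conditionally independent given
  severity; real typing has autocorrelation within and across sessions.
* The engine is CPU-oriented and deliberately small; it is not a framework
  for architecture search beyond the stated grid.
* Self-report noise in T3-style cohorts is not modelled (the synthetic
  manifest's group label is exact).
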