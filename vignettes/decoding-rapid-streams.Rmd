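---
title: "Decoding overlapping brain responses in rapid visual streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding overlapping brain responses in rapid visual streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In rapid serial visual presentation (RSVP), images are flashed at roughly
8.6 Hz (stimulus onset asynchrony, SOA, of 116 ms), so the evoked response
to each image — which unfolds over 500 ms or more — overlaps the responses
of its four or five nearest neighbours in the stream. Univariate averaging
cannot separate these superimposed responses. Multivariate decoding can:
category-selective classifiers trained on single-stimulus ("localizer")
epochs act as matched filters for each image's category and can be applied
to the stream at every time point, recovering each stimulus's processing
trajectory independently of its neighbours.

The scientific question this pipeline addresses is how *temporal attention*
selects a cued target (T2) from the stream. Two hypotheses make distinct,
decodable predictions:

* **Gradual selection** — attention simultaneously amplifies several
  stimuli around the target with graded strength. Prediction: the early
  sensory code (trained ~170 ms post-onset) should stay decodable into a
  late window (400–550 ms) not only for the target but for its temporal
  neighbours, with amplitude following a graded profile over stream
  position.
* **Discrete selection** — attention is all-or-none; only the stimuli the
  subject eventually reports receive a late processing stage. Prediction:
  a late code (trained ~370 ms) is decodable in the 400–550 ms window only
  for reported stimuli, graded by report order, and sits exactly at chance
  for unreported stimuli.

Because no public recordings accompany the design, the package pairs the
decoding pipeline with a forward simulator whose ground truth is known.
Every claim the pipeline makes is validated as a *recovery* experiment: the
simulator injects one selection regime and the pipeline must detect it.

## The forward model

Sensor data are generated as a noisy linear superposition of per-stimulus,
per-stage responses:

$$x(t) \;=\; \sum_{i=1}^{12}\sum_{s} g_{i,s}\, \mathbf a_{c_i,s}\,
k_s(t - \mathrm{onset}_i) \;+\; \varepsilon(t),
\qquad \varepsilon \sim \mathcal N(0, \sigma^2 I),$$

where $c_i$ is the category of the image at stream position $i$,
$\mathbf a_{c,s}$ a unit-norm sensor topography for (category, stage),
$k_s$ a smooth non-negative stage envelope with peak 1, and $g_{i,s}$ the
attentional gain. T1 (position 0) is a colour patch with no category code
and enters only as the timing anchor; onsets $i \times 116$ ms are rounded
to the 100 Hz sample grid and those rounded onsets are used everywhere
downstream.

**Stages.** Four envelopes model the response cascade:

| stage   | window (ms) | shape                | topography | role |
|---------|-------------|----------------------|------------|------|
| early   | 90–230      | raised-cosine bump   | own        | feed-forward transient |
| mid     | 220–330     | raised-cosine bump   | own        | intermediate processing |
| late    | 350–720     | plateau, 100 ms ramps| own        | late task-related stage |
| sustain | 440–720     | plateau, 100 ms ramps| early      | attention-dependent prolongation of the early code |

Each envelope has a 50 ms skirt on either side of its window and is zero
outside. The sustain segment deliberately *reuses the early topography*:
this is what makes a 170 ms classifier "reactivate" late in the epoch, the
biphasic signature the pipeline looks for. Stage peak amplitudes default to
1, 0.7, 0.5 and 0.8 (early, mid, late, sustain): with sensor noise
$\sigma = 1.5$ a single-stimulus epoch decodes at roughly 0.32–0.35 mean
correct-class probability around the early transient, and — because a
localizer stimulus is an attended target carrying both the late stage and
the sustain segment — at a comparable level through the sustained phase,
so the group diagonal's maximum can fall in either region. Distractors in
the stream, which lack both late components, show the early-peaked,
decaying profile.

**Selection models.** The two regimes are implemented in pure form.
Gradual: $g_{i,\mathrm{sustain}}$ follows an asymmetric Gaussian of the
positional distance $d = i - T$, with width $\sigma_R = 0.4$ positions
after the target and $\sigma_L = 1.4$ before it (asymmetry 3.5), peak 1 at
the target; no stimulus receives the late stage. Discrete:
$g_{i,\mathrm{late}}$ is nonzero *only* for the three reported positions
(1, 0.6, 0.35 by guess order), and the sustain segment is absent. The
localizer, being a single attended stimulus, carries all four stages at
unit gain. The strong forward asymmetry was fixed during generator design
so that the injected gains at the seven analyzed offsets (T−4…T+2) are
pairwise rank-distinct (a well-defined Spearman recovery target) and so
that post-target positions sit essentially at chance, matching the
qualitative physiology the simulator is meant to emulate; it was not tuned
against any test statistic afterwards.

**Behaviour.** Three distinct guesses are drawn without replacement from a
report distribution over positions 1–12: a discretized Gaussian
(σ = 1.2 positions) centred on the target mixed with a uniform guessing
floor (0.15) under the gradual model, or a target point-mass plus floor
under the discrete model. A per-lag modulation (0.8, 0.5, 0.9, 1.0 for
lags 1, 3, 7, 9) scales both the neural gains and the behavioural
precision, producing an attentional blink with lag-1 sparing. In the
discrete model behaviour is sampled *first* and the late-stage gains are
then conditioned on the sampled guesses, so neural and behavioural reports
agree trial by trial.

Topographies are drawn independently per subject: subjects differ in head
geometry, so pattern geometry must vary at the subject level. (Sharing one
topography set across subjects would make the pattern draw a dataset-level
random effect that no number of subjects averages away — a
pseudo-replication structure real recordings do not have.)

What the simulator does **not** model: realistic forward fields (no head
model or dipoles), 1/f or spatially correlated noise (an AR(1) temporal
option exists, white is the default — the simplest model under which the
decoder's null is exactly calibrated), eye/cardiac artifacts, or any
T1-related signal. Passing recovery tests therefore demonstrates the
pipeline's correctness and sensitivity under linear superposition with
homogeneous Gaussian noise — not performance on real recordings.

## The decoding pipeline

Per time sample, features are the sensor values, z-scored with mean/sd
estimated from the *training trials only* (refit in every fold; the stored
scaler travels with the classifier, so a classifier applied at another
time or task reuses its own training normalization). The classifier is a
bank of one-vs-rest linear hinge-loss SVMs with C = 1, class-balanced
sample weights, solved by dual coordinate descent (liblinear's algorithm,
with shrinking; a fixed deterministic shuffle stream makes refits
bit-for-bit reproducible). Probabilistic outputs come from per-class Platt
sigmoids fitted on the training decision values with smoothed targets,
then normalized across classes to sum to one; "classification performance"
is throughout the mean probability assigned to the true category (chance
0.25 with four classes), with hard-label accuracy as a secondary metric
only. The sigmoid slope is constrained non-positive so calibrated
probabilities are monotone in the decision values.

Temporal generalization trains at every sample of the −50…550 ms localizer
grid and tests at every sample, within a 5-fold stratified
cross-validation so train- and test-time data always come from independent
trials. For localizer-to-stream transfer, classifiers are refit on the
full localizer and applied without refitting to per-stimulus epochs of the
stream (0–900 ms after each rounded onset, closed-open windows
throughout). Per-stimulus correct-class probabilities are averaged per
trial, then per condition (target vs non-target, lag, guess membership),
then tested across subjects with Wilcoxon signed-rank tests and
Benjamini–Hochberg FDR within explicitly declared families (testing times
× anchor training times 120–370 ms × conditions/positions). Tests against
chance are one-sided (greater), between-condition tests two-sided; the
choice is recorded in each result row since the convention is not forced
by the procedure. Onsets/offsets of decodable periods use the
median-threshold rule (first/last sample strictly above the timecourse's
50th percentile, on group-averaged data). The moving-average smoother
(window 3) exists for exported timecourses only and is never applied
before statistics.

Weights are made interpretable by the activation-pattern transform
$\mathbf a = \Sigma \mathbf w$, computed in the z-scored space where the
weights live (covariance pooled over training trials; the class-pooled
choice follows the standard transform) and mapped back to sensor units via
the stored scale. Note that a one-vs-rest discriminant's ground truth is a
category *contrast* — its pattern contains negative images of the other
categories — so recovery is assessed against the injected contrast
topography, where near-perfect cosines are attainable; against a single
category topography the cosine is bounded near 0.87 by construction.

## Statistics layer

The signed-rank test drops exact zeros, mid-ranks ties, and reports
$W$ = sum of positive-difference ranks. For $n \le 15$ the p-value is
exact, from the full $2^n$ sign-assignment distribution of the observed
(possibly tied) ranks via a convolution over doubled ranks; beyond that a
normal approximation with tie and continuity corrections takes over (the
two agree within 0.02 at the boundary). BH-FDR adjustment delegates to the
standard step-up implementation and is checked against the hand formula.
The factorial nonparametric analysis is a repeated-measures ANOVA on
aligned-rank-transformed data: per effect, responses are aligned by cell
means (subtract the cell mean, add back the effect's own estimated
contribution), mid-ranked over the whole dataset, and submitted to a
balanced within-subject ANOVA with the effect-by-subject stratum as error.
Alignment operates on the raw scale, so the procedure is invariant to
positive affine — not arbitrary monotone — transforms; its interaction
type-I error under nulls with strong main effects is verified by
simulation (0.05 ± 0.01).

## Model identification

A run is labelled by the early-vs-late signature at the target position:
mean performance in the 400–550 ms window for the 170 ms classifier minus
the same for the 370 ms classifier. Gradual selection makes the early
elevation dominate (the sustain segment carries the early code into the
window, nothing late is gated); discrete selection reverses the sign.

## Problem sizes, defaults, and what the checks run

Generator defaults mirror the reference design: 15 subjects, 300 localizer
and 300 RSVP trials per subject, 13-stimulus streams, lags {1, 3, 7, 9},
102 sensors, 100 Hz. The validation experiments run scaled-down but
statistically adequate sizes, chosen once as the package's analysis
configuration: 30 sensors, 160 localizer trials, N = 15 subjects per
experiment, 96 RSVP trials for the 10-seed-per-regime recovery studies and
the full 300 for the single overlap-separability experiment (whose weakest
probed code, the fading mid-stage tail at 330 ms post-onset, needs the
full design's power); the null-calibration study uses 100 label
permutations of a 200-trial localizer. Positional profiles pool lags 7 and 9 (so offsets
T−4…T+2 exist in the stream) and compare positions relative to the target;
the "unreported" control stimulus is drawn uniformly (seeded) from the
nine positions outside the three guesses on each trial.

Numerical conventions worth knowing: all windows are closed-open
$[t_0, t_1)$; the localizer epoch grid is the 61-sample inclusive
−50…550 ms grid; dual coordinate descent stops at a projected-gradient gap
of 0.01 (tests that compare hyperplanes to oracles tighten this); ties in
hard labels resolve to the fixed class order (hard labels feed confusion
matrices only); the anti-alias filter for down-sampling is a zero-phase
FIR with unit DC gain and reflection padding, cutoff 30 Hz when targeting
100 Hz.

## Known limitations

Identification uses a fixed two-anchor signature rather than a fitted
model comparison; mixed regimes (both sustain and late gating) would need
the full profile. Between-subject variance comes from independent
topography draws and noise only; real subjects additionally differ in
response latencies and amplitudes, which the generator holds fixed. Exact
signed-rank enumeration is quadratic in the rank total and is capped at
n = 15, matching the intended group sizes. The plain-text dataset bundle
trades compactness for transparency; very large simulations should be
regenerated from config + seed rather than stored.
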