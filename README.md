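# tgdecode

Temporal-generalization decoding of overlapping brain responses in rapid
serial visual presentation (RSVP) streams, with a ground-truth forward
simulator for validating every step of the analysis.

## The problem

When images are flashed at ~8.6 Hz (stimulus onset asynchrony 116 ms), the
evoked sensor-level response to each image (≈ 500 ms long) overlaps those of
its neighbours. `tgdecode` separates them with multivariate decoding:
per-timepoint one-vs-rest linear SVMs (C = 1, class-balanced, leakage-free
z-scoring, Platt-calibrated probabilistic output) are trained on
single-stimulus localizer epochs and transferred to the stream, where
per-stimulus re-epoching yields each image's own processing trajectory as a
training-time × testing-time matrix of mean correct-class probabilities
(chance 0.25 for four categories).

The package targets a specific scientific contrast — how temporal attention
selects a cued target from the stream:

* **gradual selection**: a graded, simultaneous amplification of several
  stimuli around the target (the early ~170 ms sensory code stays decodable
  in a late 400–550 ms window for the target *and* its neighbours);
* **discrete selection**: all-or-none gating in which only reported stimuli
  receive a late (~370 ms) processing stage, graded by report order.

Because no public recordings exist for this design, a forward simulator with
known ground truth generates localizer + RSVP datasets (linear superposition
of category- and stage-specific topographies with configurable attentional
gain, plus behavioral guesses), and the pipeline is validated by recovery:
inject a regime, require the analysis to detect it.

## Worked example

```r
library(tgdecode)

cfg <- experiment_config(
  sim   = sim_config(n_sensors = 30, n_localizer_trials = 160,
                     n_rsvp_trials = 96, n_subjects = 15, rng_seed = 11),
  model = selection_model("gradual"),
  seed  = 11)

tr <- run_transfer_stage(cfg, train_times = c(120, 170, 220, 270, 320, 370))

pp <- tr$position_profile
round(matrix(pp$group_mean[pp$anchor %in% c(170, 370)], nrow = 2, byrow = FALSE,
             dimnames = list(c("t170", "t370"), -4:2)), 3)
#>         -4    -3    -2    -1     0     1     2
#> t170 0.253 0.251 0.257 0.279 0.276 0.253 0.254
#> t370 0.247 0.250 0.250 0.252 0.253 0.250 0.250

tr$identification$label
#> [1] "gradual"
```

The first row is the mean 400–550 ms correct-class probability of the
170 ms classifier for stimuli at positions T−4…T+2 relative to the target
(lags 7 and 9 pooled): the target and the two preceding stimuli (0.276,
0.279, 0.257) sit above chance 0.25 with a graded fall-off, while
post-target positions stay at chance — the gradual signature. The second
row shows the 370 ms classifier flat at chance everywhere (nothing is gated
late in this regime). `tr$position_stats` carries the signed-rank tests
with FDR across positions; `identify_selection_model()` labels the run from
the early-vs-late target elevation. Rerunning with
`selection_model("discrete")` flips the signature: the 370 ms row rises at
the target only (0.261 for this seed), graded over Guess 1 > Guess 2 >
Guess 3 in `tr$guess_table`, and unreported stimuli stay within ±0.01 of
chance.

A command-line front end for the same stages ships in
`inst/scripts/tgdecode` (`simulate`, `decode`, `run-all`, with YAML/JSON
configs via `write_config()`).

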