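# gesturekit

Personalized surface-electromyography (sEMG) gesture recognition and
vibrotactile message encoding, at desk scale.

Wearable gesture-communication systems for deaf-blind users — for example
people with progressive Usher syndrome — read muscle activation from a few
forearm sEMG channels, classify the wearer's hand gesture with a small
per-user model, and render messages back as vibration patterns on a
ten-motor arm sleeve. Because sEMG varies strongly between individuals
(muscle geometry, electrode placement, activation timing), a model trained
for one user outperforms a single model shared across users, and the
advantage grows with the number of users a shared model must serve.
`gesturekit` implements that whole pipeline in R, replacing hardware and
human subjects with a controllable synthetic signal generator so the
personalization claims can be studied quantitatively on a laptop.

## What is inside

* **Synthetic sEMG envelopes** — gestures are per-channel activation
  envelopes (trapezoid / gaussian bursts, 0–10 mV); users are *phenotypes*:
  per-channel gains, onset timing jitter, a row-stochastic channel-mixing
  matrix emulating electrode shift and crosstalk, envelope noise and slow
  drift, all scaled by one `variability_level` (0 = identical users).
* **Preprocessing** — per-channel z-score standardization
  `z = (x − μ)/σ` with parameters fitted on training data and persisted
  into the model artifact, and sliding-window segmentation (32 samples,
  50 % overlap at 50 Hz).
* **Classifier** — a lightweight 1D CNN: two Conv1D→ReLU→max-pool blocks,
  then five dense layers whose final width is the user's class count;
  trained with Adam (lr 0.001, mini-batches of 32), cross-entropy loss,
  a stratified validation split, early stopping on validation loss (minimum
  10 epochs) and best-epoch weight restoration. Implemented from scratch on
  base-R matrix algebra and verified against numerical gradients.
* **Registry** — a file-backed, append-only store of per-user, per-life-stage
  profiles, versioned model artifacts (single-file JSON with exact binary
  weight round-trip), training reports, prediction logs and a referential
  integrity audit. Gesture-bank edits mark mismatched artifacts stale.
* **Streaming** — online inference over JSON-lines packet streams with a
  ring buffer, stride-cadence emissions, loss-tolerant parsing and a
  guarantee that streaming output is identical to batch prediction;
  timestamp gaps reset the buffer so no window spans a dropout.
* **Evaluation** — the two personalization experiments: a cohort-size scan
  comparing personalized models against one cross-user model trained on the
  pooled windows of the same users, and a live-protocol reproduction
  (7 subjects × 3 of 10 gestures × 5 repetitions).
* **Haptics** — encode gesture labels or text into spatiotemporal vibration
  patterns for a 10-motor sleeve, with injective, fully configurable symbol
  maps and an exact decoder.

## Worked example

```r
library(gesturekit)

bank <- make_gesture_bank(10, n_channels = 4, seed = 7)   # shared gesture bank
ph   <- sample_phenotypes(1, variability_level = 1, seed = 3)
ds   <- synthesize_dataset(bank[1:3], ph, reps_per_gesture = 5,
                           sim_config(rng_seed = 9))      # 3 gestures x 5 reps
print(ds)
#> <semg_dataset> 15 recordings, 1 users, 3 gestures

scaler <- fit_scaler(ds$recordings)
batch  <- bind_batches(lapply(ds$recordings, function(r)
  segment_windows(apply_scaler(r, scaler), windowing_config())))
print(batch)
#> <window_batch> 120 windows x 4 channels x 32 samples (user U01)

res <- train(batch, scaler, train_cfg = train_config(seed = 2, max_epochs = 15))
print(res$report)
#> <training_report> stopped at epoch 15 (max_epochs); best epoch 15: val loss 0.0001, val accuracy 1.000
```

Each 3-s repetition at 50 Hz yields 150 samples, hence eight 32-sample
windows at stride 16; 3 gestures × 5 repetitions × 8 windows = 120 windows.
The report's accuracy is window-level on the held-out stratified split.

Streaming inference on the packet form of a recording:

```r
pk <- packets_from_recording(ds$recordings[[1]])   # ts_ms steps of 20 ms
em <- stream_infer(pk, res$artifact)
head(em[, 1:2], 3)
#>   ts_ms label
#> 1   620   G01
#> 2   940   G01
#> 3  1260   G01
```

And the personalization experiment itself:

```r
scan <- run_group_size_scan(
  cohort_spec(n_users = 12, variability_level = 1, seeds = 1:5),
  subset_sizes = c(2, 4, 8, 12))
print(scan)
#> <eval_result> scan experiment, 5 seeds
#>  subset_size personalized_accuracy cross_accuracy     gap_pp
#>            2                     1      0.9958333  0.4166667
#>            4                     1      0.8520833 14.7916667
#>            8                     1      0.8364583 16.3541667
#>           12                     1      0.8750000 12.5000000
```

`gap_pp` is the macro-averaged personalized validation accuracy minus the
cross-user model's, in percentage points: personalized models stay at
ceiling while the shared model degrades as it absorbs more users'
conflicting signal renditions (chiefly rotated sleeve montages mapping one
user's gesture onto another's pattern). At `variability_level = 0` the
same scan yields gaps of exactly zero.

A command-line wrapper is installed at `inst/cli/gesturekit`
(`simulate`, `train`, `stream`, `evaluate`, `encode`, `audit`), e.g.

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gesturekit", package="gesturekit"))') \
  encode --message HELLO --out pattern.json
```

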