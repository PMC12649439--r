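---
title: "gesturekit: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gesturekit: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gesturekit)
```

This vignette is the package's own account of its science: what the
synthetic signal generator emulates and what it deliberately does not, how
the classifier and its training loop are defined, which parameters matter,
and where the design was genuinely open and a choice had to be made.

## The problem

A wearable gesture-communication system reads a few channels of surface
electromyography (sEMG) from the forearm, classifies the wearer's hand
gesture, and renders messages back as vibration patterns on an arm sleeve.
The signal form consumed everywhere in this package is the *envelope*: the
rectified, low-pass-filtered sEMG magnitude, sampled at 50 Hz on 4
channels, with amplitudes in the 0–10 mV range typical of envelope-output
sensor front-ends. sEMG is strongly user-specific — muscle geometry,
electrode placement and activation timing differ between people — which is
why the package centres on comparing *personalized* models (one per user)
against a single *cross-user* model trained on pooled data.

## The synthetic generator

No public long-term per-user envelope corpus exists at the scale this
package needs, so training data comes from a generative model with two
layers.

**Gesture templates.** A gesture is, per channel, an activation profile:
onset and duration as fractions of a repetition, a peak amplitude in
(0, 10] mV on a low baseline (0.3 mV), and a shape — a plateau trapezoid
or a gaussian burst. The bank sampler codes gestures *spatially*: each
bank gesture activates a distinct subset of one to three channels at a
common 6 mV peak, because amplitude is unreliable across users
(gain and effort variability) and so is not a coding dimension. Subsets
are drawn as whole orbits of the one-slot montage rotation, which makes
the bank simultaneously channel-balanced (every channel active in an
equal share of gestures) and rotation-closed (a gesture pattern seen
through a rotated sleeve is still a valid bank pattern rather than an
out-of-vocabulary one). A repetition records a *held* gesture over a
3-second recording (150 samples at 50 Hz): activation switches on within
the first tenth of the recording, rises in ~5 % of the active phase (the
settling time of a 3.6 Hz envelope low-pass) and persists until near the
end, so every 32-sample window overlaps genuine activation and window
labels are meaningful everywhere in a repetition.

These template rules protect the zero-variability control. The cross-user
model is scored over the union class space (ten gestures) while each
personalized model chooses among three, so any window that is ambiguous
among bank gestures — a baseline-only tail window, a slow-onset ramp
window, or two near-identical templates — handicaps the pooled model
*even with identical users*, and the null comparison would no longer
isolate inter-user variability.

**User phenotypes.** Inter-user variability is parametric and scaled by a
single `variability_level` $v$ — and, deliberately, $v$ moves only
*between-user* dispersion:

* per-channel amplitude gains, log-normal with sd $0.5v$;
* a systematic per-user onset shift, $\mathcal N(0, (0.12v)^2)$ s, applied
  to every repetition of that user;
* channel mixing = montage rotation × crosstalk blur: with probability
  $\min(0.5v, 0.8)$ the user wears the sleeve rotated by one slot (every
  electrode over the neighbouring muscle — the classic wearable placement
  failure), and mild leakage $\ell_c \sim U(0.02v, 0.1v)$ blurs each
  channel toward its neighbour.

Within-user properties are constants shared by everyone: a 0.02 s
repetition-to-repetition onset wobble, a log-normal effort factor
(sd 0.18–0.2) scaling each repetition's activation — a muscle never
contracts with identical strength twice — and the sensor-electronics
noise floor (0.3 mV Gaussian) and slow drift (0.1 mV at 0.25 Hz). Keeping
those common is essential: per-user noise or drift magnitudes would hand
a pooled classifier a trivial fingerprint (within-window variance) with
which to identify users and dodge genuine gesture conflicts.

At $v = 0$ every user receives unit gains, identity mixing and zero
systematic shift — phenotypes are identical by contract, the null
condition the evaluation experiments rely on.

Why rotation is the load-bearing distortion: per-channel z-scoring removes
any affine per-channel distortion, so gain differences largely vanish
after standardization, and sub-noise crosstalk blur is invisible. A
rotated montage, however, maps one user's gesture pattern onto the *bank
pattern of a different gesture* (the bank is rotation-closed), so pooled
training faces windows that are genuinely identically distributed under
two different labels — an irreducible conflict that no amount of model
capacity resolves, exactly the mechanism by which shared cross-user
models degrade in practice. A personalized model is untouched: its own
three patterns remain distinct under any fixed montage.

A repetition is rendered template (onsets moved by the user's systematic
shift plus that repetition's wobble) → effort scaling → gains → mixing →
drift + Gaussian noise → clipped at zero (an
envelope is a rectified magnitude, so samples are non-negative). Every
(user, gesture, repetition) triple draws from its own substream derived
from one top-level seed (`derive_seed()`), making all generation a pure
function of (bank, phenotypes, config, seed).

**What the simulator does not emulate.** Motor-unit biophysics, the
specific FDS/ED/FPL muscles, raw-signal spectral realism, electrode–skin
impedance changes, fatigue, and within-session non-stationarity. Passing
tests therefore show that the *pipeline and the personalization logic*
behave correctly under controlled, realistic-scale variability — not that
the classifier would reach the same accuracy on recorded human data. A
raw-signal mode exists for preprocessing tests only:
`envelope_from_raw()` rectifies, smooths with a first-order low-pass
(cutoff 3.6 Hz, the analog envelope stage of typical sensor front-ends) and
decimates to 50 Hz. The 20–500 Hz bandpass of the acquisition hardware is a
hardware property; at a 50 Hz envelope rate it would sit above Nyquist and
is deliberately not a software stage.

## Preprocessing

Standardization is per channel, $z = (x - \mu)/\sigma$, with the
*population* (1/n) standard deviation — the convention of the widely used
feature scalers, chosen for train/deployment consistency over
unbiasedness. Parameters are fitted on training recordings only, persisted
inside the model artifact, and reused verbatim at inference; transforming
held-out data never refits them. Channels with zero spread are flagged and
guarded with an epsilon so they map to zero rather than dividing by zero.

Windowing takes 32-sample windows at 50 % overlap (stride 16, i.e. 640 ms
windows emitted every 320 ms at 50 Hz). Incomplete tails are dropped, never
padded: the model input shape is fixed. Window labels broadcast the
recording's label; when per-sample labels exist, a majority rule applies
with ties broken by the centre sample. Standardization is applied to the
continuous recording before segmentation; for a linear per-channel map the
order is algebraically irrelevant, but fixing it keeps artifacts
deterministic.

## The classifier and its training

The network is intentionally small: two 1D convolution blocks
(32 filters then 64, kernel 3, ReLU, max-pool 2) followed by five dense
layers 256→128→64→32→$K$, ReLU between and none after the last, where $K$
is the user's class count — the only shape that changes with the gesture
bank. With 4 channels and 32-sample windows this is ≈ 140k parameters and a
≈ 1.6 MB serialized artifact. Convolutions run as im2col matrix products;
the backward pass is hand-derived and checked against numerical
differentiation in the test suite.

Training minimizes multi-class cross-entropy with Adam at learning rate
0.001 in mini-batches of 32. A stratified 80/20 validation split (at least
one window per class held out) is fixed for the whole run. Early stopping:
training stops at the first epoch $e \ge$ `min_epochs` (10) at which
validation loss has not strictly improved for `early_stop_patience` (5)
consecutive epochs, else at `max_epochs`; the artifact carries the weights
of the best-validation-loss epoch, so its stored metrics match what it will
do in deployment. Argmax ties break to the lowest class index for
determinism. `train_config()` defaults `max_epochs` to 200; the evaluation
drivers cap it at 30 because validation loss plateaus long before that at
these data sizes, and holding the epoch budget identical across arms is
part of the experimental design.

Reported accuracy is window-level on the validation split.
Repetition-level decisions (majority over a repetition's windows,
`majority_label()`) are exposed separately and are generally at least as
good; window-level is the stricter, and therefore the primary, metric.

## The evaluation experiments

Two experiments, both on synthetic cohorts drawing 3 gestures per user from
a shared 10-gesture bank, 5 repetitions per gesture (the live-protocol data
budget), replicated over 5 seeds:

* **Group-size scan** — for each cohort size $U$: $U$ personalized models
  vs one cross-user model trained on the pooled windows of the same $U$
  users, classes being the union of their gesture sets. Reported: macro
  mean personalized validation accuracy, cross-user validation accuracy on
  the pooled split, and their gap in percentage points.
* **Live protocol** — 7 subjects, per-subject personalized and cross-user
  accuracy and loss.

Fairness rules, enforced structurally:

* Both arms consume *byte-identical* per-user window batches, windowed
  once per repetition so no window straddles two repetitions.
* Each user's scaler is fitted on a *calibration session* — one pass over
  the full gesture bank, the standard sEMG onboarding step — rather than
  on their assigned training gestures. This keeps the standardization
  statistics independent of which three gestures a user trains: a scaler
  fitted on the training subset would encode the user's class assignment
  in the absolute signal levels, and a pooled model could exploit that
  fingerprint instead of reading muscle activation patterns.
* One stratified train/validation partition is drawn per user and shared
  by both arms, holding out whole repetitions (window-level splits of
  overlapping windows leak near-duplicates of training data into
  validation and pin both arms to a memorization ceiling). The cross-user
  model trains on exactly the union of the users' training windows, both
  arms are scored on identical validation windows (a paired comparison),
  and no arm ever trains on any window of a validation repetition.
* Architecture, training configuration and training seed are identical
  across arms.

Consequently at $U = 1$ the two arms train literally the same model on
the same partition and the gap is exactly zero — a useful built-in
control. With equal window counts per user, the cross-user model's
pooled validation accuracy equals the mean of its per-user accuracies,
so macro- and window-weighted averaging coincide.

Open points the experiments had to decide: personalized accuracies are
macro-averaged over users (not window-weighted); the cross-user model is
scored against the full union class space (a shared model in deployment
cannot know whose windows it is seeing); its per-subject accuracy is
computed on that subject's rows of the pooled validation split. The
published headline number for the 36-user public-dataset comparison depends
on that external dataset and is out of scope here; the synthetic
experiments reproduce the *qualitative* claims — a positive gap at every
cohort size, non-decreasing with size, and no subject for whom the shared
model beats the personalized one.

## Registry, streaming, haptics

The registry is a directory tree: one directory per (user, life stage) with
append-only profile revisions, versioned single-file artifacts, training
reports and a JSON-lines prediction log. Nothing is deleted or rewritten;
gesture-bank edits append a revision and mark mismatched artifacts with a
`.stale` sidecar so they can never be silently served. `audit_registry()`
re-checks referential integrity of the whole store from disk.

Streaming inference maintains a per-segment buffer of the last 32
standardized samples and emits at stride cadence, which makes the $k$-th
emission equal — `identical()`, not merely close — to batch prediction on
the $k$-th sliding window. A timestamp jump greater than twice the nominal
20 ms sample period is a stream gap: the buffer resets, so no window ever
mixes pre- and post-gap samples. (Exactness requires evaluating the
reference one window at a time; pooled BLAS forward passes may reassociate
floating-point sums across batch shapes.) Latency instrumentation is
observational only and never changes emissions.

The haptic coder maps symbols to spatiotemporal patterns on a 10-motor
sleeve. The default letter map codes position (motor index) and pulse count
(group of ten) in a 300 ms slot with 100 ms inter-symbol gaps; gesture maps
use single bursts coded by motor × duration level (capacity 30). All maps
are injective by construction and fully replaceable via JSON. `haptic_decode()`
is the exact inverse of `haptic_encode()` — the electronic receiver is a
round-trip check; the intended receiver is, of course, a human arm.

## Numerical choices and degenerate inputs

* Envelope samples are clipped at zero; scaler epsilon 1e-8 mV guards
  constant channels.
* Recordings shorter than one window yield an empty batch, not an error;
  repetition length is `round(duration × rate)`.
* Max-pool ties keep the first element; argmax ties keep the lowest class
  index; majority-label ties fall back to the centre sample, then
  alphabetical order.
* Out-of-order or malformed packets are dropped and counted (datagram
  semantics), with a warning past 50 % loss; corrupted lines can never
  crash the reader.
* Artifact weights serialize as base64 little-endian IEEE doubles: exact
  round-trip, schema-versioned, portable across machines.
* All test and acceptance problem sizes (cohorts up to 12 users, 5 seeds,
  3 s repetitions giving 24 validation windows per user) were chosen as
  the smallest scales at which the personalization effect is measured
  stably — with many fewer validation windows per user, a single window
  flips an accuracy by several percentage points and the per-subject
  comparisons become coin flips; they run on one CPU in minutes.

## Known limitations

The phenotype model is phenomenological — its dispersions are calibrated to
be *plausible*, not fitted to any measured population; absolute accuracies
and gap magnitudes therefore characterize the simulator, not human cohorts.
Envelope-level simulation cannot probe raw-signal preprocessing choices.
The registry's file-per-artifact design targets desk scale, not concurrent
multi-writer servers. Training is single-threaded CPU; at these model sizes
that is a feature, not a bottleneck.
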