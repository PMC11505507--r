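---
title: "Methods: real-time freezing-of-gait detection and cueing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time freezing-of-gait detection and cueing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogcue)
```

## The problem

Freezing of gait (FoG) is an episodic inability to initiate or continue
walking that affects most people with advanced Parkinson's disease. External
rhythmic cues — here, vibratory stimulation — help patients resume walking,
but cueing is most effective when delivered *on demand*, which requires
detecting an episode within a fraction of a second on a body-worn device.

`fogcue` re-implements such a closed-loop system at desk scale: a 40 Hz,
20-channel gait stream is classified sample by sample by a compact
convolutional + recurrent network, a threshold turns scores into detections,
and a countdown state machine converts detections into cue commands that
persist for three seconds beyond the last detection. Because the patient
recordings behind the original system are not public, the package ships a
synthetic gait generator that reproduces their statistical shape, so every
stage is testable end to end.

## Past-samples windowing

The classifier input for sample $t$ is the flat vector

$$v = [u_{1,t},\dots,u_{20,t},\; u_{1,t-1},\dots,u_{20,t-1},\;\dots,\;u_{20,t-PS}],$$

the current sample's 20 channels followed by the previous $PS$ samples,
length $20(PS+1)$ — 800 features at the deployed default $PS=39$ (one second
of context). $PS$ is a per-patient hyperparameter; `tune_past_samples()`
scans the deployment grid $\{15, 30, 40, 60, 100\}$ and breaks F1 ties
toward the smaller, cheaper window.

Offline training uses `batch_windows()`; online inference maintains a
rolling buffer (`push_sample()`) that shifts one slot per sample. The two
must agree exactly — a model trained offline runs online — and in this
implementation they do bitwise, because both paths are pure memory
rearrangements of the same float32 values and prediction uses one sequential
scalar code path regardless of batch size. The property suite asserts this
identity on generated recordings.

**Warm-up.** No window is emitted until the buffer holds $PS+1$ samples; at
40 Hz that is at most 2.5 s even at $PS=100$. Padding with fabricated
history was rejected as it would feed the classifier data that never
occurred.

## The classifier

`build_fog_model()` constructs, and `fog_train()` trains, the network:

1. **Normalization layer.** Feature-wise standardization with per-feature
   moments frozen from the training windows at fit start and a learned scale
   (`gamma`) and offset (`beta`) pair trained by gradient. Inference always
   uses the frozen moments, so streaming needs no running statistics and the
   offline/online identity is preserved. This replaces dataset-wide static
   z-scoring (`normalize_static()`, retained for experiments), which becomes
   stale as data accumulate.
2. **Reshape** of the 800-vector to 20 channels x 40 time steps (oldest step
   first).
3. **1-D convolution along time**: 32 filters, kernel 5, same-length
   padding, ReLU. The flattened feature count is $32 \times 40 = 1280$.
4. **Sequence view** of the 1280 features as 40 steps x 32 features. A
   literal length-1280 scalar sequence would make the recurrent layers
   process 1280 steps per sample — implausible at 40 Hz on a
   microcontroller — so the flatten is treated as a formal counting step.
5. **Two simple tanh recurrent layers** (64 then 32 units); the second
   layer's final hidden state feeds
6. **a single sigmoid output neuron** — FoG is a binary, not multi-activity,
   problem.

The exact convolutional and recurrent widths of the original embedded model
are not published; the sizes above are the minimal configuration consistent
with every printed shape (800 in, 20 x 40 reshape, 1280 flattened, two
recurrent layers, one output).

**Single precision.** The embedded target stores everything as 32-bit
floats. All parameters are float32-representable, and both the forward pass
and the BPTT trainer (implemented in C++) compute in `float` throughout.

**Training.** Weighted binary cross-entropy (inverse-frequency class
weights by default, since FoG is typically 1.5–15% of samples), Adam at
learning rate $10^{-3}$, batch 128, 6 epochs, backpropagation through time
across all 40 steps. The split is chronological 60% train / 40% test —
shuffled splits would leak temporally adjacent, near-duplicate windows
across the boundary. Optimizer settings are exposed in `fog_train_config()`
because the original training hyperparameters are unpublished. Training is
deterministic given the seed (single-threaded, fixed shuffle stream).

## Streaming detection and cueing

`run_stream()` emulates the 25 ms loop. The threshold function is strict —
a score must *exceed* the threshold (default 0.9; per-patient values of
0.2–0.4 were used clinically) — making boundary behaviour testable. The
`FoG_condition` countdown is set to 3 on detection and loses one unit per
second of silence, its timer restarting at each detection, so an isolated
detection cues for exactly 120 samples (3 s) and continued detections
extend the cue. The decrement clock is locked to the last detection rather
than to absolute sample count, matching the stated "3 s from the last
detected FoG sample". Cue on/off commands are logged (the stand-in for the
RF message to the vibration actuators); intensity is metadata only.

## Evaluation

Sample-level metrics (`fog_metrics()`) report accuracy, precision,
sensitivity, specificity and F1; zero-denominator metrics are reported as 0
with a `degenerate` flag rather than dropped, so heavily imbalanced runs
still produce full rows. Event-level evaluation (`event_report()`) counts an
episode as detected if any thresholded detection falls inside it, measures
delay from episode onset to the first detection within it (x 25 ms per
sample at 40 Hz), and counts false-positive *events* as maximal detection
runs overlapping no labeled episode — discrete occurrences, the way
clinicians count spurious cues. Delay is measured on thresholded detections,
not raw scores, since cueing is what the patient experiences.
`ablation_harness()` retrains on channel subsets (CF / ACC / GYRO / MA) to
rank sensor groups.

## Stimulation-effect statistics

`two_proportion_test()` compares FoG sample rates without ($r_1$) and with
($r_2$) stimulation using the unpooled standard error

$$SE = \sqrt{\frac{r_1(1-r_1)}{n_1} + \frac{r_2(1-r_2)}{n_2}}, \qquad
  z = \frac{r_2 - r_1}{SE},$$

two-sided $p = 2\Phi(-|z|)$, and percent reduction $(r_1-r_2)/r_1 \times
100$. The sign convention makes a reduction negative, matching how the
result tables are printed. Sidedness is not stated in the source material;
two-sided is the conservative choice and matches the printed p-value
magnitudes. `exact_binomial_check()` cross-validates the normal
approximation by Monte-Carlo simulation under the pooled null.

## The synthetic generator

`generate_recording()` emulates the recording protocol: interleaved walking,
standing and turning with a configured number of FoG episodes. Defaults
(300 s, 10 episodes, 5.9% prevalence) mirror the cohort averages; the
generator reproduces the cohort's extremes (1.5–15.4% prevalence, 4–86
episodes, 9.5k–99k samples) by configuration. Episode durations are drawn
uniformly and rescaled so that the episode count wins when count and
prevalence conflict.

Signal models: walking is a 1 Hz gait fundamental (the cueing rhythm
approximates walking cadence) plus two harmonics with person-specific
amplitudes and phases on accelerometer/gyroscope channels and a small sway
on angle channels; standing is noise; turning adds a slow 0.1–0.3 Hz drift
on gyroscope/angle channels; FoG suppresses the locomotor band (x 0.15) and
adds a low-amplitude 3.5–7.5 Hz tremor on accelerometer/gyroscope channels
with elevated muscle-activity variance — the classic trembling-in-place
surrogate. The 20 channels are 6 accelerometer + 6 gyroscope + 4
complementary-filter angle + 4 muscle-activity, matching the four sensor
groups of the ablation study.

**What passing tests do and do not show.** The surrogate FoG signature is
documented and spectrally detectable by construction; no raw-signal
characterization of real FoG episodes was available to imitate. Detection
results on synthetic data therefore validate the *pipeline* — windowing,
training, thresholding, cue timing, event metrics — not clinical
performance. Real FoG is far more heterogeneous; the original system's
per-patient detection counts are not reproducible at desk scale and are not
claimed.

## Numerical choices and degenerate inputs

* Normalization variance floor $10^{-8}$ and epsilon $10^{-5}$ inside the
  layer; constant channels cannot divide by zero.
* Threshold comparisons are strict (`>`); score exactly at threshold does
  not trigger.
* `tune_past_samples()` breaks ties toward smaller PS.
* Single-class training splits raise an error advising resimulation rather
  than silently fitting a constant.
* Scores during warm-up are defined as 0 (never detected).
* Model files store a JSON header plus raw little-endian float32 arrays;
  loads validate magic, version and (optionally) the expected PS, and a
  truncated file fails without producing a partial model.

## Problem sizes

The bundled tests train on short recordings (60 s, PS = 9) for speed; the
end-to-end recovery checks and the acceptance script use 500 s recordings
(20,000 samples, 12 FoG episodes, 8% prevalence) with PS = 39, 6 epochs —
about half a minute of training per model on one core. Those sizes were
chosen as the smallest at which event-level behaviour (multiple held-out
episodes, realistic imbalance) is meaningful.

## Known limitations

* The muscle-activity channels are a variance model only; no physiological
  EMG realism (and none is needed for the pipeline's logic).
* The recurrent cell type of the original network (simple/GRU/LSTM) is
  unpublished; simple tanh cells are used.
* Real-time pacing is simulated by sample index (25 ms/sample); no
  wall-clock scheduling, RF transmission or actuator control.
* Sample-level precision/sensitivity on real recordings are not reproduced;
  with the published imbalance they are dominated by labeling conventions
  that are not recoverable from the source material.
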