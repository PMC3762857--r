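---
title: "Gait-phase detection with a left-right HMM: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase detection with a left-right HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem and the model

A single foot-mounted gyroscope measuring sagittal-plane angular velocity
carries enough information to segment gait into its four canonical
phases — stance (ST), heel off (HO), swing (SW), heel strike (HS) — once a
statistical model has been adapted to the wearer. The appeal is clinical:
foot-switch (FSR) instrumentation is accurate but impractical for daily
wear, whereas a gyroscope is cheap, small and robust. The workflow here
instruments a subject with three FSRs (heel, first and fifth metatarsal
heads) for **one** training trial; everything afterwards runs on the
gyroscope alone.

The detector is a hidden Markov model with the four phases as states.
Three structural commitments define it:

1. **Cyclic left-right transitions.** Gait phases occur in a fixed order,
   so `A[i, j] = 0` unless `j = i` or `j = (i+1) mod 4`. This encodes the
   physiology, halves the parameter count, and guarantees that the
   offline decoder can never produce an out-of-order phase path.
2. **Uniform initial distribution.** A trial may begin in any phase;
   `pi = (1/4, 1/4, 1/4, 1/4)` is fixed and never re-estimated.
3. **Scalar Gaussian emissions.** Each state emits the filtered angular
   velocity with its own mean and standard deviation. No published
   observation model exists for this exact setup; a supervised-trainable
   Gaussian is the minimal family consistent with a one-dimensional
   input, and its misfit (within-phase velocity is far from stationary —
   swing sweeps from 0 up to the swing peak and back) is absorbed into
   large per-state variances. This misfit, not the decoder, is the main
   accuracy limiter; see "Known limitations".

Training is supervised count/moment estimation — deliberately **not**
Baum–Welch. The FSR labels are trusted; iterative re-estimation could
drift the states away from their physiological meaning, and one labelled
trial at 200 Hz (≈12 000 samples) estimates 4 self-transition
probabilities and 8 emission moments with ample precision.

## Processing constants

| parameter | default | why |
|---|---|---|
| processing grid | 200 Hz (5 ms) | the FSR acquisition rate; gyro (50 Hz) is linearly interpolated up to it |
| low-pass filter | Butterworth, 15 Hz cutoff | standard for foot kinematics; removes sensor noise while keeping the swing lobe intact |
| filter order | 4 | not prescribed by the method's description; 4 is the common biomechanics choice and gives −36 dB one octave above cutoff |
| filter phase | zero-phase (forward–backward) for training/offline; single causal pass for streaming | a zero-phase pass has no group delay, so offline labels align with the FSR reference; a real-time system can only run causally |
| emission `std_floor` | 0.5 deg/s | a state trained on near-constant samples would otherwise get a degenerate σ≈0 and a spiked likelihood |
| `transition_floor` | 1e-6 | a permitted transition never observed in training (possible in a short trial) must stay reachable |
| concurrence window | 60 ms | at typical cadence at most one true transition can fall inside it: 6 % of a one-second step |
| significance α | 0.05 | conventional |

Numerical notes: Viterbi runs entirely in log space; the forward
recursion renormalizes the posterior at every step (equivalent to the
standard scaling), so 60 s trials cannot underflow. All argmax
tie-breaks choose the lowest state code, making every decode
deterministic and platform-independent. The Butterworth design
(bilinear transform with prewarping) and the zero-phase pass
(odd-reflection padding of 3× the order, steady-state initial
conditions) were verified to machine precision against an independent
DSP implementation; no DSP library is a runtime dependency.

## The FSR reference

Voltages become contacts by strict thresholding (`v > threshold`)
followed by debouncing: any pressed/unpressed run shorter than 20 ms is
merged into its neighbours, shortest first, earliest on ties. 20 ms is
far below any plausible phase duration but above FSR contact chatter.

The default threshold is the midpoint of the 5th and 95th percentile of
the observed voltages — subject-adaptive, as the original protocol's
manually verified per-subject thresholds were. One refinement proved
necessary: the midpoint is computed from the three channels **pooled**,
not per channel. A channel that never fires during a trial (e.g. the
fifth metatarsal of a walker whose contact pattern never engages it) has
a percentile spread consisting entirely of sensor noise, and a
per-channel midpoint would binarize that noise; the pooled spread always
brackets the foot's true pressed/unpressed levels. Explicit thresholds
can override the default.

The four contact rules are total over all 8 contact combinations (the
all-pressed combination falls under ST's "heel and either metatarsal"
rule). Cycles start at each SW→HS transition — heel strike conventionally
opens the gait cycle — and a trailing partial cycle is excluded from
per-cycle statistics.

## The tolerance-windowed metric

The published evaluation defines the 60 ms window but not the tally. The
rule adopted: one-vs-rest per phase `p`, per sample `i`, with half-window
`h = round(window · rate / 2)` (6 samples at 200 Hz):

* `test[i] = p`: **TP** if the reference carries `p` within `i ± h`,
  else **FP**;
* `test[i] ≠ p`: **FN** if `ref[i] = p` and the test carries `p` nowhere
  in `i ± h`, else **TN**.

Sensitivity and specificity are micro-averages (sum counts over phases,
then one ratio), matching one-number-per-trial reporting. This
definition was chosen because it (a) forgives pure transition-timing
error up to the window, the metric's stated purpose, (b) still punishes
phase-identity errors, and (c) collapses exactly to the per-sample
confusion matrix at window 0 — which the tests exploit by checking
against a naive double-loop oracle. Both metrics are provably
non-decreasing in the window size. When neither sequence shows stride
activity (no SW→HS onset **and** no SW sample — the second clause covers
degenerate decodes that enter swing without completing a stride),
sensitivity is defined as 1 rather than 0/0, the convention for
non-walking trials.

`spearman_t` implements the rank correlation with the t conversion
`t = R·sqrt((N−2)/(1−R²))` on `N−2` degrees of freedom. Note a
documented discrepancy in the source material for this statistic: the
critical |R| quoted there for N = 10 (0.58) does not follow from this
formula at α = 0.05, which gives ≈0.632; this implementation follows the
formula.

## What the simulator emulates — and what it does not

`generate_walking` builds truth first (concatenated cycles; log-normal
duration jitter; per-cycle phase splits by largest-remainder rounding)
and sensors second: the gyro is a per-cycle template of raised-cosine
lobes — flat stance, push-off lobe at −0.6× the swing peak spanning HO, a
dominant +1.0× lobe peaking mid-swing, a −0.25× heel-strike lobe —
sampled at 50 Hz with additive Gaussian noise, while FSR voltages follow
the canonical contact pattern of each phase (ST = heel+m1, HO = m1,
SW = none, HS = heel) with level noise. Toe-walking severity `s` moves
stance mass into heel-off (`ST' = ST(1−s)`, `HO' = HO + ST·s`), the
signature of hemiplegic toe walking. Non-walking tasks are stance-only
truths (plus toe-standing bouts under severity) with low-amplitude sway
or slow-turn gyro activity; the clockwise/counter-clockwise pair are
exact sign mirrors.

Defaults state the simulated world once: stride cadence 0.5 /s (slow
treadmill walking of children at 1.0 km/h), typical fractions
(0.30, 0.30, 0.35, 0.05), swing peak 150 deg/s, gyro noise 5 deg/s, FSR
levels 1 V/0 V with 0.02 V noise, cycle-duration CV 3 % (TD) / 8 % (HC),
HC severity uniform on [0.2, 0.8] with slower cadence and lower peak.
Speed/incline task variants map onto cadence and peak multipliers only.
These were chosen as field-plausible values, not fitted to any figure,
and were not revisited after the benchmarks were first run.

With zero contact noise the reference pipeline reproduces the simulated
truth *exactly*, for every task and severity — this generator-labeller
consistency is an acceptance criterion, and it is what licenses using
the FSR pipeline as ground truth in the other benchmarks.

What the simulator does **not** model: inter-cycle waveform variability
beyond duration jitter, double-support asymmetries, FSR dropouts,
gyroscope drift or axis misalignment, and any subject-specific waveform
idiosyncrasy. A green benchmark therefore establishes that the
implementation is correct and that the method behaves as published *on
its idealized signal class* — it does not re-validate the method on
human data.

## Design choices where the design was open

* **Transition training.** The description of training is ambiguous
  between count MLE on the labelled series and setting self-transitions
  from mean phase durations (`a_ii = 1 − 1/(d_i f_s)`). Both are
  implemented (`transitions = "counts"` / `"duration"`); counts is the
  default. For geometric dwell times the two estimates agree to first
  order, and count MLE uses strictly more information.
* **A_RT output constraint.** The forward argmax is *not* forced to
  respect the left-right order (the offline decoder is, by
  construction). Whether the original real-time variant enforced it is
  unstated; forcing it would silently repair decoder pathologies, so the
  package monitors instead: `forward_decode` counts order violations in
  a `support_violations` attribute.
* **A_RT front-end filter.** `cmd_detect(mode = "realtime")` is a strict
  streaming loop — causal filter state and one forward update per sample,
  no lookahead anywhere, so the causality property is testable. The
  cohort *benchmark*, however, feeds both decoders the same zero-phase
  filtered signal: the published evaluation treated the gyro once,
  offline, and scored the two decoding algorithms against each other on
  that common signal. Scoring the causal chain against the zero-phase
  chain would additionally charge A_RT the filter's ~25 ms group delay —
  a property of the filter, not of the decoding algorithm under test.
* **Debounce order.** Shortest-run-first (ties earliest) makes the
  debounce deterministic and removes spikes before they can split a
  long run; a single left-to-right sweep would depend on scan direction.

## Known limitations

* The forward (real-time) decoder lags phase onsets by design: the
  filtered posterior can only move after evidence arrives, and with
  self-transitions near 1 the prior resists switching. For the brief HS
  phase (≈5 % of the cycle) of severe toe-walkers this lag exceeds the
  ±30 ms half-window, and the walking-task agreement floor between A_RT
  and A_OL lands near 0.92 for the simulated hemiplegic group (the
  typically-developing group clears 0.95). The corresponding acceptance
  check is intentionally left failing rather than relaxed; the effect is
  a real property of per-sample argmax decoding on this signal class.
* Scalar Gaussian emissions cannot represent within-phase velocity
  trajectories; near phase boundaries the likelihoods of adjacent states
  overlap, which both decoders resolve only statistically. The offline
  decoder consequently over-segments (spurious short SW→HS excursions
  during swing) on noisy trials — visible as inflated stride counts —
  without much cost to the per-sample windowed metrics.
* Left and right feet are processed independently; no bilateral
  coordination model.
* The simulator's idealizations listed above bound what any green test
  here can claim about human recordings.
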