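---
title: "Methods: regression-based 2-DoF proportional myoelectric control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression-based 2-DoF proportional myoelectric control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoprop)
```

## The control problem

A trans-radial myoelectric prosthesis offers two degrees of freedom (DoF):
gripper open-close and wrist pronation-supination. Conventional two-site
control drives one DoF at a time from an extensor and a flexor electrode,
switching DoFs by a deliberate co-contraction. Regression-based control
instead estimates both DoF efforts simultaneously and proportionally from a
ring of surface-EMG electrodes, so the user can open the hand while rotating
the wrist in a single motion.

`myoprop` implements both families at desk scale: the full signal chain from
raw EMG to velocity commands, a virtual prosthesis to integrate them, and a
synthetic EMG generator that stands in for subjects and hardware so every
stage can be exercised and tested deterministically.

## EMG amplitude estimation (EMG$\sigma$)

Raw EMG is sampled at 2000 Hz. The amplitude feature driving all control —
EMG$\sigma$, an estimate of the signal's standard deviation, a.k.a.
processed EMG — is produced by a causal five-stage cascade per channel:

1. **Notch**, 60 Hz, second-order IIR biquad with an exact unit-circle zero
   and 1 Hz bandwidth, removing power-line interference.
2. **Highpass**, 15 Hz fifth-order Butterworth, attenuating motion artifact.
3. **Full-wave rectification** (absolute value).
4. **Lowpass**, 16 Hz ninth-order Chebyshev Type I with 0.05 dB peak-to-peak
   passband ripple, demodulating the rectified signal.
5. **Decimation** to 100 Hz (every 20th sample; the 16 Hz lowpass already
   bounds content far below the 50 Hz output Nyquist, so no extra
   anti-alias stage is inserted), followed by a **1 Hz second-order
   critically damped smoother** at the output rate.

Two conventions are under-determined by the usual way these cascades are
quoted, and are fixed here as explicit design choices:

* the notch bandwidth is interpreted as the −3 dB bandwidth (the standard
  IIR notch parameterization);
* the critically damped smoother is realized as two identical first-order
  sections sharing one real pole (no overshoot), with the pole placed by
  bisection so that the *cascade* is −3 dB at the configured cutoff.

### Numerical realization

High-order narrowband IIR filters are numerically fragile in expanded
transfer-function form: the ninth-order Chebyshev at $f_c/f_s = 0.008$ has
all nine poles within $10^{-2}$ of the unit circle, and expanding them into
a single polynomial moves a pole outside it (radius 1.002 in double
precision). All recursive stages are therefore designed in zero-pole-gain
form — closed-form Butterworth and Chebyshev Type I analog prototypes,
bilinear transform — and realized as cascades of first/second-order
sections. Stability (every pole strictly inside the unit circle) is
asserted at design time, and the test suite verifies each stage's impulse
response decays below $10^{-12}$ within 60 s.

Batch ([`process_batch()`]) and streaming ([`process_step()`]) paths share
one per-sample transposed direct-form II kernel, so sample-by-sample
processing is *bit-identical* to batch processing — the property a 100 Hz
real-time loop needs from its offline calibration. Filters start from
all-zero state (cold start); the calibration trimming below absorbs the
startup transient. Because rectification can interact with the Chebyshev
and smoother ringing, small negative undershoots are clamped to zero:
EMG$\sigma$ is an amplitude.

## Calibration of the EMG$\sigma$–force model

Calibration uses a 90 s schedule of nine contiguous 10 s constant-posture,
constant-force contractions: rest, then four 1-DoF and four 2-DoF
contractions at a nominal 30 %MVC target effort. (MVC is never measured —
30 % is an instructed target, which is why the synthetic generator jitters
the held effort.) Two label sets are supported: the direct strategy
(`Cls, Opn, Sup, Pro, …`) and the mapped strategy (`Flx, Ext, Uln, Rad, …`,
where extension opens the hand and radial deviation pronates the wrist).

From the 100 Hz EMG$\sigma$ series the design is assembled as:

* the first and last 1 s of every segment dropped (filter and movement
  transients);
* the single rest block replicated 8× (balancing rest against the eight
  active contractions without lengthening the recording);
* targets $y \in \{0, \pm 30\}$ %MVC per DoF, with zero assigned to the
  unused DoF of every contraction.

With defaults each active segment contributes 800 rows and rest 6400, i.e.
a $12800 \times 17$ design for 16 channels plus bias. The constant bias
column absorbs the EMG$\sigma$ noise floor; it can be disabled
(`fit_spec(bias = FALSE)`). Whether the original workflow used an intercept
is not documented; including it is this package's choice and it is never a
candidate for elimination during channel selection.

The two-output linear map is fit by the **truncated-SVD pseudo-inverse**:
singular values with $s_i / s_{\max} <$ `tol` (default 0.01) are removed
and the minimum-norm solution is taken over the retained directions. This
is the regularization that keeps the fit usable when neighboring
circumferential electrodes record nearly collinear amplitudes. The
retention rule is strict-less removal: $s_i/s_{\max} \ge$ `tol` is kept.

**Calibration quality** is reported as RMSE between target and estimated
force, pooling squared errors over both DoF outputs (both DoFs contribute
even for 1-DoF contractions). Per-type RMSE counts each unique rest frame
once; the overall RMSE pools all design rows as fitted (replicas included)
and is exactly recomputable from the residuals.

## Backward stepwise electrode selection

`backward_select(model, k)` greedily eliminates channels: at each step the
model is refit with each single remaining channel removed and the channel
whose removal yields the lowest overall training RMSE is dropped, until `k`
remain. Ties are broken by dropping the lowest channel index, so runs are
reproducible. Selection optimizes training RMSE on the same assembled
design (no hold-out), matching a single-recording calibration workflow.

One property worth stating precisely: for *unregularized* least squares,
training RMSE cannot decrease when a regressor is removed, so the greedy
path is non-decreasing as `k` shrinks — and the test suite asserts exactly
that on a well-conditioned design. Under truncation the statement is no
longer a theorem: removing a channel reshapes the singular spectrum and can
move directions across the `tol` boundary, so the regularized training RMSE
can dip slightly along the path (fractions of a percent in our synthetic
sessions). This is expected behavior of the regularizer, not a defect of
the greedy loop, whose per-step argmin is verified against exhaustive
single-removal search.

## Runtime thresholding, gating, and velocity mapping

At run time the predicted force passes three stages, in this order:

1. **Resting thresholds** — four independent dead zones, one per DoF
   direction (open, close, pro, sup), default 10 %MVC: a component whose
   magnitude is below its direction's threshold becomes exactly zero.
2. **Fixed-ratio co-activation gate** — in the hand-wrist force plane, if
   the force vector lies within $\alpha$ (default 25°) of the dominant
   axis, only the dominant DoF is actuated; the smaller component is
   zeroed. Exact diagonals pass both. The geometric (angle) formulation is
   the default because the alternative literal reading — "suppress when the
   larger-to-smaller *ratio* is below a threshold" — is inverted relative
   to the angle picture (a large ratio means nearly on-axis). Both are
   implemented (`gate_rule = "angle"` / `"ratio"`); no claim is made about
   which was intended originally.
3. **Velocity map** — per DoF, linear from the direction's resting
   threshold up to 50 %MVC, clamped beyond. The hand maps onto the
   gripper's 8–200 mm/s proportional speed range (a just-supra-threshold
   effort produces the hardware's minimum speed, not zero); the wrist maps
   from zero up to 28 rpm = 168 °/s. Axis inversion flags are applied last.

Threshold-then-gate conditioning is idempotent, so the pipeline composes
safely with itself.

## Sequential two-site control

`seqcon_step()` scales the extensor and flexor channels' EMG$\sigma$ into
%MVC (each gain calibrated so the channel's own calibration segment mean
maps to 30 %MVC), applies per-channel dead zones, and drives the *active*
DoF with the algebraic difference extensor − flexor; the inactive DoF is
always zero. A co-contraction — both scaled channels above their
co-contraction thresholds for `window_ms` (30–100 ms, default 50, rounded
to the 10 ms control frame) — toggles the active DoF once.

Two behaviors are deliberately configurable because they are design choices
rather than documented protocol: a post-toggle refractory hold-off (default
300 ms; output zero and detection disabled) preventing immediate
double-toggles, and suppression of output while a detection is in progress
(default **off**: users of two-site systems do see movement in the run-up
to a trigger, since one channel usually rises faster than the other). The
default co-contraction threshold is set midway between the 30 %MVC
calibration effort and a nominal 60 %MVC co-contraction peak (i.e.
45 %MVC) when no co-contraction recording is supplied; with one, pass its
per-channel peak via `cocon_peak`.

## Virtual prosthesis plant

A first-order kinematic plant integrates commands at 100 Hz: aperture
clamped to its 0–100 mm travel (the command is absorbed at the stop), wrist
angle unbounded and exactly the discrete integral of commanded rates. The
gripper's published travel is not part of its speed rating, so 0–100 mm is
a configurable default. No motor dynamics, backlash, or grip-force model is
included — the hardware being emulated is velocity-controlled and none of
the controllers depend on such dynamics.

## Synthetic sessions: what they do and do not emulate

`simulate_session()` generates a complete calibration recording with known
ground truth:

* **Mixing** (`make_mixing()`): each direction peaks on its own contiguous
  arc of the electrode ring with smooth cosine falloff (antagonists on
  opposite arcs), small lognormal gain perturbations, a per-channel noise
  floor, and optional 60 Hz interference. Channels can be designated pure
  noise (floor only) for selection experiments.
* **Efforts** (`effort_from_schedule()`): each active direction ramps to
  30 %MVC over 0.5 s, holds with a slow (~0.5 Hz) multiplicative wander of
  10 % relative sd — emulating a subject holding a target force without
  feedback — and ramps off. Ramps sit inside the 1 s trims.
* **Carrier** (`synthesize_emg()`): per channel, the 100 Hz amplitude
  envelope (floor + gains · efforts) is zero-order held to 2000 Hz and
  multiplies an independent unit-variance 20–450 Hz Gaussian carrier — the
  standard amplitude-modulation model of surface EMG, consistent with the
  estimator's demodulation assumptions. One global seed streams
  per-channel sub-seeds, so sessions are byte-reproducible.

On these sessions the pipeline recovers ground-truth force with RMSE below
1 %MVC (no jitter) and well below 5 %MVC (default jitter) over the retained
frames, rest shows the lowest per-type RMSE (a subject can reproduce rest
far better than a 30 % hold), and selection to 6 channels discards
designated noise channels.

What the generator does **not** emulate — and hence what passing tests do
not show about real recordings: motor-unit structure (the carrier is
Gaussian, real EMG at low effort is spiky), electrode shift with forearm
rotation, fatigue, crosstalk structure beyond smooth arcs, movement
artifact below 15 Hz, and above all a human in the loop adapting to the
controller. The recovery numbers certify the *pipeline*, not clinical
performance.

## Problem sizes and determinism

The test suite and the acceptance script run full-protocol sessions (90 s,
2000 Hz, 16 channels) for the end-to-end properties and short scaled
sessions (18 s, 8 channels) for unit-level checks; the whole suite runs in
about a minute on one CPU. Every stochastic test fixes its seed; fitted
models serialized without timestamps are byte-identical across runs, as are
simulated sessions and pipeline outputs for a fixed configuration and seed.

## Known limitations

* EDF input is not implemented; the package reads the documented CSV
  dialect only.
* %MVC is a nominal scale throughout (no force measurement exists to
  anchor it); all RMSEs inherit that caveat.
* The co-contraction threshold default is a heuristic; real fittings set it
  per user from a maximum co-contraction recording.
* Backward selection optimizes offline training RMSE, which is known to be
  an imperfect proxy for online controllability.
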