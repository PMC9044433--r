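# myoprop

Regression-based, simultaneous and proportional two degree-of-freedom
(2-DoF) myoelectric control of a hand–wrist prosthesis, from multichannel
surface EMG — as a tested R package with a virtual prosthesis and a seeded
synthetic EMG generator in place of subjects and hardware.

## Who this is for

Researchers and engineers working on upper-limb myoelectric control who
want a reproducible, desk-scale implementation of the full chain:
EMG amplitude estimation → linear EMGσ–force calibration → electrode
selection → thresholding/gating → velocity commands → plant. Three control
strategies are implemented: **DirCon** (native open-close and
pronation-supination drive the matching prosthesis actions), **MapCon**
(wrist extension-flexion drives hand open-close, radial-ulnar deviation
drives wrist rotation), and the conventional two-site sequential
controller **SeqCon** with co-contraction mode switching.

## The model

Raw EMG (2000 Hz) becomes **EMGσ** — a 100 Hz running estimate of the EMG
standard deviation — via a causal cascade: 60 Hz notch (1 Hz bandwidth) →
15 Hz 5th-order Butterworth highpass → full-wave rectification → 16 Hz
9th-order Chebyshev I lowpass (0.05 dB ripple) → decimate ×20 → 1 Hz
2nd-order critically damped smoother. Streaming and batch processing are
bit-identical.

Calibration fits the 2-output linear map

    F = W' σ + b,    F = (hand, wrist) in %MVC

on a 90 s schedule (rest + eight 10 s contractions at a 30 %MVC target,
first/last second trimmed, rest weighted 8×) by the **truncated-SVD
pseudo-inverse**: singular values with `s_i / s_max < Tol` (default 0.01)
are removed and the minimum-norm solution taken. **Backward stepwise
selection** greedily drops the channel whose removal yields the lowest
training RMSE until the target electrode count (e.g. 6 of 16) remains.

At run time each force estimate passes per-direction resting thresholds
(default 10 %MVC), a fixed-ratio co-activation gate (suppresses the
smaller DoF inside α = 25° of the dominant axis), and a linear velocity
map (threshold → hardware minimum speed, 50 %MVC → maximum: 200 mm/s hand,
28 rpm = 168 °/s wrist). SeqCon instead scales two channels to %MVC,
drives the active DoF with their algebraic difference, and toggles DoFs on
a co-contraction sustained for 30–100 ms.

## Worked example

Simulate a 16-channel calibration session, calibrate, select 6 electrodes,
and drive the controller:

```r
library(myoprop)
ses   <- simulate_session("DirCon", n_channels = 16, seed = 42)
sigma <- process_batch(ses$raw)
model <- emg_force_fit(sigma, ses$schedule)
summary(model)
#> 2-DoF EMG-sigma force model (DirCon)
#>   channels: ch01, ch02, ch03, ch04, ch05, ch06, ch07, ch08, ch09, ch10,
#>             ch11, ch12, ch13, ch14, ch15, ch16 (+ bias)
#>   singular values retained: 12 of 17 (Tol = 0.01)
#>   calibration RMSE: 1.396 %MVC overall
#>
#> Calibration-quality RMSE by contraction type (%MVC):
#>    Rest     Cls     Opn     Sup     Pro Cls+Sup Cls+Pro Opn+Sup Opn+Pro
#>   0.064   1.633   1.719   1.555   1.745   2.186   2.242   2.301   2.226
```

The overall RMSE says the fitted map tracks the ±30 %MVC targets to within
about 1.4 %MVC on the calibration data; rest is far lower than the active
types because the synthetic "subject" holds rest perfectly but wanders
around an active 30 % target. Now select electrodes and predict:

```r
model6 <- backward_select(model, 6)
model6
#> 2-DoF EMG-sigma force model (DirCon)
#>   channels: ch02, ch05, ch08, ch10, ch12, ch14 (+ bias)
#>   singular values retained: 7 of 7 (Tol = 0.01)
#>   calibration RMSE: 1.402 %MVC overall

pred <- predict(model6, sigma)
rmse <- sqrt(mean((pred[1001:1900, ] - ses$truth[1001:1900, ])^2))
cat(sprintf("force-recovery RMSE over the held Cls segment: %.2f %%MVC\n", rmse))
#> force-recovery RMSE over the held Cls segment: 3.09 %MVC

regression_controller_step(sigma$sigma[1500, ], model6)
#>   hand_mm_s wrist_deg_s
#>      -96.99        0.00
```

Six optimally-sited electrodes cost almost nothing in training RMSE
(1.402 vs 1.396 %MVC). During the closing contraction the controller
commands the gripper to close at ~97 mm/s with the wrist correctly gated
to zero. `run_pipeline()` runs the same chain end to end (including the
virtual plant and CSV/JSON outputs), and `inst/cli/myoprop.R` exposes
`simulate` / `calibrate` / `select-channels` / `run` subcommands.

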