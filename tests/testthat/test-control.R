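cfg_default <- controller_config()
plant_default <- plant_spec()

test_that("resting thresholds zero sub-threshold components per direction", {
  expect_equal(apply_rest_threshold(c(hand = 9, wrist = 0), cfg_default),
               c(hand = 0, wrist = 0))
  expect_equal(apply_rest_threshold(c(hand = 0, wrist = 0), cfg_default),
               c(hand = 0, wrist = 0))
  # per-direction thresholds act componentwise on the signed value
  cfg <- controller_config(rest_thresholds = c(open = 10, close = 10,
                                               pro = 10, sup = 12))
  expect_equal(apply_rest_threshold(c(hand = 12, wrist = -11), cfg),
               c(hand = 12, wrist = 0))
  # exactly at threshold passes
  expect_equal(apply_rest_threshold(c(hand = 10, wrist = -10), cfg_default),
               c(hand = 10, wrist = -10))
})

test_that("angle gate suppresses the smaller DoF inside alpha, passes diagonals", {
  expect_equal(coactivation_gate(c(hand = 30, wrist = 0), 25),
               c(hand = 30, wrist = 0))
  expect_equal(coactivation_gate(c(hand = 30, wrist = 30), 25),
               c(hand = 30, wrist = 30))  # 45 deg >= alpha
  expect_equal(coactivation_gate(c(hand = 30, wrist = 10), 25),
               c(hand = 30, wrist = 0))   # 18.4 deg < alpha
  expect_equal(coactivation_gate(c(hand = -10, wrist = 30), 25),
               c(hand = 0, wrist = 30))   # sign-independent magnitudes
  expect_equal(coactivation_gate(c(hand = 20, wrist = 15), 25),
               c(hand = 20, wrist = 15))  # 36.9 deg passes
})

test_that("gate boundary angle is recovered to within 0.01 degree by bisection", {
  for (alpha in c(15, 25, 35)) {
    surv <- function(th) {
      f <- c(hand = 30 * cos(th * pi / 180), wrist = 30 * sin(th * pi / 180))
      coactivation_gate(f, alpha)[["wrist"]] != 0
    }
    lo <- 0; hi <- 44.9
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (surv(mid)) hi <- mid else lo <- mid
    }
    expect_lt(abs((lo + hi) / 2 - alpha), 0.01)
  }
})

test_that("ratio rule implements the literal larger-over-smaller reading", {
  # ratio 3 >= default threshold 1/tan(25) = 2.14: both pass
  expect_equal(coactivation_gate(c(hand = 30, wrist = 10), 25, rule = "ratio"),
               c(hand = 30, wrist = 10))
  # ratio 1.2 < 2.14: smaller suppressed
  expect_equal(coactivation_gate(c(hand = 30, wrist = 25), 25, rule = "ratio"),
               c(hand = 30, wrist = 0))
  # on-axis passes (no smaller force to compare)
  expect_equal(coactivation_gate(c(hand = 30, wrist = 0), 25, rule = "ratio"),
               c(hand = 30, wrist = 0))
})

test_that("velocity map spans threshold-to-saturation with clamping and inversion", {
  f2v <- function(f) force_to_velocity(f, cfg_default, plant_default)
  expect_equal(f2v(c(hand = 0, wrist = 0)),
               c(hand_mm_s = 0, wrist_deg_s = 0))
  expect_equal(f2v(c(hand = 50, wrist = 0))[["hand_mm_s"]], 200)
  expect_equal(f2v(c(hand = 80, wrist = 0)), f2v(c(hand = 50, wrist = 0)))
  expect_equal(f2v(c(hand = 10, wrist = 0))[["hand_mm_s"]], 8)  # plant minimum
  expect_equal(f2v(c(hand = 30, wrist = 0))[["hand_mm_s"]], 8 + 0.5 * 192)
  expect_equal(f2v(c(hand = -50, wrist = 0))[["hand_mm_s"]], -200)
  expect_equal(f2v(c(hand = 0, wrist = 50))[["wrist_deg_s"]], 168)
  expect_equal(f2v(c(hand = 0, wrist = -50))[["wrist_deg_s"]], -168)
  cfg_inv <- controller_config(invert_wrist = TRUE)
  expect_equal(force_to_velocity(c(hand = 50, wrist = 50), cfg_inv,
                                 plant_default),
               c(hand_mm_s = 200, wrist_deg_s = -168))
})

test_that("threshold-gate conditioning is idempotent", {
  set.seed(41)
  for (i in 1:200) {
    f <- c(hand = runif(1, -60, 60), wrist = runif(1, -60, 60))
    once <- myoprop:::condition_force(f, cfg_default)
    expect_identical(myoprop:::condition_force(once, cfg_default), once)
  }
})

test_that("regression controller: zero frame rests, calibration replay closes the hand", {
  ses <- small_session(jitter = 0)
  m <- emg_force_fit(ses$sigma, ses$schedule, ses$fitspec)
  cmd0 <- regression_controller_step(numeric(8), m)
  expect_equal(cmd0, c(hand_mm_s = 0, wrist_deg_s = 0))
  # frames from the held portion of the Cls segment: strictly closing, no wrist
  cls_i <- which(ses$schedule$type == "Cls")
  fs <- 100
  idx <- round(ses$schedule$start_s[cls_i] * fs) + 60:140
  for (i in idx[seq(1, length(idx), by = 20)]) {
    cmd <- regression_controller_step(ses$sigma$sigma[i, ], m)
    expect_lt(cmd[["hand_mm_s"]], 0)
    expect_equal(cmd[["wrist_deg_s"]], 0)
  }
  # wrist inversion flips only the wrist
  pro_i <- which(ses$schedule$type == "Pro")
  ip <- round(ses$schedule$start_s[pro_i] * fs) + 100
  cmd <- regression_controller_step(ses$sigma$sigma[ip, ], m)
  cmd_inv <- regression_controller_step(ses$sigma$sigma[ip, ], m,
                                        controller_config(invert_wrist = TRUE))
  expect_equal(cmd_inv[["wrist_deg_s"]], -cmd[["wrist_deg_s"]])
  expect_equal(cmd_inv[["hand_mm_s"]], cmd[["hand_mm_s"]])
})

test_that("sequential gains calibrate to effort over the dedicated segments", {
  sched <- build_schedule("MapCon")
  sig <- matrix(0.01, 9000, 4)
  ext_i <- which(sched$type == "Ext"); flx_i <- which(sched$type == "Flx")
  sig[sched$start_s[ext_i] * 100 + 1:1000, 2] <- 0.2
  sig[sched$start_s[flx_i] * 100 + 1:1000, 3] <- 0.5
  ss <- sigma_series(sig)
  sp <- seqcon_calibrate(ss, sched, ext_channel = 2, flx_channel = 3)
  expect_equal(sp$gain_ext, 30 / 0.2)
  expect_equal(sp$gain_flx, 30 / 0.5)
  # replaying the Ext segment through the gain recovers ~30 %MVC
  expect_equal(mean(sig[sched$start_s[ext_i] * 100 + 101:900, 2]) * sp$gain_ext,
               30)
  # swapped channels swap gains
  sp2 <- seqcon_calibrate(ss, sched, ext_channel = 3, flx_channel = 2)
  expect_equal(sp2$gain_ext, 30 / mean(sig[sched$start_s[ext_i] * 100 + 101:900, 3]))
  # degenerate channel errors
  expect_error(seqcon_calibrate(sigma_series(matrix(0, 9000, 4)), sched, 1, 2),
               "degenerate")
  # default co-contraction threshold sits midway between effort and peak
  expect_equal(sp$cocon_thr_ext, 45)
})

test_that("co-contraction timer toggles exactly at the window and respects refractory", {
  sp <- seqcon_spec(1, 2, window_ms = 50, refractory_ms = 300)
  mk <- function(frames_above) {
    sig <- matrix(5, 100, 2)
    if (frames_above > 0) sig[20 + seq_len(frames_above) - 1, ] <- 60
    sigma_series(sig)
  }
  # window - 10 ms: no toggle
  expect_equal(attr(run_seqcon(mk(4), sp), "toggles"), 0L)
  # >= window: exactly one toggle, hand -> wrist
  r <- run_seqcon(mk(30), sp)
  expect_equal(attr(r, "toggles"), 1L)
  expect_equal(r$active_dof[100], "wrist")
  # output forced to zero during the refractory hold-off
  toggle_frame <- which(r$active_dof == "wrist")[1]
  refr <- toggle_frame + 0:29
  expect_true(all(r$hand_mm_s[refr] == 0 & r$wrist_deg_s[refr] == 0))
})

test_that("net drive routes to the active DoF only, never both", {
  sp <- seqcon_spec(1, 2, gain_ext = 1, gain_flx = 1)
  st <- seqcon_state(sp)
  r <- seqcon_step(c(30, 0), sp, st)
  expect_gt(r$command[["hand_mm_s"]], 0)   # opening
  expect_equal(r$command[["wrist_deg_s"]], 0)
  st$active_dof <- "wrist"
  r <- seqcon_step(c(30, 0), sp, st)
  expect_gt(r$command[["wrist_deg_s"]], 0)  # pronation
  expect_equal(r$command[["hand_mm_s"]], 0)
  # flexor dominance drives the negative direction
  r <- seqcon_step(c(0, 30), sp, seqcon_state(sp))
  expect_lt(r$command[["hand_mm_s"]], 0)
  # property: a frame never actuates both DoFs
  set.seed(43)
  sig <- matrix(runif(400, 0, 80), 200, 2)
  out <- run_seqcon(sigma_series(sig), sp)
  expect_false(any(out$hand_mm_s != 0 & out$wrist_deg_s != 0))
})

test_that("seqcon_spec validates window, distinct channels and thresholds", {
  expect_error(seqcon_spec(1, 1), "distinct")
  expect_error(seqcon_spec(1, 2, window_ms = 20))
  expect_error(seqcon_spec(1, 2, window_ms = 150))
  expect_error(controller_config(gate_alpha_deg = 45))
  expect_error(controller_config(vel_sat_pct = 0))
  expect_error(controller_config(rest_thresholds = c(open = 60, close = 10,
                                                     pro = 10, sup = 10)))
})
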