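# Deterministic sub-seed stream: one global seed fans out to per-purpose
# seeds (effort jitter, one per channel carrier) so channels are independent
# yet the whole session is reproducible from a single integer.
substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Circumferential electrode mixing model for synthetic EMG
#'
#' Emulates a ring of bipolar electrodes around the forearm: each of the
#' four contraction directions (canonical columns `open`, `close`, `pro`,
#' `sup`; read them as ext/flx/rad/uln under mapped-strategy semantics)
#' peaks on its own contiguous arc of channels with a smooth cosine falloff
#' (clipped at zero), antagonist directions on opposite arcs, plus a small
#' per-gain lognormal perturbation. Channels listed in `noise_channels`
#' carry no direction gain at all, only their noise floor.
#'
#' @param n_channels number of channels (at least 4 informative)
#' @param seed integer seed; the mixing is deterministic given the seed
#' @param noise_floor per-channel baseline amplitude (scalar recycled)
#' @param interference_amp amplitude of additive 60 Hz power-line
#'   interference (0 disables)
#' @param gain_scale peak direction gain, amplitude units per %MVC
#' @param noise_channels indices of channels with zero direction gain
#' @return an object of class `mixing_model` with `gains` (channels x 4),
#'   `noise_floor`, `interference_amp`
#' @export
make_mixing <- function(n_channels, seed, noise_floor = 0.005,
                        interference_amp = 0, gain_scale = 1 / 30,
                        noise_channels = integer(0)) {
  if (n_channels - length(noise_channels) < 4)
    stop("mixing needs at least 4 informative channels", call. = FALSE)
  set.seed(seed)
  offset <- runif(1, 0, 2 * pi)
  theta <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  centers <- offset + 2 * pi * c(open = 0, close = 0.5, pro = 0.25, sup = 0.75)
  gains <- sapply(centers, function(phi) pmax(0, cos(theta - phi))) * gain_scale
  gains <- gains * matrix(exp(0.1 * rnorm(length(gains))), nrow(gains))
  gains[noise_channels, ] <- 0
  colnames(gains) <- names(centers)
  rownames(gains) <- sprintf("ch%02d", seq_len(n_channels))
  noise_floor <- rep_len(noise_floor, n_channels)
  ok <- vapply(seq_len(4), function(d) {
    any(gains[, d] > 2 * noise_floor)
  }, logical(1))
  if (!all(ok))
    stop("mixing invariant violated: a direction has no channel gain above twice its noise floor",
         call. = FALSE)
  structure(list(gains = gains, noise_floor = noise_floor,
                 interference_amp = interference_amp,
                 n_channels = n_channels, seed = seed),
            class = "mixing_model")
}

#' Synthetic session specification
#'
#' @param seed integer seed driving every random draw of the session
#' @param fs_hz raw sampling rate (default 2000); must be an integer
#'   multiple of 100
#' @param ramp_s effort on/off ramp duration at segment edges (default 0.5)
#' @param effort_jitter_rel relative standard deviation of the slow
#'   multiplicative effort wander during holds (default 0.1), emulating a
#'   subject's inability to hold a fixed force without feedback
#' @param carrier_band_hz passband of the band-limited Gaussian carrier
#'   (default 20-450 Hz, the surface-EMG energy band)
#' @return an object of class `session_spec`
#' @export
session_spec <- function(seed = 1, fs_hz = 2000, ramp_s = 0.5,
                         effort_jitter_rel = 0.1,
                         carrier_band_hz = c(20, 450)) {
  stopifnot(fs_hz > 0, fs_hz %% 100 == 0, ramp_s >= 0,
            effort_jitter_rel >= 0, effort_jitter_rel < 1,
            length(carrier_band_hz) == 2,
            carrier_band_hz[1] > 0, carrier_band_hz[2] < fs_hz / 2,
            carrier_band_hz[1] < carrier_band_hz[2])
  structure(list(seed = as.integer(seed), fs_hz = fs_hz, ramp_s = ramp_s,
                 effort_jitter_rel = effort_jitter_rel,
                 carrier_band_hz = carrier_band_hz),
            class = "session_spec")
}

#' Ground-truth effort trajectory realizing a calibration schedule
#'
#' For each segment, every active direction ramps linearly to `effort_pct`
#' over `ramp_s`, holds with slow multiplicative jitter, and ramps off in
#' the segment's last `ramp_s`. Rest segments are all-zero. At most one
#' direction per DoF is active at a time. 100 Hz frames.
#'
#' @param schedule a [build_schedule()] result
#' @param effort_pct hold effort, %MVC
#' @param spec a [session_spec()] (seed, ramps, jitter)
#' @return an object of class `effort_trajectory`: matrix `efforts`
#'   (frames x 4, columns open/close/pro/sup, nonnegative %MVC) plus
#'   `fs_hz = 100`
#' @export
effort_from_schedule <- function(schedule, effort_pct = 30,
                                 spec = session_spec()) {
  stopifnot(inherits(schedule, "calibration_schedule"))
  fs <- 100
  set.seed(substream_seeds(spec$seed, 1)[1])
  n <- round(sum(schedule$duration_s) * fs)
  eff <- matrix(0, n, 4, dimnames = list(NULL, c("open", "close", "pro", "sup")))
  alpha <- exp(-2 * pi * 0.5 / fs)  # one-pole smoother, ~0.5 Hz wander
  for (i in seq_len(nrow(schedule))) {
    act <- active_directions(schedule$type[i])
    if (!any(act > 0)) next
    n_seg <- round(schedule$duration_s[i] * fs)
    i0 <- round(schedule$start_s[i] * fs)
    ramp_n <- min(round(spec$ramp_s * fs), floor(n_seg / 4))
    prof <- rep(effort_pct, n_seg)
    if (ramp_n > 0) {
      prof[seq_len(ramp_n)] <- effort_pct * seq_len(ramp_n) / ramp_n
      prof[n_seg - ramp_n + seq_len(ramp_n)] <- effort_pct * rev(seq_len(ramp_n)) / ramp_n
    }
    for (d in which(act > 0)) {
      p <- prof
      if (spec$effort_jitter_rel > 0) {
        w <- as.numeric(stats::filter(rnorm(n_seg), alpha, "recursive",
                                      init = 0)) * (1 - alpha)
        s <- sd(w)
        if (s > 0) w <- w / s
        p <- pmax(0, p * (1 + spec$effort_jitter_rel * w))
      }
      eff[i0 + seq_len(n_seg), d] <- p
    }
  }
  structure(list(efforts = eff, fs_hz = fs, schedule = schedule,
                 effort_pct = effort_pct),
            class = "effort_trajectory")
}

#' Signed 2-DoF ground-truth force of an effort trajectory
#'
#' @param traj an [effort_from_schedule()] result
#' @return matrix (frames x 2), columns `hand` (= open - close) and `wrist`
#'   (= pro - sup), in %MVC
#' @export
ground_truth_force <- function(traj) {
  stopifnot(inherits(traj, "effort_trajectory"))
  e <- traj$efforts
  cbind(hand = e[, "open"] - e[, "close"],
        wrist = e[, "pro"] - e[, "sup"])
}

#' Synthesize amplitude-modulated raw surface EMG
#'
#' Per channel, the raw signal is `(noise_floor + gains . effort_frame)`,
#' zero-order held from 100 Hz to the raw rate, multiplied by an
#' independent unit-variance band-limited Gaussian carrier, plus optional
#' 60 Hz sinusoidal interference. Deterministic given the session seed:
#' each channel's carrier draws from its own sub-seed.
#'
#' @param traj an [effort_from_schedule()] result
#' @param mixing a [make_mixing()] model
#' @param spec a [session_spec()]
#' @return a [raw_emg()] recording at `spec$fs_hz`
#' @export
synthesize_emg <- function(traj, mixing, spec = session_spec()) {
  stopifnot(inherits(traj, "effort_trajectory"),
            inherits(mixing, "mixing_model"))
  decim <- spec$fs_hz / traj$fs_hz
  stopifnot(decim == round(decim))
  n100 <- nrow(traj$efforts)
  n_raw <- n100 * decim
  amp100 <- traj$efforts %*% t(mixing$gains)  # frames x channels
  amp100 <- sweep(amp100, 2, mixing$noise_floor, "+")
  hold <- rep(seq_len(n100), each = decim)
  seeds <- substream_seeds(spec$seed, 1 + mixing$n_channels)
  bp <- signal::butter(4, spec$carrier_band_hz / (spec$fs_hz / 2), type = "pass")
  raw <- matrix(0, n_raw, mixing$n_channels)
  t_raw <- (seq_len(n_raw) - 1) / spec$fs_hz
  interf <- if (mixing$interference_amp > 0)
    mixing$interference_amp * sin(2 * pi * 60 * t_raw) else 0
  for (ch in seq_len(mixing$n_channels)) {
    set.seed(seeds[1 + ch])
    carrier <- run_stage(list(list(b = as.numeric(bp$b), a = as.numeric(bp$a))),
                         rnorm(n_raw))$y
    carrier <- carrier / sd(carrier)
    raw[, ch] <- amp100[hold, ch] * carrier + interf
  }
  raw_emg(raw, fs_hz = spec$fs_hz,
          channel_names = rownames(mixing$gains))
}

# Scaled-duration schedule for quick examples and tests: same nine-segment
# structure, shorter segments.
scaled_schedule <- function(strategy, scale) {
  sched <- build_schedule(strategy)
  sched$duration_s <- sched$duration_s * scale
  sched$start_s <- cumsum(c(0, head(sched$duration_s, -1)))
  sched
}

#' Simulate a full synthetic calibration session
#'
#' Convenience wrapper: builds the schedule, the circumferential mixing,
#' the jittered effort trajectory, the raw EMG and the signed ground truth,
#' all deterministically from one seed.
#'
#' @param strategy `"DirCon"` or `"MapCon"`
#' @param n_channels number of electrodes (default 16)
#' @param seed integer session seed
#' @param session a [session_spec()] (defaults to `session_spec(seed)`)
#' @param mixing a [make_mixing()] model (defaults to one drawn from `seed`)
#' @param effort_pct target effort, %MVC
#' @param duration_scale scale factor on the 10 s segment duration (1 =
#'   full 90 s session; smaller values give quick sessions for examples)
#' @param noise_channels channels carrying only noise floor (passed to
#'   [make_mixing()])
#' @return list of class `emg_session`: `raw`, `traj`, `truth`, `schedule`,
#'   `mixing`, `session`, `strategy`
#' @export
simulate_session <- function(strategy = "DirCon", n_channels = 16, seed = 1,
                             session = session_spec(seed),
                             mixing = NULL, effort_pct = 30,
                             duration_scale = 1,
                             noise_channels = integer(0)) {
  if (is.null(mixing))
    mixing <- make_mixing(n_channels, seed, noise_channels = noise_channels)
  schedule <- if (duration_scale == 1) build_schedule(strategy)
              else scaled_schedule(strategy, duration_scale)
  traj <- effort_from_schedule(schedule, effort_pct, session)
  raw <- synthesize_emg(traj, mixing, session)
  structure(list(raw = raw, traj = traj,
                 truth = ground_truth_force(traj),
                 schedule = schedule, mixing = mixing, session = session,
                 strategy = attr(schedule, "strategy")),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("synthetic %s session: %d channels, %.1f s at %g Hz (seed %d)\n",
              x$strategy, ncol(x$raw$samples),
              nrow(x$raw$samples) / x$raw$fs_hz, x$raw$fs_hz, x$session$seed))
  invisible(x)
}
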