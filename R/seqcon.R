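#' Two-site sequential controller specification
#'
#' Conventional sequential control uses two channels (extensor and flexor
#' sites). Each channel's EMG-sigma is scaled by a gain into %MVC, a
#' resting dead zone is applied per channel, and the estimated force is the
#' algebraic difference extensor minus flexor, driving whichever DoF is
#' currently active. A co-contraction (both scaled channels above their
#' co-contraction thresholds for `window_ms`) toggles the active DoF.
#'
#' @param ext_channel,flx_channel channel indices (distinct)
#' @param gain_ext,gain_flx scale factors, %MVC per sigma unit
#' @param rest_thr_ext,rest_thr_flx per-channel resting dead zones, %MVC
#' @param cocon_thr_ext,cocon_thr_flx co-contraction detection thresholds,
#'   %MVC
#' @param window_ms co-contraction duration required to toggle, within
#'   30-100 ms (default 50); rounded to the nearest 10 ms control frame
#' @param refractory_ms post-toggle hold-off during which output is zero and
#'   detection is disabled (default 300; may be 0)
#' @param initial_dof DoF active at start (`"hand"`)
#' @param suppress_during_detection zero the output while a co-contraction
#'   is accumulating but has not yet toggled (default `FALSE`: movement
#'   before the trigger completes is not suppressed)
#' @return an object of class `seqcon_spec`
#' @export
seqcon_spec <- function(ext_channel, flx_channel,
                        gain_ext = 1, gain_flx = 1,
                        rest_thr_ext = 10, rest_thr_flx = 10,
                        cocon_thr_ext = 45, cocon_thr_flx = 45,
                        window_ms = 50, refractory_ms = 300,
                        initial_dof = c("hand", "wrist"),
                        suppress_during_detection = FALSE) {
  initial_dof <- match.arg(initial_dof)
  if (ext_channel == flx_channel)
    stop("extensor and flexor channels must be distinct", call. = FALSE)
  stopifnot(window_ms >= 30, window_ms <= 100, refractory_ms >= 0,
            rest_thr_ext >= 0, rest_thr_flx >= 0,
            cocon_thr_ext >= 0, cocon_thr_flx >= 0,
            gain_ext > 0, gain_flx > 0)
  structure(list(ext_channel = as.integer(ext_channel),
                 flx_channel = as.integer(flx_channel),
                 gain_ext = gain_ext, gain_flx = gain_flx,
                 rest_thr_ext = rest_thr_ext, rest_thr_flx = rest_thr_flx,
                 cocon_thr_ext = cocon_thr_ext, cocon_thr_flx = cocon_thr_flx,
                 window_ms = window_ms, refractory_ms = refractory_ms,
                 initial_dof = initial_dof,
                 suppress_during_detection = isTRUE(suppress_during_detection)),
            class = "seqcon_spec")
}

#' Calibrate the sequential controller's channel gains from a recording
#'
#' Sets each channel gain so the mean EMG-sigma over its dedicated trimmed
#' calibration segment (Ext segment for the extensor channel, Flx for the
#' flexor) maps to `effort_pct` %MVC: `gain = effort_pct / mean(sigma)`.
#' Resting thresholds default to 10 %MVC; each co-contraction threshold is
#' set midway between `effort_pct` and that channel's co-contraction peak
#' (default peak 60 %MVC when no co-contraction recording is supplied). All
#' values remain editable on the returned spec.
#'
#' @param sigma a [sigma_series()] covering the schedule
#' @param schedule a [build_schedule()] result containing `Ext` and `Flx`
#'   segments (the mapped-strategy schedule)
#' @param ext_channel,flx_channel channel indices
#' @param effort_pct calibration target effort, %MVC
#' @param trim_s edge trim per segment, s
#' @param cocon_peak length-2 numeric, co-contraction peak scaled force for
#'   the ext and flx channels, %MVC
#' @param ... further arguments passed to [seqcon_spec()]
#' @return a [seqcon_spec()]
#' @export
seqcon_calibrate <- function(sigma, schedule, ext_channel, flx_channel,
                             effort_pct = 30, trim_s = 1,
                             cocon_peak = c(60, 60), ...) {
  stopifnot(inherits(sigma, "sigma_series"),
            inherits(schedule, "calibration_schedule"))
  seg_mean <- function(type, ch) {
    i <- match(type, schedule$type)
    if (is.na(i))
      stop(sprintf("schedule has no '%s' segment (sequential calibration needs the mapped-strategy schedule)",
                   type), call. = FALSE)
    fs <- sigma$fs_hz
    idx <- round(schedule$start_s[i] * fs) +
      seq(round(trim_s * fs) + 1, round((schedule$duration_s[i] - trim_s) * fs))
    mean(sigma$sigma[idx, ch])
  }
  m_ext <- seg_mean("Ext", ext_channel)
  m_flx <- seg_mean("Flx", flx_channel)
  if (m_ext <= 0 || m_flx <= 0)
    stop("degenerate channel: zero mean EMG-sigma over its calibration segment",
         call. = FALSE)
  seqcon_spec(ext_channel, flx_channel,
              gain_ext = effort_pct / m_ext, gain_flx = effort_pct / m_flx,
              cocon_thr_ext = (effort_pct + cocon_peak[1]) / 2,
              cocon_thr_flx = (effort_pct + cocon_peak[2]) / 2, ...)
}

#' Initial state of the sequential controller
#'
#' @param spec a [seqcon_spec()]
#' @return an object of class `seqcon_state` with fields `active_dof`,
#'   `cocon_elapsed_ms`, `refractory_remaining_ms`, `toggles`
#' @export
seqcon_state <- function(spec) {
  structure(list(active_dof = spec$initial_dof,
                 cocon_elapsed_ms = 0, refractory_remaining_ms = 0,
                 toggles = 0L),
            class = "seqcon_state")
}

#' One 100 Hz step of the sequential controller
#'
#' Scales both channels into %MVC, applies per-channel dead zones, and
#' routes the algebraic difference (extensor minus flexor) to the active
#' DoF through the velocity map; the inactive DoF is always zero. The
#' co-contraction timer accumulates (10 ms per frame) while both scaled
#' values exceed their co-contraction thresholds, resetting otherwise; on
#' reaching `window_ms` the active DoF toggles once, the timer resets, and
#' the refractory hold-off starts (output zero, detection disabled, until it
#' expires).
#'
#' @param sigma_frame numeric vector of per-channel EMG-sigma
#' @param spec a [seqcon_spec()]
#' @param state a [seqcon_state()]
#' @param plant a [plant_spec()]
#' @param cfg a [controller_config()] supplying the velocity map's
#'   saturation and direction thresholds
#' @return list with `command` (named velocity vector) and updated `state`
#' @export
seqcon_step <- function(sigma_frame, spec, state, plant = plant_spec(),
                        cfg = controller_config()) {
  dt_ms <- 1000 / plant$loop_hz
  s_ext <- unname(sigma_frame[spec$ext_channel]) * spec$gain_ext
  s_flx <- unname(sigma_frame[spec$flx_channel]) * spec$gain_flx
  suppressed <- FALSE
  if (state$refractory_remaining_ms > 0) {
    state$refractory_remaining_ms <- max(0, state$refractory_remaining_ms - dt_ms)
    state$cocon_elapsed_ms <- 0
    suppressed <- TRUE
  } else if (s_ext > spec$cocon_thr_ext && s_flx > spec$cocon_thr_flx) {
    state$cocon_elapsed_ms <- state$cocon_elapsed_ms + dt_ms
    if (state$cocon_elapsed_ms >= round(spec$window_ms / dt_ms) * dt_ms) {
      state$active_dof <- if (state$active_dof == "hand") "wrist" else "hand"
      state$toggles <- state$toggles + 1L
      state$cocon_elapsed_ms <- 0
      state$refractory_remaining_ms <- spec$refractory_ms
      suppressed <- TRUE
    } else if (spec$suppress_during_detection) suppressed <- TRUE
  } else {
    state$cocon_elapsed_ms <- 0
  }
  cmd <- c(hand_mm_s = 0, wrist_deg_s = 0)
  if (!suppressed) {
    e <- if (s_ext >= spec$rest_thr_ext) s_ext else 0
    f <- if (s_flx >= spec$rest_thr_flx) s_flx else 0
    net <- e - f
    force <- if (state$active_dof == "hand") c(hand = net, wrist = 0)
             else c(hand = 0, wrist = net)
    cmd <- force_to_velocity(force, cfg, plant)
  }
  list(command = cmd, state = state)
}

#' Run the sequential controller over a full sigma series
#'
#' @param sigma a [sigma_series()]
#' @param spec a [seqcon_spec()]
#' @param plant a [plant_spec()]
#' @param cfg a [controller_config()]
#' @return data frame with `t_s`, the active DoF, the net force and the
#'   velocity commands per frame; attribute `toggles` carries the toggle
#'   count
#' @export
run_seqcon <- function(sigma, spec, plant = plant_spec(),
                       cfg = controller_config()) {
  stopifnot(inherits(sigma, "sigma_series"))
  n <- nrow(sigma$sigma)
  state <- seqcon_state(spec)
  out <- data.frame(t_s = (seq_len(n) - 1) / sigma$fs_hz,
                    active_dof = character(n),
                    hand_mm_s = numeric(n), wrist_deg_s = numeric(n))
  for (i in seq_len(n)) {
    r <- seqcon_step(sigma$sigma[i, ], spec, state, plant, cfg)
    state <- r$state
    out$active_dof[i] <- state$active_dof
    out$hand_mm_s[i] <- r$command[["hand_mm_s"]]
    out$wrist_deg_s[i] <- r$command[["wrist_deg_s"]]
  }
  attr(out, "toggles") <- state$toggles
  out
}
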