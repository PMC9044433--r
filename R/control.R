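#' Controller configuration for the regression-based 2-DoF controllers
#'
#' @param rest_thresholds named nonnegative %MVC dead-zone thresholds for the
#'   four DoF directions (`open`, `close`, `pro`, `sup`); default 10 each
#' @param gate_alpha_deg co-activation gate angle alpha in degrees (default
#'   25): a force vector within alpha of the dominant axis actuates only the
#'   dominant DoF
#' @param vel_sat_pct effort (%MVC) mapped to maximum actuator speed
#'   (default 50); larger efforts are clamped
#' @param invert_hand,invert_wrist flip the sign of the corresponding
#'   velocity command (offered to users of the mapped strategy)
#' @param gate_rule `"angle"` (default) gates on the force-vector angle;
#'   `"ratio"` is the literal larger-to-smaller force-ratio reading (the two
#'   disagree; see the methods vignette)
#' @param ratio_threshold gate threshold for `gate_rule = "ratio"`; defaults
#'   to `1 / tan(gate_alpha_deg)`
#' @return an object of class `controller_config`
#' @export
controller_config <- function(rest_thresholds = c(open = 10, close = 10,
                                                  pro = 10, sup = 10),
                              gate_alpha_deg = 25, vel_sat_pct = 50,
                              invert_hand = FALSE, invert_wrist = FALSE,
                              gate_rule = c("angle", "ratio"),
                              ratio_threshold = NULL) {
  gate_rule <- match.arg(gate_rule)
  stopifnot(all(c("open", "close", "pro", "sup") %in% names(rest_thresholds)),
            all(rest_thresholds >= 0),
            gate_alpha_deg >= 0, gate_alpha_deg < 45,
            vel_sat_pct > 0, vel_sat_pct <= 100,
            all(rest_thresholds < vel_sat_pct))
  if (is.null(ratio_threshold))
    ratio_threshold <- if (gate_alpha_deg > 0) 1 / tan(gate_alpha_deg * pi / 180) else Inf
  structure(list(rest_thresholds = rest_thresholds[c("open", "close", "pro", "sup")],
                 gate_alpha_deg = gate_alpha_deg, vel_sat_pct = vel_sat_pct,
                 invert_hand = isTRUE(invert_hand),
                 invert_wrist = isTRUE(invert_wrist),
                 gate_rule = gate_rule, ratio_threshold = ratio_threshold),
            class = "controller_config")
}

#' Per-direction resting thresholds (hard dead zone)
#'
#' Each signed DoF estimate is zeroed when its magnitude is below the
#' threshold of the direction it points in (open/close for hand,
#' pro/sup for wrist); otherwise it passes unchanged. This suppresses noise
#' and small unintentional activation around rest.
#'
#' @param f named numeric `c(hand =, wrist =)` signed force in %MVC
#' @param cfg a [controller_config()]
#' @return thresholded force vector
#' @export
apply_rest_threshold <- function(f, cfg = controller_config()) {
  thr <- cfg$rest_thresholds
  h_thr <- if (f[["hand"]] >= 0) thr[["open"]] else thr[["close"]]
  w_thr <- if (f[["wrist"]] >= 0) thr[["pro"]] else thr[["sup"]]
  c(hand = if (abs(f[["hand"]]) < h_thr) 0 else f[["hand"]],
    wrist = if (abs(f[["wrist"]]) < w_thr) 0 else f[["wrist"]])
}

#' Fixed-ratio co-activation gate
#'
#' Suppresses the smaller-magnitude DoF when the 2-DoF force vector lies
#' within `alpha_deg` of the dominant axis in the hand-wrist plane: with
#' `a = atan2(min(|hand|,|wrist|), max(|hand|,|wrist|))` in degrees, if
#' `a < alpha_deg` the smaller component becomes zero, otherwise both pass.
#' An exact diagonal (`a = 45`) always passes both. The alternative
#' `rule = "ratio"` instead zeroes the smaller component when the
#' larger-to-smaller magnitude ratio is below `ratio_threshold`.
#'
#' @param f named numeric `c(hand =, wrist =)` signed %MVC
#' @param alpha_deg gate angle in `[0, 45)`
#' @param rule `"angle"` or `"ratio"`
#' @param ratio_threshold threshold for the ratio rule
#' @return gated force vector
#' @export
coactivation_gate <- function(f, alpha_deg = 25, rule = c("angle", "ratio"),
                              ratio_threshold = NULL) {
  rule <- match.arg(rule)
  stopifnot(alpha_deg >= 0, alpha_deg < 45)
  h <- abs(f[["hand"]]); w <- abs(f[["wrist"]])
  if (h == 0 && w == 0) return(c(hand = 0, wrist = 0))
  suppress_smaller <- if (rule == "angle") {
    a <- atan2(min(h, w), max(h, w)) * 180 / pi
    a < alpha_deg
  } else {
    if (is.null(ratio_threshold))
      ratio_threshold <- if (alpha_deg > 0) 1 / tan(alpha_deg * pi / 180) else Inf
    min(h, w) > 0 && max(h, w) / min(h, w) < ratio_threshold
  }
  out <- c(hand = f[["hand"]], wrist = f[["wrist"]])
  if (suppress_smaller && h != w) {
    if (h < w) out[["hand"]] <- 0 else out[["wrist"]] <- 0
  }
  out
}

condition_force <- function(f, cfg)
  coactivation_gate(apply_rest_threshold(f, cfg), cfg$gate_alpha_deg,
                    cfg$gate_rule, cfg$ratio_threshold)

#' Map thresholded, gated force to actuator velocity commands
#'
#' Per DoF: zero force gives zero velocity; a nonzero component maps
#' linearly from its direction's resting threshold (at the plant's minimum
#' actuation speed) up to `vel_sat_pct` %MVC (at the plant's maximum speed),
#' clamped at maximum beyond. Sign is preserved; inversion flags flip it.
#' The hand uses the gripper's 8-200 mm/s proportional speed range; the
#' wrist maps from zero up to its maximum rotation speed.
#'
#' @param f named numeric `c(hand =, wrist =)`, already thresholded/gated
#' @param cfg a [controller_config()]
#' @param plant a [plant_spec()]
#' @return named numeric `c(hand_mm_s =, wrist_deg_s =)` (+ hand = opening,
#'   + wrist = pronation)
#' @export
force_to_velocity <- function(f, cfg = controller_config(),
                              plant = plant_spec()) {
  sat <- cfg$vel_sat_pct
  map1 <- function(val, thr, vmin, vmax) {
    if (val == 0) return(0)
    m <- min(abs(val), sat)
    frac <- max(0, min(1, (m - thr) / (sat - thr)))
    sign(val) * (vmin + frac * (vmax - vmin))
  }
  h_thr <- if (f[["hand"]] >= 0) cfg$rest_thresholds[["open"]] else cfg$rest_thresholds[["close"]]
  w_thr <- if (f[["wrist"]] >= 0) cfg$rest_thresholds[["pro"]] else cfg$rest_thresholds[["sup"]]
  v <- c(hand_mm_s = map1(f[["hand"]], h_thr, plant$hand_speed_min_mm_s,
                          plant$hand_speed_max_mm_s),
         wrist_deg_s = map1(f[["wrist"]], w_thr, 0, wrist_speed_max_deg_s(plant)))
  if (cfg$invert_hand) v[["hand_mm_s"]] <- -v[["hand_mm_s"]]
  if (cfg$invert_wrist) v[["wrist_deg_s"]] <- -v[["wrist_deg_s"]]
  v
}

#' One 100 Hz step of the regression-based controller
#'
#' Composes force prediction, resting thresholds, co-activation gate and the
#' velocity map for a single sigma frame. The runtime path is identical for
#' the direct and mapped strategies; the mapping semantics live entirely in
#' the calibration labels plus the inversion flags.
#'
#' @param sigma_frame numeric vector of per-channel EMG-sigma (one frame)
#' @param model an `emg_force_model`
#' @param cfg a [controller_config()]
#' @param plant a [plant_spec()]
#' @return named velocity command `c(hand_mm_s =, wrist_deg_s =)`
#' @export
regression_controller_step <- function(sigma_frame, model,
                                       cfg = controller_config(),
                                       plant = plant_spec()) {
  f <- predict(model, sigma_frame)
  f <- c(hand = unname(f[1, "hand"]), wrist = unname(f[1, "wrist"]))
  force_to_velocity(condition_force(f, cfg), cfg, plant)
}

#' Run the regression controller over a full sigma series
#'
#' Batch equivalent of [regression_controller_step()]: predicts force for
#' every frame, applies thresholds and gate, maps to velocity, and returns
#' the per-frame log.
#'
#' @param sigma a [sigma_series()]
#' @param model an `emg_force_model`
#' @param cfg a [controller_config()]
#' @param plant a [plant_spec()]
#' @return data frame with `t_s`, raw force (`hand_pct`, `wrist_pct`),
#'   gated force (`hand_gated_pct`, `wrist_gated_pct`) and velocity commands
#'   (`hand_mm_s`, `wrist_deg_s`)
#' @export
run_regression_controller <- function(sigma, model,
                                      cfg = controller_config(),
                                      plant = plant_spec()) {
  stopifnot(inherits(sigma, "sigma_series"))
  f <- predict(model, sigma)
  n <- nrow(f)
  gated <- matrix(0, n, 2, dimnames = list(NULL, c("hand", "wrist")))
  vel <- matrix(0, n, 2, dimnames = list(NULL, c("hand_mm_s", "wrist_deg_s")))
  for (i in seq_len(n)) {
    g <- condition_force(c(hand = unname(f[i, 1]), wrist = unname(f[i, 2])), cfg)
    gated[i, ] <- g
    vel[i, ] <- force_to_velocity(g, cfg, plant)
  }
  data.frame(t_s = (seq_len(n) - 1) / sigma$fs_hz,
             hand_pct = f[, 1], wrist_pct = f[, 2],
             hand_gated_pct = gated[, 1], wrist_gated_pct = gated[, 2],
             hand_mm_s = vel[, 1], wrist_deg_s = vel[, 2])
}
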