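#' Virtual hand-wrist prosthesis specification
#'
#' Kinematic limits modeled on the commercial hardware the controllers
#' drive: a gripper with 8-200 mm/s proportional aperture speed and a wrist
#' rotator with 28 rpm maximum speed, sampled by a 100 Hz control loop. The
#' 0-100 mm aperture travel is a configurable default (the gripper's travel
#' is not part of its published speed rating).
#'
#' @param hand_speed_min_mm_s minimum proportional aperture speed
#' @param hand_speed_max_mm_s maximum aperture speed
#' @param aperture_min_mm,aperture_max_mm aperture travel limits
#' @param wrist_speed_max_rpm maximum wrist rotation speed (28 rpm = 168
#'   deg/s)
#' @param loop_hz control-loop rate
#' @return an object of class `plant_spec`
#' @export
plant_spec <- function(hand_speed_min_mm_s = 8, hand_speed_max_mm_s = 200,
                       aperture_min_mm = 0, aperture_max_mm = 100,
                       wrist_speed_max_rpm = 28, loop_hz = 100) {
  stopifnot(hand_speed_min_mm_s > 0,
            hand_speed_min_mm_s < hand_speed_max_mm_s,
            aperture_min_mm < aperture_max_mm,
            wrist_speed_max_rpm > 0, loop_hz > 0)
  structure(list(hand_speed_min_mm_s = hand_speed_min_mm_s,
                 hand_speed_max_mm_s = hand_speed_max_mm_s,
                 aperture_min_mm = aperture_min_mm,
                 aperture_max_mm = aperture_max_mm,
                 wrist_speed_max_rpm = wrist_speed_max_rpm,
                 loop_hz = loop_hz),
            class = "plant_spec")
}

#' @rdname plant_spec
#' @param plant a `plant_spec`
#' @export
wrist_speed_max_deg_s <- function(plant) plant$wrist_speed_max_rpm * 6

#' Virtual prosthesis state
#'
#' @param aperture_mm gripper aperture; defaults to fully open
#' @param wrist_angle_deg cumulative wrist rotation (+ = pronation),
#'   unbounded
#' @param t_s elapsed time
#' @param plant a [plant_spec()] (for the default aperture)
#' @return an object of class `plant_state`
#' @export
plant_state <- function(aperture_mm = plant$aperture_max_mm,
                        wrist_angle_deg = 0, t_s = 0,
                        plant = plant_spec()) {
  stopifnot(aperture_mm >= plant$aperture_min_mm,
            aperture_mm <= plant$aperture_max_mm)
  structure(list(aperture_mm = aperture_mm,
                 wrist_angle_deg = wrist_angle_deg, t_s = t_s),
            class = "plant_state")
}

#' Advance the virtual prosthesis by one control frame
#'
#' Forward-Euler integration at `dt = 1/loop_hz`. The aperture is clamped at
#' its travel limits (command absorbed at the stop); the wrist angle is the
#' exact discrete integral of commanded rates, unclamped. A positive hand
#' command opens the gripper.
#'
#' @param state a [plant_state()]
#' @param cmd named numeric `c(hand_mm_s =, wrist_deg_s =)`
#' @param plant a [plant_spec()]
#' @return the updated `plant_state`
#' @export
plant_step <- function(state, cmd, plant = plant_spec()) {
  dt <- 1 / plant$loop_hz
  ap <- state$aperture_mm + cmd[["hand_mm_s"]] * dt
  state$aperture_mm <- min(max(ap, plant$aperture_min_mm), plant$aperture_max_mm)
  state$wrist_angle_deg <- state$wrist_angle_deg + cmd[["wrist_deg_s"]] * dt
  state$t_s <- state$t_s + dt
  state
}

#' Integrate a velocity-command log into a plant trajectory
#'
#' @param commands data frame with `hand_mm_s` and `wrist_deg_s` columns
#'   (e.g. from [run_regression_controller()] or [run_seqcon()])
#' @param state initial [plant_state()]
#' @param plant a [plant_spec()]
#' @return data frame `t_s`, `aperture_mm`, `wrist_angle_deg`, one row per
#'   frame (state after that frame's command)
#' @export
plant_run <- function(commands, state = plant_state(plant = plant),
                      plant = plant_spec()) {
  n <- nrow(commands)
  out <- data.frame(t_s = numeric(n), aperture_mm = numeric(n),
                    wrist_angle_deg = numeric(n))
  for (i in seq_len(n)) {
    state <- plant_step(state, c(hand_mm_s = commands$hand_mm_s[i],
                                 wrist_deg_s = commands$wrist_deg_s[i]), plant)
    out$t_s[i] <- state$t_s
    out$aperture_mm[i] <- state$aperture_mm
    out$wrist_angle_deg[i] <- state$wrist_angle_deg
  }
  out
}
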