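#' @keywords internal
dircon_sequence <- c("Rest", "Cls", "Opn", "Sup", "Pro",
                     "Cls+Sup", "Cls+Pro", "Opn+Sup", "Opn+Pro")

#' @keywords internal
mapcon_sequence <- c("Rest", "Flx", "Ext", "Uln", "Rad",
                     "Flx+Uln", "Flx+Rad", "Ext+Uln", "Ext+Rad")

# Signed DoF contribution of a single direction token.
# Hand: Opn/Ext = +, Cls/Flx = -.  Wrist: Pro/Rad = +, Sup/Uln = -.
direction_sign <- list(
  Opn = c(hand = 1, wrist = 0), Cls = c(hand = -1, wrist = 0),
  Pro = c(hand = 0, wrist = 1), Sup = c(hand = 0, wrist = -1),
  Ext = c(hand = 1, wrist = 0), Flx = c(hand = -1, wrist = 0),
  Rad = c(hand = 0, wrist = 1), Uln = c(hand = 0, wrist = -1))

# Canonical 4-direction (open, close, pro, sup) activation of a label;
# for MapCon labels the mapped prosthesis direction is used (Ext -> open,
# Flx -> close, Rad -> pro, Uln -> sup).
direction_columns <- list(
  Opn = "open", Ext = "open", Cls = "close", Flx = "close",
  Pro = "pro", Rad = "pro", Sup = "sup", Uln = "sup")

#' Build the 90 s calibration schedule for a control strategy
#'
#' Nine contiguous 10 s constant-posture constant-force segments: rest first,
#' then four 1-DoF and four 2-DoF contractions in the strategy's fixed order
#' (DirCon: Cls, Opn, Sup, Pro, Cls+Sup, Cls+Pro, Opn+Sup, Opn+Pro; MapCon:
#' Flx, Ext, Uln, Rad, Flx+Uln, Flx+Rad, Ext+Uln, Ext+Rad).
#'
#' @param strategy `"DirCon"` or `"MapCon"` (case-insensitive)
#' @return a data frame of class `calibration_schedule` with columns `type`,
#'   `start_s`, `duration_s` and attribute `strategy`
#' @export
build_schedule <- function(strategy = c("DirCon", "MapCon")) {
  if (is.character(strategy) && length(strategy) == 1) {
    idx <- match(tolower(strategy), c("dircon", "mapcon"))
    if (is.na(idx))
      stop(sprintf("unknown control strategy '%s' (expected DirCon or MapCon)",
                   strategy), call. = FALSE)
    strategy <- c("DirCon", "MapCon")[idx]
  } else strategy <- match.arg(strategy)
  types <- if (strategy == "DirCon") dircon_sequence else mapcon_sequence
  sched <- data.frame(type = types,
                      start_s = seq(0, 80, by = 10),
                      duration_s = rep(10, 9),
                      stringsAsFactors = FALSE)
  attr(sched, "strategy") <- strategy
  class(sched) <- c("calibration_schedule", "data.frame")
  sched
}

#' Signed 2-DoF force target of a calibration contraction type
#'
#' Active directions map to plus/minus `effort_pct` under the sign
#' convention (hand: Opn/Ext positive, Cls/Flx negative; wrist: Pro/Rad
#' positive, Sup/Uln negative); the unused DoF is assigned a target of zero.
#'
#' @param type contraction label, e.g. `"Rest"`, `"Cls"`, `"Opn+Sup"`
#' @param effort_pct target effort in %MVC (default 30)
#' @return named numeric vector `c(hand =, wrist =)` in %MVC
#' @export
targets_for <- function(type, effort_pct = 30) {
  out <- c(hand = 0, wrist = 0)
  if (identical(type, "Rest")) return(out)
  for (tok in strsplit(type, "+", fixed = TRUE)[[1]]) {
    s <- direction_sign[[tok]]
    if (is.null(s))
      stop(sprintf("unknown contraction direction '%s' in type '%s'", tok, type),
           call. = FALSE)
    out <- out + s * effort_pct
  }
  out
}

# Four-direction (open, close, pro, sup) nonnegative activation of a label.
active_directions <- function(type) {
  out <- c(open = 0, close = 0, pro = 0, sup = 0)
  if (identical(type, "Rest")) return(out)
  for (tok in strsplit(type, "+", fixed = TRUE)[[1]]) {
    col <- direction_columns[[tok]]
    if (is.null(col))
      stop(sprintf("unknown contraction direction '%s'", tok), call. = FALSE)
    out[col] <- 1
  }
  out
}

#' @export
print.calibration_schedule <- function(x, ...) {
  cat(sprintf("%s calibration schedule: %d segments, %g s total\n",
              attr(x, "strategy"), nrow(x), sum(x$duration_s)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
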