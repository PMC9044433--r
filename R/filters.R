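#' Specification of the EMG amplitude-estimation filter cascade
#'
#' Parameters for the five-stage causal cascade that turns raw surface EMG
#' into the 100 Hz EMG-sigma amplitude estimate: power-line notch, motion
#' artifact highpass, full-wave rectification (parameter free), Chebyshev
#' Type I lowpass demodulator, decimation, and a critically damped smoother
#' running at the decimated rate.
#'
#' Defaults: 60 Hz notch with 1 Hz (-3 dB) bandwidth, second-order IIR;
#' 15 Hz fifth-order Butterworth highpass; 16 Hz ninth-order Chebyshev
#' Type I lowpass with 0.05 dB peak-to-peak passband ripple; decimation by
#' 20 (2000 Hz to 100 Hz); 1 Hz second-order critically damped smoother.
#'
#' @param notch_hz notch center frequency, Hz
#' @param notch_bw_hz notch -3 dB bandwidth, Hz
#' @param hp_fc_hz,hp_order highpass cutoff (Hz) and order
#' @param lp_fc_hz,lp_order,lp_ripple_db Chebyshev Type I lowpass cutoff
#'   (Hz), order, and peak-to-peak passband ripple (dB)
#' @param decim_factor integer downsampling ratio
#' @param smooth_fc_hz,smooth_order critically damped smoother -3 dB cutoff
#'   (Hz) and order (realized as `smooth_order` identical first-order
#'   sections sharing one real pole)
#' @return an object of class `filter_spec`
#' @seealso [design_filter_bank()]
#' @export
filter_spec <- function(notch_hz = 60, notch_bw_hz = 1,
                        hp_fc_hz = 15, hp_order = 5,
                        lp_fc_hz = 16, lp_order = 9, lp_ripple_db = 0.05,
                        decim_factor = 20,
                        smooth_fc_hz = 1, smooth_order = 2) {
  spec <- list(notch_hz = notch_hz, notch_bw_hz = notch_bw_hz,
               hp_fc_hz = hp_fc_hz, hp_order = as.integer(hp_order),
               lp_fc_hz = lp_fc_hz, lp_order = as.integer(lp_order),
               lp_ripple_db = lp_ripple_db,
               decim_factor = as.integer(decim_factor),
               smooth_fc_hz = smooth_fc_hz,
               smooth_order = as.integer(smooth_order))
  stopifnot(notch_hz > 0, notch_bw_hz > 0, hp_fc_hz > 0, spec$hp_order >= 1,
            lp_fc_hz > 0, spec$lp_order >= 1, lp_ripple_db > 0,
            spec$decim_factor >= 1, smooth_fc_hz > 0, spec$smooth_order >= 1)
  class(spec) <- "filter_spec"
  spec
}

# ---- stage designs ---------------------------------------------------------
# Every recursive stage is realized as a cascade of first/second-order
# sections designed directly in zero-pole-gain form. High-order narrowband
# IIR filters (the 9th-order Chebyshev at fc/fs = 0.008 especially) are
# numerically unstable when expanded into a single transfer-function
# polynomial; second-order sections keep every pole well conditioned.

# Second-order IIR notch (biquad) with an exact unit-circle zero at f0 and
# -3 dB bandwidth bw.
design_notch <- function(f0, bw, fs) {
  w0 <- 2 * pi * f0 / fs
  beta <- tan(pi * bw / fs)
  gain <- 1 / (1 + beta)
  list(list(b = gain * c(1, -2 * cos(w0), 1),
            a = c(1, -2 * gain * cos(w0), 2 * gain - 1)))
}

# Bilinear transform (s = (z-1)/(z+1)) of analog poles, paired into
# second-order sections. `zero` is the digital zero location shared by all
# sections (-1 for lowpass, +1 for highpass); `ref_z` is the point on the
# unit circle where each section is normalized to the given gain.
sos_from_poles <- function(p_analog, zero, ref_z, ref_gain = 1) {
  p <- (1 + p_analog) / (1 - p_analog)
  real_p <- p[abs(Im(p)) < 1e-12]
  cplx_p <- p[Im(p) > 1e-12]  # one of each conjugate pair
  sections <- list()
  for (pp in cplx_p) {
    a <- c(1, -2 * Re(pp), Mod(pp)^2)
    b <- c(1, -2 * zero, zero^2)
    g <- ref_gain * abs(sum(a * ref_z^-(0:2)) / sum(b * ref_z^-(0:2)))
    sections[[length(sections) + 1]] <- list(b = g * b, a = a)
  }
  for (pp in real_p) {
    a <- c(1, -Re(pp))
    b <- c(1, -zero)
    g <- ref_gain * abs(sum(a * ref_z^-(0:1)) / sum(b * ref_z^-(0:1)))
    sections[[length(sections) + 1]] <- list(b = g * b, a = a)
  }
  sections
}

# Butterworth analog prototype poles (unit cutoff, left half plane).
butter_proto <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Chebyshev Type I analog prototype poles for passband ripple rp dB.
cheby1_proto <- function(n, rp) {
  eps <- sqrt(10^(rp / 10) - 1)
  mu <- asinh(1 / eps) / n
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
}

design_butter_hp <- function(n, fc, fs) {
  wc <- tan(pi * fc / fs)
  p <- wc / butter_proto(n)       # lowpass-to-highpass transform
  sos_from_poles(p, zero = 1, ref_z = -1 + 0i, ref_gain = 1)
}

design_cheby1_lp <- function(n, rp, fc, fs) {
  wc <- tan(pi * fc / fs)
  p <- wc * cheby1_proto(n, rp)
  # odd order: DC gain 1; even order: DC sits at the ripple trough
  dc <- if (n %% 2 == 1) 1 else 10^(-rp / 20)
  s <- sos_from_poles(p, zero = -1, ref_z = 1 + 0i, ref_gain = 1)
  s[[1]]$b <- s[[1]]$b * dc
  s
}

# Critically damped smoother: `order` identical first-order unity-DC-gain
# sections sharing one real pole, placed by bisection so the cascade is
# exactly -3 dB at fc. The repeated real pole gives a step response without
# overshoot, the point of the critically damped family.
design_critically_damped <- function(fc, order, fs) {
  w <- 2 * pi * fc / fs
  mag2_section <- function(p) (1 - p)^2 / (1 - 2 * p * cos(w) + p^2)
  target <- (1 / sqrt(2))^(2 / order)  # per-section squared magnitude at fc
  lo <- 0; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mag2_section(mid) > target) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  lapply(seq_len(order), function(i) list(b = c(1 - p, 0), a = c(1, -p)))
}

stage_poles <- function(stage) {
  unlist(lapply(stage, function(sec) {
    a <- sec$a[seq_len(max(which(sec$a != 0)))]
    if (length(a) <= 1) complex(0) else polyroot(rev(a))
  }))
}

#' Design the realizable filter bank for a sampling rate
#'
#' Instantiates every stage of a [filter_spec()] at the given input rate
#' as cascades of first/second-order sections, and verifies realizability
#' (all cutoffs below the relevant Nyquist) and stability (all recursive
#' poles strictly inside the unit circle). All stages are causal and start
#' from all-zero state.
#'
#' @param spec a [filter_spec()]
#' @param fs_hz input sampling rate, Hz
#' @return an object of class `filter_bank` holding per-stage section
#'   coefficients, the design rate and the decimated output rate
#' @export
design_filter_bank <- function(spec = filter_spec(), fs_hz = 2000) {
  stopifnot(inherits(spec, "filter_spec"), fs_hz > 0)
  nyq <- fs_hz / 2
  fs_out <- fs_hz / spec$decim_factor
  check_fc <- function(fc, nyquist, stage) {
    if (fc >= nyquist)
      stop(sprintf("filter stage '%s': cutoff %g Hz is at or above Nyquist (%g Hz)",
                   stage, fc, nyquist), call. = FALSE)
  }
  check_fc(spec$notch_hz, nyq, "notch")
  check_fc(spec$hp_fc_hz, nyq, "highpass")
  check_fc(spec$lp_fc_hz, nyq, "lowpass")
  check_fc(spec$smooth_fc_hz, fs_out / 2, "smoother")

  stages <- list(
    notch = design_notch(spec$notch_hz, spec$notch_bw_hz, fs_hz),
    highpass = design_butter_hp(spec$hp_order, spec$hp_fc_hz, fs_hz),
    lowpass = design_cheby1_lp(spec$lp_order, spec$lp_ripple_db,
                               spec$lp_fc_hz, fs_hz),
    smoother = design_critically_damped(spec$smooth_fc_hz, spec$smooth_order,
                                        fs_out))
  for (nm in names(stages)) {
    r <- Mod(stage_poles(stages[[nm]]))
    if (length(r) && max(r) >= 1)
      stop(sprintf("filter stage '%s' is unstable (pole radius %.6g)", nm, max(r)),
           call. = FALSE)
  }
  structure(list(stages = stages, fs_hz = fs_hz, fs_out = fs_out,
                 decim_factor = spec$decim_factor, spec = spec),
            class = "filter_bank")
}

#' Complex frequency response of a filter-bank stage
#'
#' Evaluates the transfer function of one stage of a [design_filter_bank()]
#' (the product over its cascaded sections) on a grid of physical
#' frequencies. The smoother runs at the decimated rate; all other stages
#' at the input rate.
#'
#' @param bank a `filter_bank`
#' @param f frequencies in Hz
#' @param stage one of `"notch"`, `"highpass"`, `"lowpass"`, `"smoother"`
#' @return complex vector of H(f)
#' @export
filter_bank_response <- function(bank, f, stage = "notch") {
  stopifnot(inherits(bank, "filter_bank"))
  stage <- match.arg(stage, names(bank$stages))
  st <- bank$stages[[stage]]
  fs <- if (stage == "smoother") bank$fs_out else bank$fs_hz
  vapply(f, function(fi) {
    z <- exp(1i * 2 * pi * fi / fs)
    h <- 1 + 0i
    for (sec in st) {
      zb <- z^-(seq_along(sec$b) - 1)
      za <- z^-(seq_along(sec$a) - 1)
      h <- h * sum(sec$b * zb) / sum(sec$a * za)
    }
    h
  }, complex(1))
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("EMG-sigma filter cascade specification\n")
  cat(sprintf("  notch:    %g Hz, -3 dB bandwidth %g Hz (2nd-order IIR biquad)\n",
              x$notch_hz, x$notch_bw_hz))
  cat(sprintf("  highpass: %g Hz, order %d Butterworth\n", x$hp_fc_hz, x$hp_order))
  cat(sprintf("  lowpass:  %g Hz, order %d Chebyshev I, %g dB ripple\n",
              x$lp_fc_hz, x$lp_order, x$lp_ripple_db))
  cat(sprintf("  decimate: by %d\n", x$decim_factor))
  cat(sprintf("  smoother: %g Hz, order %d critically damped\n",
              x$smooth_fc_hz, x$smooth_order))
  invisible(x)
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("EMG-sigma filter bank: %g Hz in, %g Hz out (decimate by %d)\n",
              x$fs_hz, x$fs_out, x$decim_factor))
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %d section(s)\n", nm, length(x$stages[[nm]])))
  invisible(x)
}
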