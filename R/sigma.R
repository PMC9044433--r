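#' Multichannel raw surface EMG recording
#'
#' Container for raw EMG sampled at a common rate (rows = samples, columns =
#' channels). Values must be finite; at least two channels are required (a
#' single-site recording cannot drive either controller family).
#'
#' @param samples numeric matrix, rows = time samples, cols = channels
#' @param fs_hz sampling rate in Hz
#' @param channel_names optional character vector of channel labels; defaults
#'   to `ch01, ch02, ...`
#' @return an object of class `raw_emg`
#' @export
raw_emg <- function(samples, fs_hz = 2000, channel_names = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("raw EMG samples must be numeric", call. = FALSE)
  if (ncol(samples) < 2)
    stop("raw EMG requires at least 2 channels", call. = FALSE)
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite raw EMG value at sample %d, channel %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a positive scalar", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(ncol(samples)))
  stopifnot(length(channel_names) == ncol(samples))
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel_names = channel_names),
            class = "raw_emg")
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("raw EMG: %d samples x %d channels at %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              nrow(x$samples) / x$fs_hz))
  invisible(x)
}

#' Per-channel EMG-sigma amplitude series at the decimated rate
#'
#' @param sigma numeric matrix (rows = frames, cols = channels), nonnegative
#' @param fs_hz frame rate, Hz (100 by default)
#' @param channel_names optional labels
#' @return an object of class `sigma_series`
#' @export
sigma_series <- function(sigma, fs_hz = 100, channel_names = NULL) {
  sigma <- as.matrix(sigma)
  stopifnot(is.numeric(sigma), all(is.finite(sigma)), all(sigma >= 0), fs_hz > 0)
  if (is.null(channel_names))
    channel_names <- colnames(sigma)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(ncol(sigma)))
  colnames(sigma) <- channel_names
  structure(list(sigma = sigma, fs_hz = fs_hz, channel_names = channel_names),
            class = "sigma_series")
}

#' @export
print.sigma_series <- function(x, ...) {
  cat(sprintf("EMG-sigma series: %d frames x %d channels at %g Hz (%.2f s)\n",
              nrow(x$sigma), ncol(x$sigma), x$fs_hz, nrow(x$sigma) / x$fs_hz))
  invisible(x)
}

# Run one cascade stage (a list of first/second-order sections) over a
# signal, threading per-section filter state. zi is a list of state
# vectors, one per section; NULL means cold start.
run_stage <- function(stage, x, zi = NULL) {
  if (is.null(zi))
    zi <- lapply(stage, function(sec)
      numeric(max(length(sec$b), length(sec$a)) - 1))
  zf <- vector("list", length(stage))
  for (s in seq_along(stage)) {
    r <- df2t_filter(stage[[s]]$b, stage[[s]]$a, x, zi[[s]])
    x <- r$y
    zf[[s]] <- r$zf
  }
  list(y = x, zf = zf)
}

#' Batch EMG-sigma estimation
#'
#' Applies the causal cascade notch -> highpass -> full-wave rectification ->
#' Chebyshev lowpass -> decimation -> critically damped smoother to every
#' channel independently, from all-zero initial filter state (cold start; the
#' calibration trimming absorbs the startup transient). Output frames are
#' taken every `decim_factor`-th input sample, so the output length is
#' `floor(nrow / decim_factor)`. Negative smoother undershoot is clamped to
#' zero, EMG-sigma being an amplitude estimate.
#'
#' @param raw a [raw_emg()] recording
#' @param bank a [design_filter_bank()] designed at `raw$fs_hz`
#' @return a [sigma_series()] at `bank$fs_out`
#' @export
process_batch <- function(raw, bank = design_filter_bank(fs_hz = raw$fs_hz)) {
  stopifnot(inherits(raw, "raw_emg"), inherits(bank, "filter_bank"))
  if (!isTRUE(all.equal(raw$fs_hz, bank$fs_hz)))
    stop(sprintf("raw EMG rate %g Hz does not match filter bank design rate %g Hz",
                 raw$fs_hz, bank$fs_hz), call. = FALSE)
  d <- bank$decim_factor
  n_out <- floor(nrow(raw$samples) / d)
  out <- matrix(0, n_out, ncol(raw$samples))
  for (ch in seq_len(ncol(raw$samples))) {
    x <- raw$samples[, ch]
    x <- run_stage(bank$stages$notch, x)$y
    x <- run_stage(bank$stages$highpass, x)$y
    x <- abs(x)
    x <- run_stage(bank$stages$lowpass, x)$y
    x <- x[seq_len(n_out) * d]
    x <- run_stage(bank$stages$smoother, x)$y
    out[, ch] <- pmax(x, 0)
  }
  sigma_series(out, fs_hz = bank$fs_out, channel_names = raw$channel_names)
}

#' Streaming EMG-sigma estimation state
#'
#' Creates the per-channel filter state for sample-by-sample processing with
#' [process_step()]. Streaming output is bit-identical to [process_batch()]
#' on the concatenated input: both paths run the same transposed direct-form
#' II kernel in the same order.
#'
#' @param bank a `filter_bank`
#' @param n_channels number of channels the stream will carry
#' @return an object of class `emg_stream_state`
#' @export
emg_stream_state <- function(bank, n_channels) {
  stopifnot(inherits(bank, "filter_bank"), n_channels >= 1)
  mk <- function(stage) lapply(seq_len(n_channels), function(ch)
    lapply(stage, function(sec)
      numeric(max(length(sec$b), length(sec$a)) - 1)))
  structure(list(bank = bank, n_channels = n_channels,
                 z_notch = mk(bank$stages$notch),
                 z_hp = mk(bank$stages$highpass),
                 z_lp = mk(bank$stages$lowpass),
                 z_sm = mk(bank$stages$smoother),
                 count = 0L),
            class = "emg_stream_state")
}

#' Advance the streaming EMG-sigma estimator by one raw sample
#'
#' Feeds one multichannel raw frame through the cascade. A sigma frame is
#' emitted once every `decim_factor` input samples (so the first emission
#' happens after `decim_factor` samples have been consumed); otherwise
#' `sigma` is `NULL`.
#'
#' @param frame numeric vector, one raw sample per channel
#' @param state an [emg_stream_state()]
#' @return list with `sigma` (numeric vector or `NULL`) and the updated
#'   `state`
#' @export
process_step <- function(frame, state) {
  stopifnot(inherits(state, "emg_stream_state"))
  if (length(frame) != state$n_channels)
    stop(sprintf("frame has %d channels but stream state was created for %d",
                 length(frame), state$n_channels), call. = FALSE)
  bank <- state$bank
  state$count <- state$count + 1L
  emit <- state$count %% bank$decim_factor == 0L
  sig <- if (emit) numeric(state$n_channels) else NULL
  for (ch in seq_len(state$n_channels)) {
    r <- run_stage(bank$stages$notch, frame[ch], state$z_notch[[ch]])
    state$z_notch[[ch]] <- r$zf
    r <- run_stage(bank$stages$highpass, r$y, state$z_hp[[ch]])
    state$z_hp[[ch]] <- r$zf
    r <- run_stage(bank$stages$lowpass, abs(r$y), state$z_lp[[ch]])
    state$z_lp[[ch]] <- r$zf
    if (emit) {
      s <- run_stage(bank$stages$smoother, r$y, state$z_sm[[ch]])
      state$z_sm[[ch]] <- s$zf
      sig[ch] <- max(s$y, 0)
    }
  }
  list(sigma = sig, state = state)
}
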