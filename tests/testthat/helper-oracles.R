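# Independent reference implementations used as test oracles. These must
# stay separate from the package's own code paths: the filter oracle is a
# direct-form I recursion in plain R, the pseudo-inverse oracle goes through
# the eigendecomposition of the normal matrix, and the toggle oracle is a
# literal per-frame counter.

# Direct-form I recursion (zero initial conditions), one section.
ref_filter_df1 <- function(b, a, x) {
  nb <- length(b); na <- length(a)
  n <- length(x)
  xp <- c(rep(0, nb - 1), x)
  yp <- c(rep(0, na - 1), numeric(n))
  for (i in seq_len(n)) {
    acc <- sum(b * xp[(i + nb - 1):i])
    if (na > 1) acc <- acc - sum(a[-1] * yp[(i + na - 2):i])
    yp[i + na - 1] <- acc
  }
  yp[-seq_len(na - 1)]
}

ref_run_stage <- function(stage, x) {
  for (sec in stage) x <- ref_filter_df1(sec$b, sec$a, x)
  x
}

# Full amplitude-estimation chain for one channel, by direct recursion.
ref_sigma_chain <- function(x, bank) {
  y <- ref_run_stage(bank$stages$notch, x)
  y <- ref_run_stage(bank$stages$highpass, y)
  y <- abs(y)
  y <- ref_run_stage(bank$stages$lowpass, y)
  y <- y[seq_len(floor(length(y) / bank$decim_factor)) * bank$decim_factor]
  y <- ref_run_stage(bank$stages$smoother, y)
  pmax(y, 0)
}

# Truncated pseudo-inverse through the eigendecomposition of X'X, with the
# same retention rule (sqrt(lambda_i)/sqrt(lambda_max) >= tol).
ref_pinv_coef <- function(X, Y, tol) {
  E <- eigen(crossprod(X), symmetric = TRUE)
  d <- sqrt(pmax(E$values, 0))
  keep <- d / max(d) >= tol
  V <- E$vectors[, keep, drop = FALSE]
  V %*% ((t(V) %*% crossprod(X, Y)) / E$values[keep])
}

# Literal per-frame co-contraction toggle counter: the timer accumulates
# over consecutive frames where both channels are supra-threshold, a toggle
# fires when it reaches the window, and detection is disabled while the
# refractory countdown runs.
ref_toggle_count <- function(above, window_frames, refractory_frames) {
  elapsed <- 0L; refr <- 0L; count <- 0L
  for (a in above) {
    if (refr > 0L) { refr <- refr - 1L; elapsed <- 0L; next }
    if (a) {
      elapsed <- elapsed + 1L
      if (elapsed >= window_frames) {
        count <- count + 1L
        elapsed <- 0L
        refr <- refractory_frames
      }
    } else elapsed <- 0L
  }
  count
}

# Session cache: full-length synthetic sessions are the expensive fixture,
# so tests sharing one build it once per run.
.session_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- fn()
  .session_cache[[key]]
}

# Small quick session (8 channels, 18 s) for unit tests.
small_session <- function(strategy = "DirCon", seed = 9, jitter = 0.1) {
  key <- sprintf("small_%s_%d_%g", strategy, seed, jitter)
  cached(key, function() {
    ses <- simulate_session(strategy, n_channels = 8, seed = seed,
                            session = session_spec(seed, effort_jitter_rel = jitter,
                                                   ramp_s = 0.2),
                            duration_scale = 0.2)
    ses$sigma <- process_batch(ses$raw)
    ses$fitspec <- fit_spec(trim_s = 0.2)
    ses
  })
}

# Full-length default session shared by the acceptance-style checks.
full_session <- function(seed = 42, jitter = 0.1) {
  key <- sprintf("full_%d_%g", seed, jitter)
  cached(key, function() {
    ses <- simulate_session("DirCon", n_channels = 16, seed = seed,
                            session = session_spec(seed, effort_jitter_rel = jitter))
    ses$sigma <- process_batch(ses$raw)
    ses
  })
}

# Frame indices retained after trimming (one copy of each segment).
retained_frames <- function(schedule, trim_s = 1, fs = 100) {
  idx <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    s <- round(schedule$start_s[i] * fs)
    n <- round(schedule$duration_s[i] * fs)
    tr <- round(trim_s * fs)
    idx <- c(idx, s + seq(tr + 1, n - tr))
  }
  idx
}

# Hand-built design_data for direct tests of the solver.
manual_design <- function(X, Y, spec = fit_spec(bias = FALSE),
                          labels = rep("Cls", nrow(X))) {
  if (spec$bias) X <- cbind(X, `(bias)` = 1)
  structure(list(X = X, Y = Y, row_labels = labels,
                 replica = rep(FALSE, nrow(X)),
                 channels = seq_len(ncol(X) - spec$bias),
                 channel_names = sprintf("ch%02d", seq_len(ncol(X) - spec$bias)),
                 strategy = "DirCon", schedule = NULL, spec = spec),
            class = "design_data")
}
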