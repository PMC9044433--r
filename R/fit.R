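#' Calibration fitting specification
#'
#' @param tol singular-value truncation ratio: singular values whose ratio to
#'   the largest is below `tol` are removed from the pseudo-inverse
#'   (default 0.01)
#' @param rest_weight integer replication of the single rest contraction in
#'   the design (default 8), balancing rest against the eight active
#'   contractions without lengthening the recording
#' @param effort_pct per-direction target effort in %MVC (default 30)
#' @param trim_s duration removed from both ends of every 10 s segment to
#'   avoid filter and movement transients (default 1)
#' @param bias include a constant-1 regressor to absorb the EMG-sigma noise
#'   floor (default `TRUE`)
#' @return an object of class `fit_spec`
#' @export
fit_spec <- function(tol = 0.01, rest_weight = 8, effort_pct = 30,
                     trim_s = 1, bias = TRUE) {
  stopifnot(tol > 0, tol < 1, rest_weight >= 1,
            effort_pct > 0, effort_pct <= 100, trim_s >= 0,
            is.logical(bias), length(bias) == 1)
  structure(list(tol = tol, rest_weight = as.integer(rest_weight),
                 effort_pct = effort_pct, trim_s = trim_s, bias = bias),
            class = "fit_spec")
}

#' Assemble the regression design from a calibration recording
#'
#' Trims `trim_s` from both ends of every segment on the sigma frame grid,
#' replicates the rest block `rest_weight` times, and pairs each retained
#' frame with its signed force target (active directions at plus/minus
#' `effort_pct`, zero for the unused DoF). With defaults each active segment
#' contributes 800 rows and rest 6400.
#'
#' @param sigma a [sigma_series()] covering the full schedule
#' @param schedule a [build_schedule()] result
#' @param spec a [fit_spec()]
#' @return an object of class `design_data` with elements `X` (frames x
#'   channels, plus a trailing bias column when enabled), `Y` (frames x 2
#'   signed %MVC), `row_labels`, `replica` (marks rest replica rows),
#'   `channels`, `channel_names`, `strategy`, `spec`
#' @export
assemble_design <- function(sigma, schedule, spec = fit_spec()) {
  stopifnot(inherits(sigma, "sigma_series"),
            inherits(schedule, "calibration_schedule"),
            inherits(spec, "fit_spec"))
  fs <- sigma$fs_hz
  need <- sum(schedule$duration_s) * fs
  if (nrow(sigma$sigma) < need)
    stop(sprintf("sigma series covers %.2f s but the schedule needs %.2f s (%.2f s missing)",
                 nrow(sigma$sigma) / fs, need / fs,
                 (need - nrow(sigma$sigma)) / fs), call. = FALSE)
  if (2 * spec$trim_s >= min(schedule$duration_s))
    stop("trim_s removes entire segments", call. = FALSE)
  trim_n <- round(spec$trim_s * fs)
  rows <- list(); labs <- list(); targ <- list(); repl <- list()
  for (i in seq_len(nrow(schedule))) {
    seg_len <- round(schedule$duration_s[i] * fs)
    idx <- round(schedule$start_s[i] * fs) + seq_len(seg_len)
    if (trim_n > 0) idx <- idx[(trim_n + 1):(seg_len - trim_n)]
    reps <- if (schedule$type[i] == "Rest") spec$rest_weight else 1L
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- idx
      labs[[length(labs) + 1]] <- rep(schedule$type[i], length(idx))
      repl[[length(repl) + 1]] <- rep(r > 1L, length(idx))
      targ[[length(targ) + 1]] <- matrix(targets_for(schedule$type[i], spec$effort_pct),
                                         length(idx), 2, byrow = TRUE)
    }
  }
  X <- sigma$sigma[unlist(rows), , drop = FALSE]
  if (spec$bias) X <- cbind(X, `(bias)` = 1)
  Y <- do.call(rbind, targ)
  colnames(Y) <- c("hand", "wrist")
  structure(list(X = X, Y = Y,
                 row_labels = unlist(labs), replica = unlist(repl),
                 channels = seq_along(sigma$channel_names),
                 channel_names = sigma$channel_names,
                 strategy = attr(schedule, "strategy"),
                 schedule = schedule, spec = spec),
            class = "design_data")
}

#' @export
print.design_data <- function(x, ...) {
  cat(sprintf("calibration design: %d rows x %d regressors (%d channels%s), %s\n",
              nrow(x$X), ncol(x$X), length(x$channels),
              if (x$spec$bias) " + bias" else "",
              if (is.null(x$strategy)) "" else x$strategy))
  invisible(x)
}

# Truncated-SVD minimum-norm least-squares solve. Retains singular value
# s_i iff s_i / s_max >= tol (strict-less removal).
pinv_solve <- function(X, Y, tol) {
  sv <- svd(X)
  if (max(sv$d) <= 0)
    stop("degenerate design: all singular values are zero", call. = FALSE)
  keep <- sv$d / max(sv$d) >= tol
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% Y) / sv$d[keep])
  list(coef = coef, n_retained = sum(keep), d = sv$d)
}

new_emg_force_model <- function(coef, design, tol, n_retained, d, call = NULL,
                                history = NULL) {
  rn <- c(design$channel_names[design$channels],
          if (design$spec$bias) "(bias)")
  dimnames(coef) <- list(rn, c("hand", "wrist"))
  m <- structure(list(coefficients = coef,
                      channels = design$channels,
                      channel_names = design$channel_names[design$channels],
                      strategy = design$strategy,
                      bias = design$spec$bias,
                      tol_used = tol,
                      n_singular_retained = n_retained,
                      singular_values = d,
                      design = design,
                      selection_history = history,
                      call = call),
                 class = "emg_force_model")
  m$quality <- quality_rmse(m, design)
  m
}

#' Fit the EMG-sigma to force map by truncated pseudo-inverse least squares
#'
#' Solves the 2-output linear least-squares problem `X B ~ Y` through the
#' singular value decomposition of the design matrix, removing every
#' singular value whose ratio to the largest is less than `tol` and taking
#' the minimum-norm solution over the retained directions. This is the
#' regularization that makes the fit usable when circumferential electrodes
#' record highly correlated EMG amplitudes.
#'
#' @param design a [assemble_design()] result
#' @param tol truncation ratio (defaults to the design's `fit_spec`)
#' @return an object of class `emg_force_model`
#' @seealso [emg_force_fit()] for the one-call interface from a sigma series
#' @export
fit_pseudo_inverse <- function(design, tol = design$spec$tol) {
  stopifnot(inherits(design, "design_data"), tol > 0, tol < 1)
  if (nrow(design$X) < 2) stop("design needs at least 2 rows", call. = FALSE)
  if (!all(is.finite(design$X)))
    stop("non-finite entries in design matrix", call. = FALSE)
  s <- pinv_solve(design$X, design$Y, tol)
  new_emg_force_model(s$coef, design, tol, s$n_retained, s$d,
                      call = sys.call())
}

#' Calibrate a 2-DoF EMG-sigma force model from a sigma series
#'
#' One-call calibration: assembles the trimmed, rest-weighted design from
#' the recording and schedule, then fits the truncated pseudo-inverse model.
#'
#' @param sigma a [sigma_series()] covering the 90 s schedule
#' @param schedule a [build_schedule()] result
#' @param spec a [fit_spec()]
#' @return an `emg_force_model` with calibration-quality RMSE report
#' @examples
#' ses <- simulate_session("DirCon", n_channels = 8, seed = 1, duration_scale = 0.2)
#' sig <- process_batch(ses$raw)
#' m <- emg_force_fit(sig, ses$schedule, fit_spec(trim_s = 0.2))
#' m
#' @export
emg_force_fit <- function(sigma, schedule, spec = fit_spec()) {
  design <- assemble_design(sigma, schedule, spec)
  m <- fit_pseudo_inverse(design, spec$tol)
  m$call <- sys.call()
  m
}

#' Calibration-quality RMSE report
#'
#' Root-mean-square error between target and estimated force, pooling
#' squared errors over both DoF outputs. Per-type RMSE counts each unique
#' rest frame once (replicas excluded); the overall RMSE pools all design
#' rows as fitted, replicas included, and is recomputable from the per-row
#' residuals.
#'
#' @param model an `emg_force_model`
#' @param design a `design_data` (defaults to the model's own)
#' @return list with `rmse_by_type` (named, %MVC) and `rmse_overall` (%MVC)
#' @export
quality_rmse <- function(model, design = model$design) {
  res <- design$Y - design$X %*% model$coefficients
  types <- unique(design$row_labels)
  by_type <- vapply(types, function(tp) {
    sel <- design$row_labels == tp & !design$replica
    sqrt(mean(res[sel, ]^2))
  }, numeric(1))
  list(rmse_by_type = by_type, rmse_overall = sqrt(mean(res^2)))
}

drop_design_channel <- function(design, ch) {
  col <- match(ch, design$channels)
  design$X <- design$X[, -col, drop = FALSE]
  design$channels <- design$channels[-col]
  design
}

#' Backward stepwise electrode selection
#'
#' Greedy elimination: at each step the model is refit with each single
#' remaining channel removed, and the channel whose removal yields the
#' lowest overall training RMSE is permanently dropped, until `k` channels
#' remain. Ties are broken by dropping the lowest channel index; the bias
#' column is never a candidate. Selection is on the same assembled design
#' the model was fit to (no hold-out), matching a single-recording
#' calibration workflow.
#'
#' @param model an `emg_force_model` carrying its design
#' @param k target channel count
#' @param tol truncation ratio for the refits (defaults to the model's)
#' @return the refit `emg_force_model` on the selected channels, with a
#'   `selection_history` data frame (one row per elimination step)
#' @export
backward_select <- function(model, k, tol = model$tol_used) {
  stopifnot(inherits(model, "emg_force_model"))
  if (is.null(model$design))
    stop("model carries no design data (was it read from file?); refit first",
         call. = FALSE)
  design <- model$design
  if (k < 1 || k > length(design$channels))
    stop(sprintf("k = %d outside 1..%d available channels",
                 k, length(design$channels)), call. = FALSE)
  hist <- data.frame(step = integer(), dropped_channel = integer(),
                     rmse_after = numeric())
  while (length(design$channels) > k) {
    rmses <- vapply(design$channels, function(ch) {
      d2 <- drop_design_channel(design, ch)
      s <- pinv_solve(d2$X, d2$Y, tol)
      sqrt(mean((d2$Y - d2$X %*% s$coef)^2))
    }, numeric(1))
    drop_ch <- design$channels[which.min(rmses)]  # first = lowest index on ties
    design <- drop_design_channel(design, drop_ch)
    hist <- rbind(hist, data.frame(step = nrow(hist) + 1L,
                                   dropped_channel = drop_ch,
                                   rmse_after = min(rmses)))
  }
  s <- pinv_solve(design$X, design$Y, tol)
  new_emg_force_model(s$coef, design, tol, s$n_retained, s$d,
                      call = sys.call(), history = hist)
}

#' Predict 2-DoF force from EMG-sigma
#'
#' Linear map using only the model's selected channels (plus bias if
#' fitted), per frame, suitable for the 100 Hz control loop.
#'
#' @param object an `emg_force_model`
#' @param newdata a [sigma_series()], or a numeric matrix/vector of sigma
#'   values whose columns cover the model's channels. Columns are matched by
#'   channel name when available, otherwise by position index.
#' @param ... unused
#' @return matrix (frames x 2) of signed forces in %MVC, columns `hand`
#'   (+ = open) and `wrist` (+ = pronation)
#' @export
predict.emg_force_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  if (inherits(newdata, "sigma_series")) newdata <- newdata$sigma
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (!is.null(colnames(newdata))) {
    col <- match(object$channel_names, colnames(newdata))
    if (anyNA(col))
      stop(sprintf("sigma input is missing model channel(s): %s",
                   paste(object$channel_names[is.na(col)], collapse = ", ")),
           call. = FALSE)
  } else {
    col <- object$channels
    if (max(col) > ncol(newdata))
      stop(sprintf("sigma input has %d columns but model needs channel index %d",
                   ncol(newdata), max(col)), call. = FALSE)
  }
  X <- newdata[, col, drop = FALSE]
  if (object$bias) X <- cbind(X, 1)
  out <- X %*% object$coefficients
  colnames(out) <- c("hand", "wrist")
  out
}

#' @export
fitted.emg_force_model <- function(object, ...)
  object$design$X %*% object$coefficients

#' @export
residuals.emg_force_model <- function(object, ...)
  object$design$Y - fitted(object)

#' @export
coef.emg_force_model <- function(object, ...) object$coefficients

#' @export
print.emg_force_model <- function(x, ...) {
  cat(sprintf("2-DoF EMG-sigma force model (%s)\n",
              if (is.null(x$strategy)) "unknown strategy" else x$strategy))
  cat(sprintf("  channels: %s%s\n", paste(x$channel_names, collapse = ", "),
              if (x$bias) " (+ bias)" else ""))
  cat(sprintf("  singular values retained: %d of %d (Tol = %g)\n",
              x$n_singular_retained, length(x$singular_values), x$tol_used))
  cat(sprintf("  calibration RMSE: %.3f %%MVC overall\n",
              x$quality$rmse_overall))
  invisible(x)
}

#' @export
summary.emg_force_model <- function(object, ...) {
  structure(list(model = object,
                 rmse_by_type = object$quality$rmse_by_type,
                 rmse_overall = object$quality$rmse_overall,
                 history = object$selection_history),
            class = "summary.emg_force_model")
}

#' @export
print.summary.emg_force_model <- function(x, ...) {
  print(x$model)
  cat("\nCalibration-quality RMSE by contraction type (%MVC):\n")
  print(round(x$rmse_by_type, 3))
  if (!is.null(x$history) && nrow(x$history)) {
    cat("\nBackward-selection path (channel dropped, training RMSE after):\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}

#' Plot calibration targets against model-estimated force
#'
#' Two stacked panels (hand, wrist) over the retained calibration frames:
#' dashed target force, solid model estimate.
#'
#' @param x an `emg_force_model`
#' @param ... passed to [matplot()]
#' @export
plot.emg_force_model <- function(x, ...) {
  keep <- !x$design$replica
  fit <- fitted(x)[keep, , drop = FALSE]
  Y <- x$design$Y[keep, , drop = FALSE]
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (j in 1:2) {
    matplot(cbind(Y[, j], fit[, j]), type = "l", lty = c(2, 1),
            col = c("red", "blue"),
            xlab = "retained calibration frame (100 Hz)",
            ylab = sprintf("%s force (%%MVC)", colnames(Y)[j]), ...)
    legend("topright", c("target", "estimated"), lty = c(2, 1),
           col = c("red", "blue"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
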