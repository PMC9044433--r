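test_that("calibration schedules reproduce the printed contraction sequences", {
  d <- build_schedule("DirCon")
  expect_equal(d$type, c("Rest", "Cls", "Opn", "Sup", "Pro",
                         "Cls+Sup", "Cls+Pro", "Opn+Sup", "Opn+Pro"))
  m <- build_schedule("mapcon")
  expect_equal(m$type, c("Rest", "Flx", "Ext", "Uln", "Rad",
                         "Flx+Uln", "Flx+Rad", "Ext+Uln", "Ext+Rad"))
  for (s in list(d, m)) {
    expect_equal(nrow(s), 9)
    expect_equal(s$duration_s, rep(10, 9))
    expect_equal(sum(s$duration_s), 90)
    expect_equal(s$start_s, seq(0, 80, by = 10))  # contiguous
  }
  expect_error(build_schedule("SeqCon"), "unknown control strategy")
})

test_that("force targets follow the sign convention with zero for unused DoFs", {
  expect_equal(targets_for("Rest"), c(hand = 0, wrist = 0))
  expect_equal(targets_for("Cls"), c(hand = -30, wrist = 0))
  expect_equal(targets_for("Opn+Sup"), c(hand = 30, wrist = -30))
  expect_equal(targets_for("Pro"), c(hand = 0, wrist = 30))
  # mapped strategy aliases onto the same signed DoFs
  expect_equal(targets_for("Flx"), c(hand = -30, wrist = 0))
  expect_equal(targets_for("Ext+Rad"), c(hand = 30, wrist = 30))
  expect_equal(targets_for("Uln", effort_pct = 40), c(hand = 0, wrist = -40))
})

test_that("design assembly trims, replicates rest, and aligns targets", {
  sig <- sigma_series(matrix(runif(9000 * 16), 9000, 16))
  sched <- build_schedule("DirCon")
  des <- assemble_design(sig, sched, fit_spec())
  expect_equal(sum(des$row_labels == "Cls"), 800)
  expect_equal(sum(des$row_labels == "Rest"), 6400)
  expect_equal(nrow(des$X), 6400 + 8 * 800)
  expect_equal(ncol(des$X), 17)  # 16 channels + bias
  expect_true(all(des$Y %in% c(0, 30, -30)))
  expect_equal(unname(des$Y[des$row_labels == "Cls", 1]), rep(-30, 800))
  # no trimming: full 1000 rows per segment; bias off drops the column
  des0 <- assemble_design(sig, sched, fit_spec(trim_s = 0, bias = FALSE))
  expect_equal(sum(des0$row_labels == "Opn"), 1000)
  expect_equal(ncol(des0$X), 16)
  # short recording reports the missing duration
  expect_error(assemble_design(sigma_series(matrix(1, 800, 16)), sched),
               "missing")
})

test_that("identity design returns the targets as coefficients", {
  des <- manual_design(diag(4), matrix(rnorm(8), 4, 2))
  m <- fit_pseudo_inverse(des, tol = 1e-9)
  expect_equal(unname(m$coefficients), unname(des$Y), tolerance = 1e-12)
})

test_that("well-conditioned solve agrees with the normal equations", {
  set.seed(31)
  X <- matrix(rnorm(400), 100, 4)
  Y <- matrix(rnorm(200), 100, 2)
  m <- fit_pseudo_inverse(manual_design(X, Y))
  ref <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(m$coefficients), unname(ref), tolerance = 1e-8)
})

test_that("rank-deficient design gives the truncated minimum-norm solution", {
  set.seed(32)
  X <- matrix(rnorm(300), 100, 3)
  X <- cbind(X, X[, 2])  # exactly duplicated column
  Y <- matrix(rnorm(200), 100, 2)
  m <- fit_pseudo_inverse(manual_design(X, Y), tol = 0.01)
  ref <- ref_pinv_coef(X, Y, 0.01)
  expect_equal(unname(m$coefficients), unname(ref), tolerance = 1e-8)
  # minimum-norm solution splits the duplicated column's weight equally
  expect_equal(m$coefficients[2, ], m$coefficients[4, ], tolerance = 1e-8)
  expect_equal(m$n_singular_retained, 3)
  expect_error(fit_pseudo_inverse(manual_design(matrix(0, 10, 2),
                                                matrix(0, 10, 2))),
               "degenerate")
})

test_that("prediction is the linear map over the model's channel subset", {
  ses <- small_session()
  m <- emg_force_fit(ses$sigma, ses$schedule, ses$fitspec)
  # zero sigma with bias disabled gives exactly zero force
  spec0 <- fit_spec(trim_s = 0.2, bias = FALSE)
  m0 <- emg_force_fit(ses$sigma, ses$schedule, spec0)
  expect_equal(unname(predict(m0, matrix(0, 1, 8))), matrix(0, 1, 2),
               ignore_attr = TRUE)
  # self-consistency: residual RMSE on the design equals the reported overall
  expect_equal(sqrt(mean(residuals(m)^2)), m$quality$rmse_overall)
  # channel-subset prediction: full matrix vs just the selected columns
  m2 <- backward_select(m, 2)
  full <- predict(m2, ses$sigma)
  sub <- ses$sigma$sigma[, m2$channels, drop = FALSE]
  colnames(sub) <- m2$channel_names
  expect_equal(full, predict(m2, sub))
  # missing channel is named in the error
  bad <- ses$sigma$sigma[, 1, drop = FALSE]
  colnames(bad) <- "ch01"
  expect_error(predict(m2, bad), m2$channel_names[2], fixed = TRUE)
})

test_that("quality report: zero for an exact linear system, noise std recovered, recomputable", {
  set.seed(33)
  # exact linear system
  X <- matrix(runif(800 * 4), 800, 4)
  B <- matrix(rnorm(8), 4, 2)
  m <- fit_pseudo_inverse(manual_design(X, X %*% B))
  expect_lt(m$quality$rmse_overall, 1e-9)
  expect_true(all(m$quality$rmse_by_type < 1e-9))
  # additive output noise of known std
  s_true <- 3
  X <- matrix(runif(6400 * 4, 0.1, 1), 6400, 4)
  Y <- X %*% B + matrix(rnorm(6400 * 2, sd = s_true), 6400, 2)
  m <- fit_pseudo_inverse(manual_design(X, Y))
  expect_equal(m$quality$rmse_overall, s_true, tolerance = 0.1)
  # overall RMSE is recomputable from per-row residuals
  expect_equal(m$quality$rmse_overall, sqrt(mean(residuals(m)^2)))
})

test_that("rest replicas are counted once in the per-type report", {
  ses <- small_session()
  m <- emg_force_fit(ses$sigma, ses$schedule, ses$fitspec)
  keep <- m$design$row_labels == "Rest" & !m$design$replica
  res <- residuals(m)[keep, ]
  expect_equal(unname(m$quality$rmse_by_type[["Rest"]]), sqrt(mean(res^2)))
  expect_equal(sum(keep) * m$design$spec$rest_weight,
               sum(m$design$row_labels == "Rest"))
})

test_that("backward selection: identity at k = n, exhaustive-oracle last step, tie rule", {
  ses <- small_session()
  m <- emg_force_fit(ses$sigma, ses$schedule, ses$fitspec)
  expect_equal(backward_select(m, 8)$channels, m$channels)
  # one elimination step against exhaustive single-removal search
  m7 <- backward_select(m, 7)
  rmses <- vapply(m$channels, function(ch) {
    d2 <- myoprop:::drop_design_channel(m$design, ch)
    s <- myoprop:::pinv_solve(d2$X, d2$Y, m$tol_used)
    sqrt(mean((d2$Y - d2$X %*% s$coef)^2))
  }, numeric(1))
  best <- min(m$channels[rmses == min(rmses)])  # lowest index on ties
  expect_equal(setdiff(m$channels, m7$channels), best)
  expect_error(backward_select(m, 9), "outside")
})

test_that("selection keeps signal-carrying channels and drops pure-noise ones", {
  set.seed(34)
  # 4 channels with distinct direction gains, 2 carrying only noise
  n <- 2000
  E <- cbind(hand = rep(c(-30, 0, 30, 0), each = n / 4),
             wrist = rep(c(0, -30, 0, 30), each = n / 4))
  G <- rbind(c(1.2, 0.1), c(0.1, -0.9), c(-0.8, 0.3), c(0.2, 1.1))
  X <- cbind(E %*% t(G) + matrix(rnorm(4 * n, sd = 0.5), n, 4),
             matrix(rnorm(2 * n, sd = 2), n, 2))
  m <- fit_pseudo_inverse(manual_design(X, E))
  m4 <- backward_select(m, 4)
  expect_equal(m4$channels, 1:4)
})

test_that("without truncation the greedy RMSE path is non-decreasing as k shrinks", {
  set.seed(35)
  X <- matrix(runif(1200 * 8), 1200, 8)
  Y <- X[, 1:3] %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(2400, sd = 1), 1200, 2)
  m <- fit_pseudo_inverse(manual_design(X, Y), tol = 1e-10)
  expect_equal(m$n_singular_retained, ncol(m$design$X))  # nothing truncated
  m2 <- backward_select(m, 2, tol = 1e-10)
  expect_true(all(diff(m2$selection_history$rmse_after) >= -1e-12))
})

test_that("identical inputs give byte-identical serialized models", {
  ses <- small_session()
  m1 <- emg_force_fit(ses$sigma, ses$schedule, ses$fitspec)
  m2 <- emg_force_fit(ses$sigma, ses$schedule, ses$fitspec)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_force_model(m1, p1, timestamp = FALSE)
  write_force_model(m2, p2, timestamp = FALSE)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
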