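#' Run the full pipeline end to end
#'
#' Executes the stages requested by a run configuration: acquire raw EMG
#' (from file, or synthesized when a `simulate` block is present), estimate
#' EMG-sigma, calibrate the requested controller, optionally backward-select
#' channels, run the controller over the recording, and integrate the
#' virtual plant. Output files (`model.json`, `commands.csv`,
#' `trajectory.csv`, and `session.csv`/`truth.csv` when simulating) are
#' written atomically into `out_dir`; a failing stage leaves no partial
#' artifact. Per-stage wall-clock timings and the parameter echo are
#' returned in the report.
#'
#' Recognized configuration fields: `controller` (`"dircon"`, `"mapcon"` or
#' `"seqcon"`), `seed`, `input` (raw CSV path; ignored when simulating),
#' `simulate` (list: `n_channels`, `duration_scale`, `effort_jitter_rel`,
#' ...), `select_k`, `out_dir`, and optional `filter`, `fit`, `control`,
#' `plant` argument lists plus a `seqcon` list (`ext_channel`,
#' `flx_channel`, ...).
#'
#' @param cfg a [as_run_config()] list, a path to a YAML/JSON config, or a
#'   plain named list
#' @param verbose print per-stage progress
#' @return invisibly, a report list: `paths`, `timings_s`, `model`,
#'   `config`
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  timings <- c()
  paths <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    say("stage %-10s %6.2f s", name, timings[[name]])
    out
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  strategy <- switch(cfg$controller, dircon = "DirCon", mapcon = "MapCon",
                     seqcon = "MapCon")

  acquired <- stage("acquire", function() {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$strategy <- strategy
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      ses <- do.call(simulate_session, sim_args)
      p_raw <- file.path(cfg$out_dir, "session.csv")
      write_raw_emg(ses$raw, p_raw)
      p_truth <- file.path(cfg$out_dir, "truth.csv")
      atomic_write(p_truth, function(tmp)
        write.csv(data.frame(t_s = (seq_len(nrow(ses$truth)) - 1) / 100,
                             hand_pct = ses$truth[, "hand"],
                             wrist_pct = ses$truth[, "wrist"]),
                  tmp, row.names = FALSE))
      paths$session <<- p_raw; paths$truth <<- p_truth
      list(raw = ses$raw, schedule = ses$schedule)
    } else {
      if (is.null(cfg$input)) stop("no input path and no simulate block")
      list(raw = read_raw_emg(cfg$input), schedule = build_schedule(strategy))
    }
  })

  sigma <- stage("process", function() {
    bank <- design_filter_bank(do.call(filter_spec, cfg$filter),
                               acquired$raw$fs_hz)
    process_batch(acquired$raw, bank)
  })

  if (cfg$controller %in% c("dircon", "mapcon")) {
    model <- stage("calibrate", function() {
      m <- emg_force_fit(sigma, acquired$schedule, do.call(fit_spec, cfg$fit))
      if (!is.null(cfg$select_k)) m <- backward_select(m, cfg$select_k)
      p <- file.path(cfg$out_dir, "model.json")
      write_force_model(m, p, timestamp = FALSE, seed_provenance = cfg$seed)
      paths$model <<- p
      m
    })
    ctrl_cfg <- do.call(controller_config, cfg$control)
    plant <- do.call(plant_spec, cfg$plant)
    commands <- stage("control", function()
      run_regression_controller(sigma, model, ctrl_cfg, plant))
  } else {
    if (is.null(cfg$seqcon) || is.null(cfg$seqcon$ext_channel) ||
        is.null(cfg$seqcon$flx_channel))
      stop("stage 'calibrate' failed: seqcon needs ext_channel and flx_channel",
           call. = FALSE)
    spec <- stage("calibrate", function() {
      args <- cfg$seqcon
      known <- c("ext_channel", "flx_channel", "effort_pct", "trim_s",
                 "cocon_peak")
      cal_args <- args[names(args) %in% known]
      extra <- args[!names(args) %in% known]
      do.call(seqcon_calibrate,
              c(list(sigma = sigma, schedule = acquired$schedule), cal_args,
                extra))
    })
    model <- spec
    ctrl_cfg <- do.call(controller_config, cfg$control)
    plant <- do.call(plant_spec, cfg$plant)
    commands <- stage("control", function()
      run_seqcon(sigma, spec, plant, ctrl_cfg))
  }

  trajectory <- stage("plant", function()
    plant_run(commands, plant = plant))

  stage("write", function() {
    p_cmd <- file.path(cfg$out_dir, "commands.csv")
    atomic_write(p_cmd, function(tmp) write.csv(commands, tmp, row.names = FALSE))
    p_traj <- file.path(cfg$out_dir, "trajectory.csv")
    atomic_write(p_traj, function(tmp) write.csv(trajectory, tmp, row.names = FALSE))
    paths$commands <<- p_cmd; paths$trajectory <<- p_traj
    NULL
  })

  invisible(list(paths = paths, timings_s = unlist(timings),
                 model = model, config = cfg))
}
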