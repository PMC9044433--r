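# Atomic write: write to a temp file in the destination directory, then
# rename. A failed stage never leaves a partial artifact behind.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move temporary file into place at '%s'", path),
         call. = FALSE)
  invisible(path)
}

#' Read a raw EMG recording from the delimited CSV dialect
#'
#' The format is UTF-8 CSV with two comment header lines, `# fs_hz=<float>`
#' and `# channels=<comma-separated labels>`, followed by one row per
#' sample and one column per channel (period decimal separator).
#'
#' @param path file path
#' @return a [raw_emg()]
#' @export
read_raw_emg <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  parse_field <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), header, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^#\\s*%s=", key), "", hit[1])
  }
  fs <- parse_field("fs_hz")
  if (is.null(fs))
    stop(sprintf("'%s': missing '# fs_hz=' header line", path), call. = FALSE)
  fs <- suppressWarnings(as.numeric(fs))
  if (is.na(fs)) stop(sprintf("'%s': non-numeric fs_hz header", path), call. = FALSE)
  channels <- parse_field("channels")
  channels <- if (is.null(channels)) NULL else trimws(strsplit(channels, ",")[[1]])
  dat <- tryCatch(
    read.csv(path, header = FALSE, comment.char = "#",
             colClasses = "numeric", blank.lines.skip = TRUE),
    error = function(e)
      stop(sprintf("'%s': malformed data rows (%s)", path, conditionMessage(e)),
           call. = FALSE),
    warning = function(w)
      stop(sprintf("'%s': malformed data rows (%s)", path, conditionMessage(w)),
           call. = FALSE))
  m <- as.matrix(dat)
  if (!is.null(channels) && length(channels) != ncol(m))
    stop(sprintf("'%s': header names %d channels but rows have %d columns",
                 path, length(channels), ncol(m)), call. = FALSE)
  raw_emg(m, fs_hz = fs, channel_names = channels)
}

#' Write a raw EMG recording in the delimited CSV dialect
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces the matrix exactly. The write is atomic.
#'
#' @param raw a [raw_emg()]
#' @param path destination path
#' @return the path, invisibly
#' @export
write_raw_emg <- function(raw, path) {
  stopifnot(inherits(raw, "raw_emg"))
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# fs_hz=%.17g", raw$fs_hz),
                 paste0("# channels=", paste(raw$channel_names, collapse = ","))),
               con)
    txt <- matrix(sprintf("%.17g", raw$samples), nrow(raw$samples))
    writeLines(do.call(paste, c(split(txt, col(txt)), sep = ",")), con)
  })
}

#' Serialize a fitted force model to JSON
#'
#' Fields: strategy, channels, channel names, coefficients (row-major with
#' stated shape), bias flag, truncation tolerance, number of singular
#' values retained, quality report, optional UTC timestamp and seed
#' provenance. Numbers are written at full precision, so the model
#' round-trips losslessly through [read_force_model()]. (The calibration
#' design matrix is not serialized; a model read back supports prediction
#' and control but not re-selection.)
#'
#' @param model an `emg_force_model`
#' @param path destination path
#' @param timestamp include a `created_utc` field (set `FALSE` for
#'   byte-reproducible output)
#' @param seed_provenance optional integer recorded for bookkeeping
#' @return the path, invisibly
#' @export
write_force_model <- function(model, path, timestamp = TRUE,
                              seed_provenance = NULL) {
  stopifnot(inherits(model, "emg_force_model"))
  obj <- list(strategy = model$strategy,
              channels = model$channels,
              channel_names = model$channel_names,
              coef = as.vector(t(model$coefficients)),
              coef_shape = dim(model$coefficients),
              bias_enabled = model$bias,
              tol_used = model$tol_used,
              n_singular_retained = model$n_singular_retained,
              quality = list(rmse_by_type = as.list(model$quality$rmse_by_type),
                             rmse_overall = model$quality$rmse_overall))
  if (timestamp)
    obj$created_utc <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (!is.null(seed_provenance)) obj$seed_provenance <- seed_provenance
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE))
}

#' Read a fitted force model from JSON
#'
#' @param path path written by [write_force_model()]
#' @return an `emg_force_model` (without calibration design data)
#' @export
read_force_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- matrix(obj$coef, nrow = obj$coef_shape[1], ncol = obj$coef_shape[2],
                 byrow = TRUE)
  rn <- c(obj$channel_names, if (isTRUE(obj$bias_enabled)) "(bias)")
  dimnames(coef) <- list(rn, c("hand", "wrist"))
  structure(list(coefficients = coef,
                 channels = as.integer(obj$channels),
                 channel_names = obj$channel_names,
                 strategy = obj$strategy,
                 bias = isTRUE(obj$bias_enabled),
                 tol_used = obj$tol_used,
                 n_singular_retained = obj$n_singular_retained,
                 singular_values = NULL,
                 design = NULL,
                 quality = list(rmse_by_type = unlist(obj$quality$rmse_by_type),
                                rmse_overall = obj$quality$rmse_overall),
                 created_utc = obj$created_utc,
                 seed_provenance = obj$seed_provenance),
            class = "emg_force_model")
}

#' Read a run configuration from YAML or JSON
#'
#' A run configuration names the controller and paths and optionally
#' overrides the filter, fit, controller, sequential and plant sub-blocks;
#' unspecified fields keep their package defaults.
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file
#' @return a named list of class `run_config`
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop(sprintf("unsupported config extension '.%s'", ext), call. = FALSE)
  as_run_config(cfg)
}

#' Assemble a run configuration from a plain list
#'
#' @param cfg named list; see [run_pipeline()] for recognized fields
#' @return a `run_config`
#' @export
as_run_config <- function(cfg) {
  defaults <- list(controller = "dircon", seed = 1L, select_k = NULL,
                   input = NULL, model = NULL, out_dir = ".",
                   simulate = NULL, filter = list(), fit = list(),
                   control = list(), seqcon = NULL, plant = list())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$controller <- match.arg(tolower(cfg$controller),
                              c("dircon", "mapcon", "seqcon"))
  structure(cfg, class = "run_config")
}
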