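# Flat-text run configuration: dotted section.key = value lines, chosen for
# diff-ability in experiment logs. Unknown keys are rejected; values are
# coerced to the type of the corresponding default, so a config round-trips
# losslessly.

#' Default run configuration
#'
#' All tunable parameters of the simulate / preprocess / train / evaluate
#' pipeline with their defaults, as a named flat list (`section.key`).
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(
    simulate.n_beats = 600L,
    simulate.class_mix = "0.34,0.33,0.33",
    simulate.separation = 1,
    simulate.noise_preset = "ambulatory",
    simulate.fs = 360,
    simulate.seed = 1L,
    preprocess.r = 250L,
    preprocess.pre_samples = 100L,
    preprocess.levels = 9L,
    preprocess.wavelet = "db6",
    preprocess.threshold_scale = 1,
    preprocess.remove_baseline = TRUE,
    preprocess.target_fs = 360,
    extractor.omega = 25L,
    extractor.cell_type = "GRU",
    extractor.hidden1 = 32L,
    extractor.hidden2 = 64L,
    extractor.m = 64L,
    extractor.activation = "tanh",
    extractor.seed = 1L,
    ensemble.eta = 1,
    ensemble.c = 2,
    ensemble.pi = 0.1,
    ensemble.tau = 0.1,
    ensemble.clf_h1 = 32L,
    ensemble.clf_h2 = 16L,
    pipeline.epochs = 30L,
    pipeline.batch_size = 32L,
    pipeline.lr = 0.001,
    pipeline.train_frac = 0.6,
    pipeline.val_frac = 0.2,
    pipeline.test_frac = 0.2,
    pipeline.stratified = TRUE,
    pipeline.seed = 0L
  )
}

#' Write a run configuration
#'
#' @param config named list as from [default_run_config()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_mb(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.numeric(v)) return(sprintf("%.15g", v))
    as.character(v)
  }
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration
#'
#' Missing keys take their defaults; unknown keys are an error. Values are
#' coerced to the default's type.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return Named list (complete configuration).
#' @export
read_run_config <- function(path = NULL) {
  config <- default_run_config()
  if (is.null(path)) return(config)
  if (!file.exists(path)) stop_mb(sprintf("config file '%s' not found", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop_mb(sprintf("malformed config line: '%s'", ln))
    key <- kv[2]; val <- trimws(kv[3])
    if (!key %in% names(config)) {
      stop_mb(sprintf("unknown config key '%s'", key))
    }
    config[[key]] <- .coerce_like(val, config[[key]], key)
  }
  config
}

.coerce_like <- function(val, default, key) {
  if (is.logical(default)) {
    if (!val %in% c("true", "false", "TRUE", "FALSE")) {
      stop_mb(sprintf("config key '%s' must be true/false, got '%s'", key, val))
    }
    return(val %in% c("true", "TRUE"))
  }
  if (is.integer(default)) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num) || num != round(num)) {
      stop_mb(sprintf("config key '%s' must be an integer, got '%s'", key, val))
    }
    return(as.integer(num))
  }
  if (is.numeric(default)) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) {
      stop_mb(sprintf("config key '%s' must be numeric, got '%s'", key, val))
    }
    return(num)
  }
  val
}
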