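# Observed-dataset container, CSV/JSON serialisation and the functions
# behind the command-line entry points.

#' Observed dataset
#'
#' Container for the per-variable observed value lists a fit consumes: MEP
#' amplitudes at three stimulation times (mV), EMG onset times (s), and EMG
#' offsets (go trials, s) or EMG onset rates (partial trials, mV/s), or
#' reaction times (`rts`, stop-signal task).  Variables may have different
#' lengths (onsets exist only for responded trials).
#'
#' @param variables Named list of non-empty numeric vectors.
#' @param trial_type `"go"`, `"gs"` or `"sst"`.
#' @param n_trials Total trial count behind the dataset.
#' @param stim_times Optional stimulation times (s) the MEP variables refer
#'   to.
#' @return An object of class `"observed_dataset"`.
#' @export
observed_dataset <- function(variables, trial_type = c("go", "gs", "sst"),
                             n_trials, stim_times = NULL) {
  trial_type <- match.arg(trial_type)
  stopifnot(is.list(variables), length(variables) >= 1,
            !is.null(names(variables)), all(nzchar(names(variables))),
            is_number(n_trials), n_trials >= 1)
  for (v in names(variables)) {
    x <- variables[[v]]
    if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
      stop("variable ", v, " must be a non-empty finite numeric vector")
    variables[[v]] <- as.numeric(x)
  }
  structure(list(variables = variables, trial_type = trial_type,
                 n_trials = as.integer(n_trials), stim_times = stim_times),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat("Observed dataset (", x$trial_type, "), ", x$n_trials, " trials\n",
      sep = "")
  for (v in names(x$variables))
    cat(sprintf("  %-12s n = %4d, mean = %8.4f, sd = %8.4f\n", v,
                length(x$variables[[v]]), mean(x$variables[[v]]),
                stats::sd(x$variables[[v]])))
  invisible(x)
}

# lightweight identity check used by compare_models: variable names,
# lengths and rounded first two moments
observed_fingerprint <- function(obs) {
  stopifnot(inherits(obs, "observed_dataset"))
  list(trial_type = obs$trial_type, n_trials = obs$n_trials,
       variables = lapply(obs$variables, function(x)
         c(n = length(x), sum = round(sum(x), 9), sumsq = round(sum(x^2), 9))))
}

#' Read and write observed datasets as CSV
#'
#' One column per variable, shorter variables padded with empty cells; a
#' JSON sidecar (`<path>.json`) records the trial type, trial count,
#' stimulation times and units.
#'
#' @param obs An [observed_dataset()].
#' @param path CSV file path.
#' @return `write_observed_csv` returns `path` invisibly;
#'   `read_observed_csv` returns an [observed_dataset()].
#' @export
write_observed_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observed_dataset"))
  nmax <- max(vapply(obs$variables, length, integer(1)))
  df <- as.data.frame(lapply(obs$variables, function(x) {
    length(x) <- nmax
    x
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  sidecar <- list(trial_type = obs$trial_type, n_trials = obs$n_trials,
                  stim_times = obs$stim_times,
                  units = list(mep = "mV", times = "s", rates = "mV/s"),
                  package_version = as.character(utils::packageVersion("atmrace")))
  gt <- attr(obs, "ground_truth")
  if (!is.null(gt)) sidecar$ground_truth <- unclass_deep(gt)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  if (!file.exists(path)) stop("observed-data CSV not found: ", path)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty observed-data CSV: ", path)
  vars <- lapply(df, function(x) as.numeric(x[!is.na(x)]))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::fromJSON(sidecar_path)
    observed_dataset(vars, trial_type = sc$trial_type,
                     n_trials = sc$n_trials,
                     stim_times = sc$stim_times)
  } else {
    type <- if ("rts" %in% names(vars)) "sst"
            else if ("emg_rates" %in% names(vars)) "gs" else "go"
    observed_dataset(vars, trial_type = type,
                     n_trials = max(vapply(vars, length, integer(1))))
  }
}

#' Write simulated trials to CSV
#'
#' One row per trial: trial type, crossing flag, onset/offset (s), MEP
#' amplitudes at the stimulation times (mV) and the onset rate (mV/s).
#'
#' @param trials An `ri_trials` data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(inherits(trials, "ri_trials"))
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulation summary to JSON
#'
#' Serialises the output of [summarize_trials()] with provenance: seed,
#' configuration hash and package version.  Identical configurations give
#' byte-identical files.
#'
#' @param summary Output of [summarize_trials()].
#' @param path Output JSON path.
#' @param config The [simulation_config()] used (for the hash and seed).
#' @param extra Optional named list merged into the output.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, config = NULL, extra = NULL) {
  out <- list(
    package = "atmrace",
    package_version = as.character(utils::packageVersion("atmrace")),
    seed = config$seed,
    config_hash = if (!is.null(config)) config_hash(config),
    n_trials = summary$n_trials,
    n_crossed = summary$n_crossed,
    crossing_fraction = summary$crossing_fraction,
    stats = summary$stats
  )
  if (!is.null(extra)) out <- c(out, extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration
#'
#' JSON or YAML configuration files are accepted (YAML requires the yaml
#' package).  See [cli_simulate()] for the recognised fields.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

# build a model_spec from a config list: preset by model/trial_type, then
# parameter overrides applied on top
spec_from_config <- function(cfg) {
  model <- match.arg(cfg$model, c("atm", "hrm"))
  trial_type <- match.arg(cfg$trial_type, c("go", "gs", "stopboth", "sst"))
  spec <- switch(paste(model, trial_type),
                 "atm go" = atm_go_spec(), "hrm go" = hrm_go_spec(),
                 "atm gs" = atm_gs_spec(), "atm stopboth" = atm_gs_spec(),
                 "hrm gs" = hrm_gs_spec(), "atm sst" = sst_go_spec(),
                 stop("unsupported model/trial_type combination: ",
                      model, "/", trial_type))
  pars <- cfg$parameters
  if (!is.null(pars)) {
    num2 <- function(x) c(as.numeric(x[[1]]), as.numeric(x[[2]]))
    if (!is.null(pars$facilitation)) {
      f <- pars$facilitation
      spec$facilitation <- gaussian_process_spec(
        amplitude = num2(f$amplitude %||% spec$facilitation$amplitude),
        peak_time = num2(f$peak_time %||% spec$facilitation$peak_time),
        width = num2(f$width %||% spec$facilitation$width))
    }
    th <- spec$threshold
    if (!is.null(pars$threshold)) {
      t <- pars$threshold
      spec$threshold <- switch(th$kind,
        "fixed-decision" = threshold_spec("fixed-decision",
          fixed_value = as.numeric(t$fixed_value %||% th$fixed_value)),
        "tonic-sampled" = threshold_spec("tonic-sampled",
          tonic = num2(t$tonic %||% th$tonic)),
        "step" = threshold_spec("step",
          tonic = num2(t$tonic %||% th$tonic),
          k_inh = as.numeric(t$k_inh %||% th$k_inh),
          tau_inh = as.numeric(t$tau_inh %||% th$tau_inh),
          step_t = num2(t$step_t %||% th$step_t)))
    }
    if (!is.null(pars$secondary_peak_time))
      spec$secondary_peak_time <- check_pair(num2(pars$secondary_peak_time),
                                             "secondary_peak_time")
    if (!is.null(pars$stop_process)) {
      s <- pars$stop_process
      base <- spec$stop_process
      spec$stop_process <- gaussian_process_spec(
        amplitude = num2(s$amplitude %||% base$amplitude),
        peak_time = num2(s$peak_time %||% base$peak_time),
        width = num2(s$width %||% base$width))
    }
  }
  spec
}

config_from_cfg <- function(cfg) {
  simulation_config(
    n_trials = cfg$n_trials %||% 100000L,
    seed = cfg$seed,
    offset_mode = cfg$offset_mode %||% "recross",
    rate_calibration = cfg$rate_calibration %||% default_rate_calibration()
  )
}

require_fields <- function(cfg, fields, what) {
  missing <- setdiff(fields, names(cfg))
  if (length(missing))
    stop(what, " config is missing required field(s): ",
         paste(missing, collapse = ", "),
         "\nrequired: ", paste(fields, collapse = ", "), call. = FALSE)
}

#' Run a simulation from a configuration file
#'
#' Reads a JSON/YAML configuration with fields `model` (`"atm"`/`"hrm"`),
#' `trial_type` (`"go"`, `"gs"`, `"stopboth"`, `"sst"`), `seed`, and
#' optionally `n_trials`, `offset_mode`, `rate_calibration`,
#' `include_secondary` and nested `parameters` overriding the reference
#' values; simulates; and writes `<out_prefix>_trials.csv` and
#' `<out_prefix>_summary.json`.  The configuration is validated before any
#' file is written, so a malformed configuration produces no partial
#' output.
#'
#' @param config_path Path to the configuration file.
#' @param out_prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
cli_simulate <- function(config_path, out_prefix) {
  cfg <- read_run_config(config_path)
  require_fields(cfg, c("model", "trial_type", "seed"), "simulate")
  spec <- spec_from_config(cfg)
  config <- config_from_cfg(cfg)
  trials <- switch(cfg$trial_type,
    go = simulate_go(spec, config),
    gs = if (cfg$model == "hrm") simulate_partial_hrm(spec, config)
         else simulate_partial_atm(spec, config,
                include_secondary = isTRUE(cfg$include_secondary %||% TRUE)),
    stopboth = simulate_stop_both(spec, config)$trials,
    sst = simulate_sst_go(spec, config))
  files <- c(trials = paste0(out_prefix, "_trials.csv"),
             summary = paste0(out_prefix, "_summary.json"))
  write_trials_csv(trials, files[["trials"]])
  write_summary_json(summarize_trials(trials), files[["summary"]],
                     config = config,
                     extra = list(model = cfg$model,
                                  trial_type = cfg$trial_type))
  invisible(files)
}

#' Fit a model from a configuration file
#'
#' Reads a configuration with fields `mode` (see [fit_model()]) and `seed`,
#' and optionally `n_trials` (per-evaluation simulation size), `init`,
#' `multistart`, `maxit` and `frozen` (a `model`/`trial_type`/`parameters`
#' block resolved via the reference specs, required for `gs_*`/`sst`
#' modes; defaults to the matching reference go spec); fits the observed
#' CSV; writes the fit as JSON.
#'
#' @param config_path Path to the configuration file.
#' @param observed_csv Observed dataset CSV (see [write_observed_csv()]).
#' @param out_json Output JSON path.
#' @return The `"ri_fit"` object, invisibly.
#' @export
cli_fit <- function(config_path, observed_csv, out_json) {
  cfg <- read_run_config(config_path)
  require_fields(cfg, c("mode", "seed"), "fit")
  mode <- match.arg(cfg$mode, names(fit_modes()))
  observed <- read_observed_csv(observed_csv)
  frozen <- NULL
  if (fit_modes()[[mode]]$needs_frozen) {
    frozen <- if (!is.null(cfg$frozen)) spec_from_config(cfg$frozen)
              else if (mode == "gs_hrm") hrm_go_spec() else atm_go_spec()
  }
  config <- simulation_config(n_trials = cfg$n_trials %||% 2000L,
                              seed = cfg$seed)
  fit <- fit_model(mode, observed,
                   init = if (!is.null(cfg$init)) as.numeric(cfg$init)
                          else fit_init(mode),
                   config = config, frozen = frozen,
                   multistart = isTRUE(cfg$multistart %||% TRUE),
                   control = list(maxit = cfg$maxit %||% 400L))
  write_fit_json(fit, out_json)
  invisible(fit)
}

#' Serialise a fit result to JSON and back
#'
#' @param fit An `"ri_fit"` object.
#' @param path JSON file path.
#' @return `write_fit_json` returns `path` invisibly; `read_fit_json`
#'   returns a list usable by [compare_models()].
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ri_fit"))
  out <- list(
    package = "atmrace",
    package_version = as.character(utils::packageVersion("atmrace")),
    mode = fit$mode,
    parameters = as.list(fit$par),
    per_variable_chi2 = as.list(fit$per_variable_chi2),
    summed_chi2 = fit$summed_chi2,
    aic = fit$aic,
    n_free = fit$n_free,
    n_bins = fit$n_bins,
    convergence = fit$convergence,
    seed = fit$config$seed,
    n_sim_trials = fit$config$n_trials,
    starts = fit$starts,
    observed_fingerprint = fit$observed_fingerprint
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("could not parse fit JSON '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  for (f in c("mode", "summed_chi2", "observed_fingerprint"))
    if (is.null(x[[f]])) stop("fit JSON lacks field '", f, "': ", path)
  # restore the fingerprint's numeric-vector shape for identical() checks
  x$observed_fingerprint$variables <-
    lapply(x$observed_fingerprint$variables, function(v)
      c(n = as.numeric(v$n), sum = as.numeric(v$sum),
        sumsq = as.numeric(v$sumsq)))
  x$per_variable_chi2 <- unlist(x$per_variable_chi2)
  x$summed_chi2 <- as.numeric(x$summed_chi2)
  x$aic <- if (is.null(x$aic)) NA_real_ else as.numeric(x$aic)
  x$mode <- as.character(x$mode)
  x
}

#' Compare two fit-result JSON files
#'
#' Reads two files written by [write_fit_json()], checks they describe the
#' same observed dataset, prints the comparison report and optionally
#' writes it as JSON.
#'
#' @param fit_json_a,fit_json_b Paths to fit JSON files.
#' @param out_json Optional output path for the comparison report.
#' @return The `"ri_comparison"` object, invisibly.
#' @export
cli_compare <- function(fit_json_a, fit_json_b, out_json = NULL) {
  fa <- read_fit_json(fit_json_a)
  fb <- read_fit_json(fit_json_b)
  # normalise the fingerprints to a common shape before comparing
  norm_fp <- function(fp) list(
    trial_type = as.character(fp$trial_type),
    n_trials = as.numeric(fp$n_trials),
    variables = lapply(fp$variables, as.numeric))
  fa$observed_fingerprint <- norm_fp(fa$observed_fingerprint)
  fb$observed_fingerprint <- norm_fp(fb$observed_fingerprint)
  cmp <- compare_models(fa, fb)
  print(cmp)
  if (!is.null(out_json))
    jsonlite::write_json(list(table = cmp$table, preferred = cmp$preferred,
                              modes = cmp$modes),
                         out_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  invisible(cmp)
}

#' Generate a pseudo-empirical dataset from a configuration file
#'
#' Configuration fields: `kind` (`"go"`, `"gs"`, `"sst"` or
#' `"from_model"`), `seed`, and optionally `n`, `shape` (SST),
#' `mep_spread_kind`, and for `"from_model"` a `model`/`trial_type`/
#' `parameters` block.  Writes the dataset CSV (plus sidecar); SST
#' reaction times are written as a single `rts` column.
#'
#' @param config_path Path to the configuration file.
#' @param out_csv Output CSV path.
#' @return `out_csv`, invisibly.
#' @export
cli_synth <- function(config_path, out_csv) {
  cfg <- read_run_config(config_path)
  require_fields(cfg, c("kind", "seed"), "synth")
  kind <- match.arg(cfg$kind, c("go", "gs", "sst", "from_model"))
  obs <- switch(kind,
    go = {
      s <- empirical_summary_go(cfg$mep_spread_kind %||% "se15")
      generate_observed_go(s, n = cfg$n %||% s$n_trials, seed = cfg$seed)
    },
    gs = {
      s <- empirical_summary_gs(cfg$mep_spread_kind %||% "se15")
      generate_observed_gs(s, n = cfg$n %||% s$n_trials, seed = cfg$seed)
    },
    sst = {
      rts <- generate_sst_rts(cfg$n %||% 100000L, shape = cfg$shape %||% 4,
                              seed = cfg$seed)
      observed_dataset(list(rts = rts), trial_type = "sst",
                       n_trials = length(rts))
    },
    from_model = {
      require_fields(cfg, c("model", "trial_type"), "synth from_model")
      generate_from_model(spec_from_config(cfg), trial_type = cfg$trial_type,
                          n = cfg$n %||% 514L, seed = cfg$seed)
    })
  write_observed_csv(obs, out_csv)
  invisible(out_csv)
}
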