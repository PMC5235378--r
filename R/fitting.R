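# Tertile-binned Pearson chi-square fitting and model comparison.
#
# Each fitted variable (MEP amplitudes at three stimulation times, EMG
# onsets, and EMG offsets or onset rates) is partitioned into lower /
# middle / upper thirds using edges computed from the observed data; the
# simulator's predictions are counted in the same bins, scaled to the
# observed trial count, and compared with a Pearson chi-square.  The
# summed chi-square across variables is minimised by Nelder-Mead from a
# set of perturbed starting points.

#' Tertile bin edges
#'
#' Edges at the empirical 1/3 and 2/3 quantiles (linear-interpolation
#' quantile convention), defining lower, middle and upper thirds.  Bins are
#' half-open: `(-Inf, e1)`, `[e1, e2)`, `[e2, Inf)`, so predictions outside
#' the observed range fall in the outer bins.
#'
#' @param values Numeric vector, at least 3 values.
#' @return Length-2 numeric vector of strictly increasing edges.
#' @examples
#' tertile_edges(1:9)  # 3.67, 6.33 -> counts 3/3/3
#' @export
tertile_edges <- function(values) {
  if (!is.numeric(values) || length(values) < 3L)
    stop("need at least 3 values to form tertiles")
  e <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  if (!(e[1] < e[2]))
    stop("degenerate tertile edges: values have too many ties")
  e
}

#' Counts per tertile bin
#'
#' @param values Numeric vector.
#' @param edges Length-2 increasing edges, as from [tertile_edges()].
#' @return Integer vector of 3 counts.
#' @export
bin_counts <- function(values, edges) {
  stopifnot(is.numeric(edges), length(edges) == 2L, edges[1] < edges[2])
  c(sum(values < edges[1]),
    sum(values >= edges[1] & values < edges[2]),
    sum(values >= edges[2]))
}

#' Pearson chi-square over bins
#'
#' `sum((o - p)^2 / p)` over the bins of one variable.  Callers are
#' expected to scale predicted counts to the observed total and floor them
#' away from zero (see [fit_model()]); the statistic itself is the plain
#' Pearson form.
#'
#' @param observed_counts,predicted_counts Non-negative numeric vectors of
#'   equal length; predicted counts all zero is an error.
#' @return The chi-square value, >= 0; zero iff the counts agree exactly.
#' @examples
#' pearson_chi2(c(4, 3, 2), c(3, 3, 3))  # 2/3
#' @export
pearson_chi2 <- function(observed_counts, predicted_counts) {
  stopifnot(is.numeric(observed_counts), is.numeric(predicted_counts),
            length(observed_counts) == length(predicted_counts))
  if (any(predicted_counts < 0)) stop("predicted counts must be >= 0")
  if (all(predicted_counts == 0)) stop("all predicted counts are zero")
  sum((observed_counts - predicted_counts)^2 / predicted_counts)
}

#' Small-sample corrected AIC for a chi-square fit
#'
#' `chi2 + 2 p + 2 p (p + 1) / (n_bins - p - 1)`, with `p` free parameters
#' and `n_bins` total bins across the fitted variables.
#'
#' @param chi2 Summed chi-square of the fit.
#' @param p Number of free model parameters.
#' @param n_bins Total number of bins; must exceed `p + 1` for the
#'   correction term to be defined.
#' @return The AIC value.
#' @examples
#' aic_chi2(0, 1, 15)  # 2 + 4/13
#' @export
aic_chi2 <- function(chi2, p, n_bins) {
  stopifnot(is_number(chi2), is_number(p), p >= 0, is_number(n_bins))
  if (n_bins <= p + 1)
    stop("small-sample correction undefined: n_bins must exceed p + 1")
  chi2 + 2 * p + 2 * p * (p + 1) / (n_bins - p - 1)
}

# ---------------------------------------------------------------------------
# fit modes: which parameters are free, and how a parameter vector maps
# onto a model_spec.  SD coordinates are passed through abs() so the
# optimizer stays unconstrained while the model always sees positive SDs.

fit_modes <- function() {
  list(
    go_hrm = list(
      trial_type = "go",
      par_names = c("fac_a_mean", "fac_a_sd", "fac_b_mean", "fac_b_sd",
                    "fac_c_mean", "fac_c_sd", "decision_thresh"),
      sd_idx = c(2L, 4L, 6L), time_idx = 3L, needs_frozen = FALSE),
    go_atm = list(
      trial_type = "go",
      par_names = c("fac_a_mean", "fac_a_sd", "fac_b_mean", "fac_b_sd",
                    "fac_c_mean", "fac_c_sd", "inhib_mean", "inhib_sd"),
      sd_idx = c(2L, 4L, 6L, 8L), time_idx = 3L, needs_frozen = FALSE),
    gs_hrm = list(
      trial_type = "gs",
      par_names = c("stop_a_mean", "stop_a_sd", "stop_b_mean", "stop_b_sd",
                    "stop_c_mean", "stop_c_sd"),
      sd_idx = c(2L, 4L, 6L), time_idx = 3L, needs_frozen = TRUE),
    gs_atm = list(
      trial_type = "gs",
      par_names = c("k_inh", "tau_inh", "step_t_mean", "step_t_sd",
                    "bnew_mean", "bnew_sd"),
      sd_idx = c(4L, 6L), time_idx = c(3L, 5L), needs_frozen = TRUE),
    sst = list(
      trial_type = "sst",
      par_names = c("fac_b_mean", "fac_b_sd"),
      sd_idx = 2L, time_idx = 1L, needs_frozen = TRUE)
  )
}

#' Default optimisation starting values
#'
#' The reference best-fit estimates (see [reference_specs]) expressed as a
#' parameter vector for each fit mode; these are the canonical starting
#' points for [fit_model()].
#'
#' @param mode A fit mode name; see [fit_model()].
#' @return Named numeric vector.
#' @export
fit_init <- function(mode = names(fit_modes())) {
  mode <- match.arg(mode)
  v <- switch(mode,
    go_hrm = c(2.342, 0.323, 0.007, 0.021, 0.066, 0.010, 1.659),
    go_atm = c(2.576, 0.053, 0.006, 0.008, 0.064, 0.011, 1.798, 0.246),
    gs_hrm = c(1.644, 0.177, 0.015, 0.008, 0.087, 0.009),
    gs_atm = c(1.887, 0.060, 0.133, 0.018, 0.108, 0.002),
    sst = c(0.129, 0.048))
  stats::setNames(v, fit_modes()[[mode]]$par_names)
}

# assemble a model_spec from a free-parameter vector
spec_from_par <- function(mode, par, frozen = NULL) {
  info <- fit_modes()[[mode]]
  if (is.null(info)) stop("unknown fit mode: ", mode)
  if (length(par) != length(info$par_names))
    stop("mode ", mode, " takes ", length(info$par_names),
         " free parameters, got ", length(par))
  par <- as.numeric(par)
  par[info$sd_idx] <- abs(par[info$sd_idx])
  if (info$needs_frozen) {
    if (is.null(frozen) || !inherits(frozen, "model_spec"))
      stop("mode ", mode, " requires a frozen go-fit model_spec")
  }
  switch(mode,
    go_hrm = model_spec("hrm",
      facilitation = gaussian_process_spec(par[1:2], par[3:4], par[5:6]),
      threshold = threshold_spec("fixed-decision", fixed_value = par[7])),
    go_atm = model_spec("atm",
      facilitation = gaussian_process_spec(par[1:2], par[3:4], par[5:6]),
      threshold = threshold_spec("tonic-sampled", tonic = par[7:8])),
    gs_hrm = model_spec("hrm",
      facilitation = frozen$facilitation,
      threshold = frozen$threshold,
      stop_process = gaussian_process_spec(par[1:2], par[3:4], par[5:6])),
    gs_atm = model_spec("atm",
      facilitation = frozen$facilitation,
      threshold = threshold_spec("step",
        tonic = if (frozen$threshold$kind == "fixed-decision")
          stop("frozen spec for gs_atm must have a tonic threshold")
        else frozen$threshold$tonic,
        k_inh = abs(par[1]), tau_inh = abs(par[2]), step_t = par[3:4]),
      secondary_peak_time = par[5:6]),
    sst = model_spec("atm",
      facilitation = gaussian_process_spec(
        amplitude = c(frozen$facilitation$amplitude[1], 0),
        peak_time = par[1:2],
        width = c(frozen$facilitation$width[1], 0)),
      threshold = threshold_spec("tonic-sampled",
        tonic = c(frozen$threshold$tonic[1], 0)))
  )
}

run_mode <- function(mode, spec, config) {
  switch(fit_modes()[[mode]]$trial_type,
         go = simulate_go(spec, config),
         gs = if (spec$model == "hrm") simulate_partial_hrm(spec, config)
              else simulate_partial_atm(spec, config, include_secondary = TRUE),
         sst = simulate_sst_go(spec, config))
}

# which observed variables each trial type fits
fitted_variables <- function(trial_type) {
  switch(trial_type,
         go = c("mep_t1", "mep_t2", "mep_t3", "emg_onsets", "emg_offsets"),
         gs = c("mep_t1", "mep_t2", "mep_t3", "emg_onsets", "emg_rates"),
         sst = "rts",
         stop("unknown trial type: ", trial_type))
}

predicted_values <- function(trials, trial_type) {
  cr <- trials$crossed
  out <- list(mep_t1 = trials$mep_t1, mep_t2 = trials$mep_t2,
              mep_t3 = trials$mep_t3)
  out$emg_onsets <- trials$onset[cr]
  out$emg_offsets <- trials$offset[cr & !is.na(trials$offset)]
  out$emg_rates <- trials$rate[cr & !is.na(trials$rate)]
  if (!is.null(trials$rt)) out$rts <- trials$rt[cr]
  out[fitted_variables(trial_type)]
}

# per-variable chi-square table for a set of predictions against an
# observed dataset; predictions are scaled to the observed count and
# floored at `eps` counts
chi2_table <- function(observed, preds, trial_type, eps = 0.5,
                       penalty = 1e6) {
  vars <- fitted_variables(trial_type)
  chi2 <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    obs <- observed$variables[[v]]
    if (is.null(obs)) stop("observed dataset lacks variable ", v)
    pv <- preds[[v]]
    if (is.null(pv) || length(pv) == 0L)
      return(list(per_variable = chi2, summed = penalty, penalised = TRUE))
    edges <- tertile_edges(obs)
    o <- bin_counts(obs, edges)
    p <- bin_counts(pv, edges) / length(pv) * length(obs)
    chi2[[v]] <- pearson_chi2(o, pmax(p, eps))
  }
  list(per_variable = chi2, summed = sum(chi2), penalised = FALSE)
}

#' Chi-square objective for a fit mode
#'
#' Builds the function minimised by [fit_model()]: it assembles a model
#' from a free-parameter vector, runs the Monte-Carlo simulator with a
#' fixed seed (common random numbers across evaluations, which makes the
#' stochastic objective quasi-smooth for Nelder-Mead), bins the predictions
#' with the observed data's tertile edges, and returns the summed Pearson
#' chi-square.  If no simulated trial crosses threshold while onset
#' variables are being fitted, a large penalty value is returned instead of
#' an error so the optimizer can back away.
#'
#' @param mode Fit mode; see [fit_model()].
#' @param observed An [observed_dataset()].
#' @param config A [simulation_config()]; its `seed` is the common-random-
#'   numbers base seed and its `n_trials` the per-evaluation simulation
#'   size.
#' @param frozen Frozen go-fit [model_spec()] for the `gs_*` and `sst`
#'   modes.
#' @param penalty Value returned when predictions are empty (default 1e6).
#' @return A function of one numeric vector returning the summed
#'   chi-square.
#' @export
ri_objective <- function(mode, observed, config, frozen = NULL,
                         penalty = 1e6) {
  mode <- match.arg(mode, names(fit_modes()))
  stopifnot(inherits(observed, "observed_dataset"))
  trial_type <- fit_modes()[[mode]]$trial_type
  if (observed$trial_type != trial_type)
    stop("observed dataset is for trial type '", observed$trial_type,
         "' but mode ", mode, " fits '", trial_type, "'")
  force(config); force(frozen)
  function(par) {
    spec <- tryCatch(spec_from_par(mode, par, frozen),
                     error = function(e) NULL)
    if (is.null(spec)) return(penalty)
    trials <- tryCatch(run_mode(mode, spec, config),
                       error = function(e) NULL)
    if (is.null(trials)) return(penalty)
    preds <- predicted_values(trials, trial_type)
    chi2_table(observed, preds, trial_type, penalty = penalty)$summed
  }
}

#' Fit a model by multi-start Nelder-Mead
#'
#' Minimises the tertile-binned summed Pearson chi-square over the free
#' parameters of one fit mode:
#'
#' * `go_hrm` (7 free): go facilitation (mean, SD of a, b, c) and the fixed
#'   decision threshold.
#' * `go_atm` (8 free): go facilitation plus tonic inhibition (mean, SD).
#' * `gs_hrm` (6 free): the stop-process Gaussian; facilitation and
#'   decision threshold frozen at their go-fit values.
#' * `gs_atm` (6 free): step inhibition (`k_inh`, `tau_inh`, `step_t` mean
#'   and SD) and the secondary facilitation peak time (mean, SD);
#'   facilitation and tonic inhibition frozen at their go-fit values.
#' * `sst` (2 free): the stop-signal-task peak-time distribution.
#'
#' Starting points are the supplied `init` plus, when `multistart = TRUE`,
#' `init` with each coordinate perturbed up and down (by 10 ms for
#' time-valued coordinates, 20% otherwise); the best converged start wins.
#' SD coordinates are interpreted through `abs()`, keeping the optimizer
#' unconstrained.
#'
#' @param mode One of `"go_hrm"`, `"go_atm"`, `"gs_hrm"`, `"gs_atm"`,
#'   `"sst"`.
#' @param observed An [observed_dataset()] for the matching trial type.
#' @param init Starting parameter vector; defaults to [fit_init()].
#' @param config A [simulation_config()] controlling the per-evaluation
#'   simulation size and the common-random-numbers seed.
#' @param frozen Frozen go-fit [model_spec()] (required for `gs_*` and
#'   `sst` modes).
#' @param multistart Use the perturbed start set (default) or only `init`.
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @param penalty Objective value substituted for degenerate evaluations.
#' @return An object of class `"ri_fit"`: best-fit parameters (`par`,
#'   named; SDs already made positive), the assembled `spec`, per-variable
#'   and summed chi-square, AIC (when defined), bookkeeping fields
#'   (`n_free`, `n_bins`, `mode`, convergence code) and a `starts` data
#'   frame tracing every start.
#' @export
fit_model <- function(mode, observed, init = fit_init(mode),
                      config = simulation_config(n_trials = 2000L, seed = 1L),
                      frozen = NULL, multistart = TRUE,
                      control = list(maxit = 400L), penalty = 1e6) {
  mode <- match.arg(mode, names(fit_modes()))
  info <- fit_modes()[[mode]]
  if (length(init) != length(info$par_names))
    stop("init must have length ", length(info$par_names), " for mode ", mode)
  init <- as.numeric(init)
  fn <- ri_objective(mode, observed, config, frozen, penalty = penalty)
  safe_fn <- function(par) {
    v <- fn(par)
    if (!is.finite(v)) penalty else v
  }

  starts <- list(init)
  if (multistart) {
    for (i in seq_along(init)) {
      delta <- if (i %in% info$time_idx) 0.010
               else if (init[i] != 0) 0.2 * abs(init[i]) else 0.01
      up <- init; up[i] <- up[i] + delta
      dn <- init; dn[i] <- dn[i] - delta
      starts <- c(starts, list(up, dn))
    }
  }

  runs <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, safe_fn, method = "Nelder-Mead",
                          control = control),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimisation starts failed")
  values <- vapply(runs[ok], function(r) r$value, numeric(1))
  best <- runs[ok][[which.min(values)]]

  par <- best$par
  par[info$sd_idx] <- abs(par[info$sd_idx])
  names(par) <- info$par_names
  spec <- spec_from_par(mode, par, frozen)
  trials <- run_mode(mode, spec, config)
  tab <- chi2_table(observed, predicted_values(trials, info$trial_type),
                    info$trial_type, penalty = penalty)
  p <- length(par)
  n_bins <- 3L * length(fitted_variables(info$trial_type))
  aic <- if (n_bins > p + 1) aic_chi2(tab$summed, p, n_bins) else NA_real_

  structure(list(
    mode = mode, par = par, spec = spec,
    per_variable_chi2 = tab$per_variable, summed_chi2 = tab$summed,
    aic = aic, n_free = p, n_bins = n_bins,
    convergence = best$convergence,
    starts = data.frame(start = seq_along(values), value = values),
    config = config,
    observed_fingerprint = observed_fingerprint(observed)
  ), class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Chi-square fit (", x$mode, "), ", x$n_free, " free parameters\n",
      sep = "")
  print(round(x$par, 4))
  cat("per-variable chi-square:\n")
  print(round(x$per_variable_chi2, 4))
  cat(sprintf("summed chi-square: %.4f", x$summed_chi2))
  if (!is.na(x$aic)) cat(sprintf("   AIC: %.4f", x$aic))
  cat("\n")
  invisible(x)
}

#' Compare two fitted models
#'
#' Side-by-side report of two fits of the same observed dataset:
#' per-variable and summed chi-square, AIC, and the preferred model (lower
#' AIC; lower summed chi-square when AIC is undefined for either).  Exact
#' equality is reported as a tie.  Fits of different datasets are an error.
#'
#' @param fit_a,fit_b `"ri_fit"` objects (or equivalent lists read back
#'   from JSON) fitted to the same observed dataset.
#' @return A list of class `"ri_comparison"` with a `table` data frame,
#'   `preferred` (`"a"`, `"b"` or `"tie"`) and the two modes.
#' @export
compare_models <- function(fit_a, fit_b) {
  fa <- unclass(fit_a); fb <- unclass(fit_b)
  for (f in list(fa, fb))
    if (is.null(f$summed_chi2) || is.null(f$observed_fingerprint))
      stop("inputs must be fit results with chi-square and dataset fingerprint")
  if (!identical(fa$observed_fingerprint, fb$observed_fingerprint))
    stop("fits are for different observed datasets")
  crit_a <- if (!is.null(fa$aic) && !is.na(fa$aic) &&
                !is.null(fb$aic) && !is.na(fb$aic)) fa$aic else fa$summed_chi2
  crit_b <- if (!is.null(fa$aic) && !is.na(fa$aic) &&
                !is.null(fb$aic) && !is.na(fb$aic)) fb$aic else fb$summed_chi2
  preferred <- if (isTRUE(all.equal(crit_a, crit_b))) "tie"
               else if (crit_a < crit_b) "a" else "b"
  vars <- union(names(fa$per_variable_chi2), names(fb$per_variable_chi2))
  table <- data.frame(
    variable = c(vars, "summed", "AIC"),
    a = c(unlist(fa$per_variable_chi2)[vars], fa$summed_chi2,
          fa$aic %||% NA_real_),
    b = c(unlist(fb$per_variable_chi2)[vars], fb$summed_chi2,
          fb$aic %||% NA_real_),
    row.names = NULL
  )
  names(table)[2:3] <- c(fa$mode %||% "a", fb$mode %||% "b")
  structure(list(table = table, preferred = preferred,
                 modes = c(fa$mode %||% NA, fb$mode %||% NA)),
            class = "ri_comparison")
}

#' @export
print.ri_comparison <- function(x, ...) {
  cat("Model comparison\n")
  print(x$table, row.names = FALSE)
  cat("preferred:",
      switch(x$preferred, tie = "tie",
             a = paste0(x$modes[1], " (first)"),
             b = paste0(x$modes[2], " (second)")), "\n")
  invisible(x)
}
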