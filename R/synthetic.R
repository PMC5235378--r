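# Pseudo-empirical dataset generators.  These emulate the published summary
# distributions of the anticipatory response inhibition dataset (aggregated
# group data, nondominant hand) so that fitting and model comparison are
# fully testable without access to the original recordings, plus a
# forward-simulation generator for parameter-recovery studies.

#' Empirical summary distributions
#'
#' Per-variable (mean, spread) descriptions of the observed go and partial
#' (GS) trial data.  MEP spreads are published as standard errors over 15
#' participants, so the trial-level generator SD is `spread * sqrt(15)`
#' when `mep_spread_kind = "se15"` (the default interpretation); EMG
#' spreads are treated as trial-level SDs (they are far too large to be
#' between-subject standard errors given the task's known 20-30 ms go
#' spread).  Set `mep_spread_kind = "sd"` to treat the MEP spreads as
#' trial-level SDs instead.
#'
#' @param mep_spread_kind `"se15"` (default) or `"sd"`.
#' @return A list of class `"empirical_summary"`.
#' @name empirical_summaries
NULL

#' @rdname empirical_summaries
#' @export
empirical_summary_go <- function(mep_spread_kind = c("se15", "sd")) {
  mep_spread_kind <- match.arg(mep_spread_kind)
  structure(list(
    trial_type = "go",
    mep = data.frame(time = c(-0.150, -0.125, -0.100),
                     mean = c(0.17, 0.44, 0.74),
                     spread = c(0.02, 0.11, 0.18)),
    mep_spread_kind = mep_spread_kind,
    onset = c(mean = -0.050, sd = 0.035),
    duration = c(mean = 0.107, sd = 0.038),
    n_trials = 514L
  ), class = "empirical_summary")
}

#' @rdname empirical_summaries
#' @export
empirical_summary_gs <- function(mep_spread_kind = c("se15", "sd")) {
  mep_spread_kind <- match.arg(mep_spread_kind)
  structure(list(
    trial_type = "gs",
    mep = data.frame(time = c(-0.075, -0.050, -0.025),
                     mean = c(0.18, 0.33, 0.44),
                     spread = c(0.03, 0.11, 0.05)),
    mep_spread_kind = mep_spread_kind,
    onset = c(mean = 0.025, sd = 0.046),
    rate = c(mean = 6.8, sd = 1.2),
    n_trials = 258L
  ), class = "empirical_summary")
}

mep_sd <- function(summary) {
  if (summary$mep_spread_kind == "se15") summary$mep$spread * sqrt(15)
  else summary$mep$spread
}

#' Generate a pseudo-empirical go-trial dataset
#'
#' Draws trial-level MEP amplitudes at the three go stimulation times
#' (negative draws redrawn), EMG onsets, and EMG offsets constructed as
#' onset plus a positive burst duration, matching the published summary
#' distributions.
#'
#' @param summary An [empirical_summary_go()] description.
#' @param n Number of trials (defaults to the published 514).
#' @param seed Integer seed; generation is deterministic under a fixed
#'   seed.
#' @return An [observed_dataset()] for trial type `"go"`.
#' @examples
#' obs <- generate_observed_go(seed = 1)
#' mean(obs$variables$mep_t1)  # about 0.17 mV
#' @export
generate_observed_go <- function(summary = empirical_summary_go(),
                                 n = summary$n_trials, seed = NULL) {
  stopifnot(inherits(summary, "empirical_summary"),
            summary$trial_type == "go", is_number(n), n >= 1)
  n <- as.integer(n)
  sds <- mep_sd(summary)
  with_seed(seed, {
    meps <- lapply(seq_len(nrow(summary$mep)), function(i)
      rnorm_pos(n, summary$mep$mean[i], sds[i]))
    onsets <- stats::rnorm(n, summary$onset["mean"], summary$onset["sd"])
    durations <- rnorm_pos(n, summary$duration["mean"], summary$duration["sd"])
    observed_dataset(
      variables = list(mep_t1 = meps[[1]], mep_t2 = meps[[2]],
                       mep_t3 = meps[[3]], emg_onsets = onsets,
                       emg_offsets = onsets + durations),
      trial_type = "go", n_trials = n,
      stim_times = summary$mep$time)
  })
}

#' Generate a pseudo-empirical partial (GS) trial dataset
#'
#' As [generate_observed_go()] for the partial-trial variables: MEP
#' amplitudes at the delayed stimulation times, EMG onsets (delayed past
#' the target), and EMG onset rates.
#'
#' @param summary An [empirical_summary_gs()] description.
#' @param n Number of trials (defaults to the published 258).
#' @param seed Integer seed.
#' @return An [observed_dataset()] for trial type `"gs"`.
#' @export
generate_observed_gs <- function(summary = empirical_summary_gs(),
                                 n = summary$n_trials, seed = NULL) {
  stopifnot(inherits(summary, "empirical_summary"),
            summary$trial_type == "gs", is_number(n), n >= 1)
  n <- as.integer(n)
  sds <- mep_sd(summary)
  with_seed(seed, {
    meps <- lapply(seq_len(nrow(summary$mep)), function(i)
      rnorm_pos(n, summary$mep$mean[i], sds[i]))
    onsets <- stats::rnorm(n, summary$onset["mean"], summary$onset["sd"])
    rates <- rnorm_pos(n, summary$rate["mean"], summary$rate["sd"])
    observed_dataset(
      variables = list(mep_t1 = meps[[1]], mep_t2 = meps[[2]],
                       mep_t3 = meps[[3]], emg_onsets = onsets,
                       emg_rates = rates),
      trial_type = "gs", n_trials = n,
      stim_times = summary$mep$time)
  })
}

#' Skew-normal location and scale for target moments
#'
#' Solves for the location `xi` and scale `omega` of a skew-normal
#' distribution with shape `alpha` so that its mean and SD equal the
#' requested values: with `delta = alpha / sqrt(1 + alpha^2)`,
#' `omega = sd / sqrt(1 - 2 delta^2 / pi)` and
#' `xi = mean - omega delta sqrt(2 / pi)`.
#'
#' @param mean,sd Target mean and standard deviation.
#' @param shape Skew-normal shape parameter `alpha`.
#' @return A list with `xi`, `omega`, `alpha`, `delta`.
#' @export
skewnorm_moment_params <- function(mean, sd, shape) {
  stopifnot(is_number(mean), is_number(sd), sd > 0, is_number(shape))
  delta <- shape / sqrt(1 + shape^2)
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  xi <- mean - omega * delta * sqrt(2 / pi)
  list(xi = xi, omega = omega, alpha = shape, delta = delta)
}

#' Generate stop-signal-task go reaction times
#'
#' Samples a right-skewed skew-normal reaction-time distribution whose mean
#' and SD match the published stop-signal-task values (0.472 s and
#' 0.049 s); the location and scale are solved analytically from the
#' requested moments at the given shape.  The shape is not pinned down by
#' the published summary, so it is configurable; 4 gives the clearly
#' right-skewed profile characteristic of choice reaction times.
#'
#' @param n Number of reaction times.
#' @param shape Skew-normal shape, must be > 0 (right-skewed).
#' @param seed Integer seed.
#' @param mean,sd Target moments in seconds.
#' @return Numeric vector of reaction times in seconds.
#' @examples
#' rt <- generate_sst_rts(1000, seed = 1)
#' c(mean(rt), sd(rt))
#' @export
generate_sst_rts <- function(n, shape = 4, seed = NULL,
                             mean = 0.472, sd = 0.049) {
  stopifnot(is_number(n), n >= 1)
  if (!is_number(shape) || shape <= 0)
    stop("shape must be > 0: the reaction-time distribution is right-skewed")
  p <- skewnorm_moment_params(mean, sd, shape)
  n <- as.integer(n)
  with_seed(seed, {
    u0 <- stats::rnorm(n)
    u1 <- stats::rnorm(n)
    z <- p$delta * abs(u0) + sqrt(1 - p$delta^2) * u1
    p$xi + p$omega * z
  })
}

#' Forward-simulate an observed dataset from known parameters
#'
#' Runs the requested simulator and repackages the predicted variables as
#' an [observed_dataset()], with the generating model attached as ground
#' truth — the harness for parameter-recovery studies: fitting the returned
#' dataset should recover the generating means.
#'
#' @param spec A [model_spec()].
#' @param trial_type `"go"`, `"gs"` or `"sst"`.
#' @param n Number of simulated trials packaged as observations.
#' @param config A [simulation_config()]; its `n_trials` and `seed` are
#'   overridden by `n` and `seed`.
#' @param seed Integer seed.
#' @return An [observed_dataset()] with attribute `"ground_truth"`.
#' @export
generate_from_model <- function(spec, trial_type = c("go", "gs", "sst"),
                                n = 514L, config = simulation_config(),
                                seed = NULL) {
  trial_type <- match.arg(trial_type)
  stopifnot(inherits(spec, "model_spec"), is_number(n), n >= 1)
  cfg <- config
  cfg$n_trials <- as.integer(n)
  cfg$seed <- seed
  trials <- switch(trial_type,
                   go = simulate_go(spec, cfg),
                   gs = if (spec$model == "hrm") simulate_partial_hrm(spec, cfg)
                        else simulate_partial_atm(spec, cfg),
                   sst = simulate_sst_go(spec, cfg))
  preds <- predicted_values(trials, trial_type)
  onset_vars <- intersect(c("emg_onsets", "emg_offsets", "emg_rates", "rts"),
                          names(preds))
  if (any(vapply(preds[onset_vars], length, integer(1)) == 0L))
    stop("no simulated trial crossed threshold; cannot package onset",
         " variables as observations")
  obs <- observed_dataset(variables = preds, trial_type = trial_type,
                          n_trials = as.integer(n))
  attr(obs, "ground_truth") <- spec
  obs
}
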