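# Monte-Carlo trial simulation.  Each simulator draws per-trial parameter
# values from their normal distributions, races the facilitatory drive
# against the model's threshold, and records the predicted counterparts of
# the experimental variables: MEP amplitudes at the stimulation times, EMG
# onset/offset times and EMG onset rates.

#' Draw per-trial parameter values
#'
#' Each distributional parameter of the model is drawn independently from a
#' normal distribution with its specified mean and SD.  Draws for
#' amplitudes, widths and tonic inhibition levels are redrawn until
#' positive.  Parameters are drawn one full vector at a time, in a fixed
#' order (facilitation a, b, c; tonic inhibition; stop process a, b, c;
#' step offset; secondary peak time), so that under a shared seed the
#' facilitation draws are identical across trial types of the same model —
#' the basis of the matched-seed comparisons between go and partial trials.
#'
#' @param spec A [model_spec()].
#' @param n_trials Number of trials to draw.
#' @param trial_type One of `"go"`, `"gs"`, `"stopboth"`, `"sst"`.
#' @param include_secondary Draw the secondary facilitation peak time on
#'   ATM partial trials?
#' @param seed Optional seed; `NULL` draws from the current RNG state.
#' @return A data frame with one row per trial.
#' @export
sample_trial_params <- function(spec, n_trials,
                                trial_type = c("go", "gs", "stopboth", "sst"),
                                include_secondary = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), is_number(n_trials), n_trials >= 1)
  trial_type <- match.arg(trial_type)
  n <- as.integer(n_trials)
  with_seed(seed, {
    f <- spec$facilitation
    draws <- list(
      fac_a = rnorm_pos(n, f$amplitude[1], f$amplitude[2]),
      fac_b = stats::rnorm(n, f$peak_time[1], f$peak_time[2]),
      fac_c = rnorm_pos(n, f$width[1], f$width[2])
    )
    th <- spec$threshold
    if (th$kind %in% c("tonic-sampled", "step"))
      draws$inhib <- rnorm_pos(n, th$tonic[1], th$tonic[2])
    if (spec$model == "hrm" && trial_type == "gs") {
      if (is.null(spec$stop_process))
        stop("HRM partial trials require a stop_process in the model spec")
      s <- spec$stop_process
      draws$stop_a <- rnorm_pos(n, s$amplitude[1], s$amplitude[2])
      draws$stop_b <- stats::rnorm(n, s$peak_time[1], s$peak_time[2])
      draws$stop_c <- rnorm_pos(n, s$width[1], s$width[2])
    }
    if (spec$model == "atm" && trial_type %in% c("gs", "stopboth")) {
      if (th$kind != "step")
        stop("ATM partial/stop trials require a step threshold")
      draws$step_t <- stats::rnorm(n, th$step_t[1], th$step_t[2])
      if (include_secondary && trial_type == "gs") {
        if (is.null(spec$secondary_peak_time))
          stop("secondary facilitation requested but no secondary_peak_time",
               " in the model spec")
        draws$bnew <- stats::rnorm(n, spec$secondary_peak_time[1],
                                   spec$secondary_peak_time[2])
      }
    }
    as.data.frame(draws)
  })
}

# assemble the per-trial record data frame
make_trials <- function(trial_type, crossed, onset, offset, mep, rate,
                        params, stim_times, rt = NULL) {
  colnames(mep) <- paste0("mep_t", seq_len(ncol(mep)))
  df <- data.frame(trial_type = trial_type, crossed = crossed,
                   onset = onset, offset = offset, mep, rate = rate)
  if (!is.null(rt)) df$rt <- rt
  attr(df, "stim_times") <- stim_times
  attr(df, "sampled_params") <- params
  class(df) <- c("ri_trials", "data.frame")
  df
}

#' Simulate go trials
#'
#' On go trials the facilitatory drive races against a constant threshold:
#' the fixed decision threshold in the HRM, or a per-trial tonic inhibition
#' level in the ATM.  The predicted EMG onset is the upward crossing, the
#' offset is the downward recrossing (or onset plus the empirical burst
#' duration, per `config$offset_mode`), and the predicted MEP amplitude at
#' each stimulation time is the facilitation value (inhibition shows no
#' rise above baseline on go trials), floored at zero.  Crossings are
#' computed in closed form; trials whose drive never reaches the threshold
#' inside the time window are recorded as not crossed.
#'
#' @param spec A [model_spec()] with a `"fixed-decision"` (HRM) or
#'   `"tonic-sampled"` (ATM) threshold.
#' @param config A [simulation_config()].
#' @return An `ri_trials` data frame, one row per trial.
#' @examples
#' tr <- simulate_go(atm_go_spec(), simulation_config(n_trials = 500, seed = 1))
#' mean(tr$onset[tr$crossed])  # about -0.05 s
#' @export
simulate_go <- function(spec, config = simulation_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "simulation_config"))
  if (!spec$threshold$kind %in% c("fixed-decision", "tonic-sampled"))
    stop("go trials use a fixed decision threshold (HRM) or tonic inhibition (ATM)")
  n <- config$n_trials
  par <- sample_trial_params(spec, n, "go", seed = config$seed)
  thr <- if (spec$threshold$kind == "fixed-decision")
    rep(spec$threshold$fixed_value, n) else par$inhib
  sim_constant_threshold(spec, par, thr, config, trial_type = "go",
                         stim_times = config$stimulation_times_go)
}

# shared closed-form engine for drives racing a per-trial constant threshold
sim_constant_threshold <- function(spec, par, thr, config, trial_type,
                                   stim_times, stop_gauss = FALSE) {
  rng <- config$grid$time_range
  w <- gauss_halfwidth(par$fac_a, par$fac_c, thr)
  onset <- par$fac_b - w
  crossed <- !is.na(onset) & onset >= rng[1] & onset <= rng[2]
  if (stop_gauss) {
    ws <- gauss_halfwidth(par$stop_a, par$stop_c, thr)
    t_stop <- par$stop_b - ws
    stop_crosses <- !is.na(t_stop) & t_stop >= rng[1] & t_stop <= rng[2]
    # the responding hand only moves if facilitation wins the race
    crossed <- crossed & (!stop_crosses | onset < t_stop)
  }
  offset <- switch(config$offset_mode,
                   recross = par$fac_b + w,
                   `onset-plus-duration` = onset + config$burst_duration)
  rate <- config$rate_calibration * thr * w / par$fac_c^2
  onset[!crossed] <- NA_real_
  offset[!crossed] <- NA_real_
  rate[!crossed] <- NA_real_
  mep <- vapply(stim_times, function(ts) {
    v <- gauss_val(par$fac_a, par$fac_b, par$fac_c, ts)
    if (stop_gauss) v <- v - gauss_val(par$stop_a, par$stop_b, par$stop_c, ts)
    pmax(v, 0)
  }, numeric(nrow(par)))
  mep <- matrix(mep, nrow = nrow(par))
  make_trials(trial_type, crossed, onset, offset, mep, rate, par, stim_times)
}

#' Simulate partial (GS) trials under the horse-race model
#'
#' The stop cue launches an independent inhibitory (stop) process, a
#' Gaussian drive racing the facilitatory (go) process to the same fixed
#' decision threshold.  The responding hand moves only if facilitation
#' reaches the threshold first; its onset is then the same facilitation
#' crossing as on go trials — the model has no way to delay it.  Predicted
#' MEP amplitude is the facilitation minus the stop-process level, floored
#' at zero, and the onset rate is the calibrated facilitation slope at the
#' crossing.
#'
#' @param spec A [model_spec()] with `model = "hrm"` and a `stop_process`.
#' @inheritParams simulate_go
#' @return An `ri_trials` data frame.
#' @export
simulate_partial_hrm <- function(spec, config = simulation_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "simulation_config"))
  if (spec$model != "hrm") stop("spec must be a horse-race model")
  if (is.null(spec$stop_process)) stop("missing stop_process in model spec")
  n <- config$n_trials
  par <- sample_trial_params(spec, n, "gs", seed = config$seed)
  thr <- rep(spec$threshold$fixed_value, n)
  sim_constant_threshold(spec, par, thr, config, trial_type = "gs",
                         stim_times = config$stimulation_times_gs,
                         stop_gauss = TRUE)
}

#' Simulate partial (GS) trials under the activation threshold model
#'
#' The stop cue nonselectively raises the activation threshold: per trial
#' the threshold is the sampled step-inhibition curve (tonic baseline plus
#' an exponential rise of size `k_inh`, time constant `tau_inh`, starting
#' at `-step_t`).  The drive is the primary facilitation plus, when
#' `include_secondary = TRUE`, a secondary facilitation sharing its
#' amplitude and width (the reprogrammed unimanual response).  Onsets and
#' offsets are located on the time grid with linear interpolation; the
#' predicted MEP is the drive minus the rise of inhibition above baseline,
#' floored at zero; the onset rate is the calibrated drive slope at the
#' crossing.
#'
#' With the reference parameters and no secondary drive, no trial crosses
#' the elevated threshold — the model's case for requiring a second
#' activation process.
#'
#' `go_params` controls how the go-derived components (facilitation a, b, c
#' and the tonic baseline) enter stop-cued trials.  The default `"mean"`
#' freezes them at their fitted means, drawing only the partial-trial
#' parameters (`step_t` and the secondary peak time) per trial: only the
#' parameters estimated in the partial-trial fit carry trial-to-trial
#' variability, and the combined drive's narrow clearance over the elevated
#' threshold is preserved, so essentially every trial produces the delayed
#' response and complete cancellation produces none.  `"sampled"` redraws
#' the go components per trial as on go trials; because the drive maximum
#' clears the threshold asymptote by less than one trial-SD of the drawn
#' width, a large minority of trials then fail to cross.  `"sampled"` is
#' the mode under which `k_inh = 0` with no secondary drive degenerates
#' exactly to [simulate_go()] at a shared seed.  See the package vignette
#' for the full rationale.
#'
#' @param spec A [model_spec()] with `model = "atm"` and a `"step"`
#'   threshold.
#' @inheritParams simulate_go
#' @param include_secondary Add the secondary facilitatory drive?
#' @param mep_includes_secondary Should the predicted MEP use the combined
#'   drive (default) or the primary facilitation alone?
#' @param go_params `"mean"` (default) or `"sampled"`; see Details.
#' @return An `ri_trials` data frame.
#' @export
simulate_partial_atm <- function(spec, config = simulation_config(),
                                 include_secondary = TRUE,
                                 mep_includes_secondary = include_secondary,
                                 go_params = c("mean", "sampled")) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "simulation_config"))
  if (spec$model != "atm") stop("spec must be an activation threshold model")
  if (spec$threshold$kind != "step") stop("ATM partial trials need a step threshold")
  if (mep_includes_secondary && !include_secondary)
    stop("mep_includes_secondary requires include_secondary = TRUE")
  go_params <- match.arg(go_params)
  n <- config$n_trials
  trial_type <- if (include_secondary) "gs" else "stopboth"
  par <- sample_trial_params(spec, n, trial_type = trial_type,
                             include_secondary = include_secondary,
                             seed = config$seed)
  if (go_params == "mean") {
    # go-fit components enter as fixed values; the RNG stream is unchanged
    # (draws are made, then replaced) so seeds stay comparable across modes
    par$fac_a[] <- spec$facilitation$amplitude[1]
    par$fac_b[] <- spec$facilitation$peak_time[1]
    par$fac_c[] <- spec$facilitation$width[1]
    par$inhib[] <- spec$threshold$tonic[1]
  }
  times <- time_grid(config$grid)
  m <- length(times)
  k <- spec$threshold$k_inh
  tau <- spec$threshold$tau_inh
  onset <- offset <- rep(NA_real_, n)
  crossed <- logical(n)
  starts <- seq.int(1L, n, by = config$chunk_size)
  for (s in starts) {
    e <- min(s + config$chunk_size - 1L, n)
    ii <- s:e
    nc <- length(ii)
    tm <- matrix(times, nc, m, byrow = TRUE)
    drv <- par$fac_a[ii] * exp(-((tm - par$fac_b[ii])^2) / (2 * par$fac_c[ii]^2))
    if (include_secondary)
      drv <- drv + par$fac_a[ii] *
        exp(-((tm - par$bnew[ii])^2) / (2 * par$fac_c[ii]^2))
    tt <- tm + par$step_t[ii]
    rise <- k * (1 - exp(-tt / tau))
    rise[tt <= 0] <- 0
    cr <- first_crossing_mat(drv - (par$inhib[ii] + rise), times)
    crossed[ii] <- cr$crossed
    onset[ii] <- cr$onset
    offset[ii] <- cr$offset
  }
  if (config$offset_mode == "onset-plus-duration")
    offset <- onset + config$burst_duration
  stim_times <- config$stimulation_times_gs
  mep <- vapply(stim_times, function(ts) {
    v <- gauss_val(par$fac_a, par$fac_b, par$fac_c, ts)
    if (mep_includes_secondary)
      v <- v + gauss_val(par$fac_a, par$bnew, par$fac_c, ts)
    rise <- k * (1 - exp(-(ts + par$step_t) / tau))
    rise[ts + par$step_t <= 0] <- 0
    pmax(v - rise, 0)
  }, numeric(n))
  mep <- matrix(mep, nrow = n)
  slope <- gauss_slope_val(par$fac_a, par$fac_b, par$fac_c, onset)
  if (include_secondary)
    slope <- slope + gauss_slope_val(par$fac_a, par$bnew, par$fac_c, onset)
  rate <- config$rate_calibration * slope
  rate[!crossed] <- NA_real_
  make_trials(trial_type, crossed, onset, offset, mep, rate, par, stim_times)
}

#' Simulate stop-both trials under the activation threshold model
#'
#' A complete-cancellation (stop both hands) trial is a partial trial
#' without the secondary facilitatory drive: the elevated threshold is not
#' reached by the original go facilitation and no movement is generated.
#' Returns the fraction of trials whose drive crossed the threshold
#' (expected ~0 with the reference parameters) together with the per-trial
#' records.
#'
#' @inheritParams simulate_partial_atm
#' @return A list with `crossing_fraction` and `trials`.
#' @export
simulate_stop_both <- function(spec, config = simulation_config(),
                               go_params = c("mean", "sampled")) {
  trials <- simulate_partial_atm(spec, config, include_secondary = FALSE,
                                 mep_includes_secondary = FALSE,
                                 go_params = go_params)
  list(crossing_fraction = mean(trials$crossed), trials = trials)
}

#' Simulate go trials of the stop-signal task
#'
#' Go responses in the stop-signal task are reactions to an imperative cue,
#' so their peak-time distribution is wide; amplitude, width and tonic
#' inhibition are held at the anticipatory-task values and only the peak
#' time varies across trials.  The crossing time is reported as a reaction
#' time on the stop-signal-task scale, with the go signal at -0.400 s:
#' `rt = crossing + 0.400`.  No electromechanical delay is applied, so the
#' distribution pattern (not the absolute values) is the comparable
#' quantity.
#'
#' @param spec A [model_spec()] such as [sst_go_spec()].
#' @inheritParams simulate_go
#' @param go_signal_time Go-signal time on the anticipatory time scale
#'   (default -0.400 s).
#' @return An `ri_trials` data frame with an `rt` column (seconds).
#' @export
simulate_sst_go <- function(spec, config = simulation_config(),
                            go_signal_time = -0.400) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "simulation_config"))
  n <- config$n_trials
  par <- sample_trial_params(spec, n, "sst", seed = config$seed)
  thr <- if (spec$threshold$kind == "fixed-decision")
    rep(spec$threshold$fixed_value, n) else par$inhib
  trials <- sim_constant_threshold(spec, par, thr, config, trial_type = "sst",
                                   stim_times = config$stimulation_times_go)
  trials$rt <- trials$onset - go_signal_time
  trials
}

#' Summarise simulated trials
#'
#' Summary statistics over a set of simulated trials: the crossing
#' fraction, means and SDs of EMG onset, offset, burst duration and onset
#' rate over crossed trials, MEP amplitudes over all trials, and (when
#' present) reaction times.  The per-variable value lists feed the fitting
#' module.
#'
#' @param trials An `ri_trials` data frame.
#' @return A list with `n_trials`, `n_crossed`, `crossing_fraction`,
#'   a `stats` data frame (variable, mean, sd, n) and a `values` list.
#' @export
summarize_trials <- function(trials) {
  stopifnot(inherits(trials, "ri_trials"))
  if (nrow(trials) == 0L) stop("empty trial list")
  cr <- trials$crossed
  vals <- list()
  for (v in grep("^mep_t", names(trials), value = TRUE))
    vals[[v]] <- trials[[v]]
  vals$emg_onsets <- trials$onset[cr]
  vals$emg_offsets <- trials$offset[cr & !is.na(trials$offset)]
  vals$emg_durations <- (trials$offset - trials$onset)[cr & !is.na(trials$offset)]
  vals$emg_rates <- trials$rate[cr & !is.na(trials$rate)]
  if (!is.null(trials$rt)) vals$rts <- trials$rt[cr]
  vals <- Filter(length, vals)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  stats_df <- data.frame(
    variable = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, sd0, numeric(1)),
    n = vapply(vals, length, integer(1)),
    row.names = NULL
  )
  list(n_trials = nrow(trials), n_crossed = sum(cr),
       crossing_fraction = mean(cr), stats = stats_df, values = vals)
}
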