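#' Parameters of a Gaussian drive curve
#'
#' A single facilitatory or inhibitory process is modelled as a Gaussian
#' function of time, `a * exp(-(t - b)^2 / (2 c^2))`: `amplitude` is the
#' peak activation (in mV-equivalent units, commensurate with motor evoked
#' potential amplitudes), `peak_time` is when the drive peaks (seconds
#' relative to the response target; negative means before the target) and
#' `width` sets the curvature, i.e. how fast activation accumulates.
#'
#' @param amplitude Peak activation, > 0.
#' @param peak_time Time of the peak in seconds relative to the target.
#' @param width Gaussian width in seconds, > 0.
#' @return An object of class `"gaussian_params"`.
#' @seealso [eval_gaussian()], [onset_time()]
#' @examples
#' gaussian_params(amplitude = 2.576, peak_time = 0.006, width = 0.064)
#' @export
gaussian_params <- function(amplitude, peak_time, width) {
  stopifnot(is_number(amplitude), is_number(peak_time), is_number(width))
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (width <= 0) stop("width must be > 0")
  structure(list(amplitude = amplitude, peak_time = peak_time, width = width),
            class = "gaussian_params")
}

#' Distributional description of a Gaussian drive
#'
#' Between-trial variability in a drive is modelled by drawing each Gaussian
#' parameter independently from a normal distribution.  Each argument is a
#' `(mean, sd)` pair; amplitude and width must have positive means and their
#' per-trial draws are redrawn until positive.
#'
#' @param amplitude,peak_time,width Numeric `(mean, sd)` pairs.
#' @return An object of class `"gaussian_process_spec"`.
#' @examples
#' gaussian_process_spec(amplitude = c(2.576, 0.053),
#'                       peak_time = c(0.006, 0.008),
#'                       width     = c(0.064, 0.011))
#' @export
gaussian_process_spec <- function(amplitude, peak_time, width) {
  structure(list(
    amplitude = check_pair(amplitude, "amplitude", positive_mean = TRUE),
    peak_time = check_pair(peak_time, "peak_time"),
    width = check_pair(width, "width", positive_mean = TRUE)
  ), class = "gaussian_process_spec")
}

#' Step-inhibition parameters
#'
#' In the activation threshold model a stop cue raises inhibition as a
#' first-order step response: starting from the tonic `baseline`, inhibition
#' rises by `k_inh * (1 - exp(-(t + step_t) / tau_inh))` once `t > -step_t`.
#' `step_t` shifts the step onset and captures variability in stop-signal
#' processing time.
#'
#' @param baseline Tonic inhibition level (activation units), > 0.
#' @param k_inh Step size (activation units), >= 0.
#' @param tau_inh Time constant in seconds, > 0.
#' @param step_t Temporal offset of the step onset in seconds; the rise
#'   begins at `t = -step_t`.
#' @return An object of class `"step_inhibition_params"`.
#' @seealso [eval_step_inhibition()], [step_onset_latency()]
#' @export
step_inhibition_params <- function(baseline, k_inh, tau_inh, step_t) {
  stopifnot(is_number(baseline), is_number(k_inh), is_number(tau_inh),
            is_number(step_t))
  if (baseline <= 0) stop("baseline must be > 0")
  if (k_inh < 0) stop("k_inh must be >= 0")
  if (tau_inh <= 0) stop("tau_inh must be > 0")
  structure(list(baseline = baseline, k_inh = k_inh, tau_inh = tau_inh,
                 step_t = step_t),
            class = "step_inhibition_params")
}

#' Threshold specification
#'
#' The two models differ in what the facilitatory drive must exceed for a
#' response to be initiated:
#'
#' * `"fixed-decision"`: a single fixed decision threshold (horse-race
#'   model); supply `fixed_value`.
#' * `"tonic-sampled"`: a tonic inhibition level drawn per trial (activation
#'   threshold model, go trials); supply `tonic = c(mean, sd)`.
#' * `"step"`: tonic inhibition per trial plus a step rise triggered by the
#'   stop cue (activation threshold model, partial/stop trials); supply
#'   `tonic`, `k_inh`, `tau_inh` and `step_t = c(mean, sd)`.
#'
#' @param kind One of `"fixed-decision"`, `"tonic-sampled"`, `"step"`.
#' @param fixed_value Fixed decision threshold (activation units).
#' @param tonic `(mean, sd)` of the tonic inhibition level.
#' @param k_inh,tau_inh Step size and time constant (point values).
#' @param step_t `(mean, sd)` of the step onset offset in seconds.
#' @return An object of class `"threshold_spec"`.
#' @export
threshold_spec <- function(kind = c("fixed-decision", "tonic-sampled", "step"),
                           fixed_value = NULL, tonic = NULL,
                           k_inh = NULL, tau_inh = NULL, step_t = NULL) {
  kind <- match.arg(kind)
  out <- list(kind = kind)
  if (kind == "fixed-decision") {
    stopifnot(is_number(fixed_value))
    if (fixed_value <= 0) stop("fixed_value must be > 0")
    out$fixed_value <- fixed_value
  } else {
    out$tonic <- check_pair(tonic, "tonic", positive_mean = TRUE)
    if (kind == "step") {
      stopifnot(is_number(k_inh), is_number(tau_inh))
      if (k_inh < 0) stop("k_inh must be >= 0")
      if (tau_inh <= 0) stop("tau_inh must be > 0")
      out$k_inh <- k_inh
      out$tau_inh <- tau_inh
      out$step_t <- check_pair(step_t, "step_t")
    }
  }
  structure(out, class = "threshold_spec")
}

#' Time grid and onset conventions
#'
#' Curves are evaluated across a fixed window around the response target;
#' `min_threshold` is the activation level used to define the nominal onset
#' time of a Gaussian curve (a rise above resting corticomotor excitability,
#' in the same mV-equivalent units as the curves).
#'
#' @param min_threshold Minimum activation defining curve onset; default 0.1.
#' @param time_range Two-element window in seconds relative to the target;
#'   default `c(-0.400, 0.200)`.
#' @param grid_step Grid resolution in seconds; default 0.001.
#' @return An object of class `"onset_constants"`.
#' @export
onset_constants <- function(min_threshold = 0.1,
                            time_range = c(-0.400, 0.200),
                            grid_step = 0.001) {
  stopifnot(is_number(min_threshold), min_threshold > 0,
            is.numeric(time_range), length(time_range) == 2L,
            time_range[1] < time_range[2],
            is_number(grid_step), grid_step > 0)
  structure(list(min_threshold = min_threshold,
                 time_range = as.numeric(time_range),
                 grid_step = grid_step),
            class = "onset_constants")
}

time_grid <- function(constants) {
  seq(constants$time_range[1], constants$time_range[2],
      by = constants$grid_step)
}

#' Model specification
#'
#' Bundles the distributional components of one model/trial-type
#' combination.
#'
#' @param model `"atm"` (activation threshold model) or `"hrm"` (horse-race
#'   model).
#' @param facilitation A [gaussian_process_spec()] for the primary
#'   (bimanual go) facilitatory drive.
#' @param threshold A [threshold_spec()]; the HRM requires
#'   `"fixed-decision"`, the ATM `"tonic-sampled"` (go) or `"step"`
#'   (partial/stop trials).
#' @param secondary_peak_time Optional `(mean, sd)` of the peak time of the
#'   secondary (reprogrammed unimanual) facilitation on ATM partial trials;
#'   its amplitude and width are shared with the primary drive.
#' @param stop_process Optional [gaussian_process_spec()] for the HRM stop
#'   process on partial trials.
#' @return An object of class `"model_spec"`.
#' @examples
#' atm_go_spec()
#' hrm_gs_spec()
#' @export
model_spec <- function(model = c("atm", "hrm"), facilitation, threshold,
                       secondary_peak_time = NULL, stop_process = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(facilitation, "gaussian_process_spec"),
            inherits(threshold, "threshold_spec"))
  if (model == "hrm" && threshold$kind != "fixed-decision")
    stop("the horse-race model uses a fixed decision threshold")
  if (model == "atm" && threshold$kind == "fixed-decision")
    stop("the activation threshold model uses tonic or step inhibition")
  if (!is.null(secondary_peak_time)) {
    if (model != "atm")
      stop("secondary facilitation is only meaningful for the ATM")
    secondary_peak_time <- check_pair(secondary_peak_time,
                                      "secondary_peak_time")
  }
  if (!is.null(stop_process))
    stopifnot(inherits(stop_process, "gaussian_process_spec"))
  structure(list(model = model, facilitation = facilitation,
                 threshold = threshold,
                 secondary_peak_time = secondary_peak_time,
                 stop_process = stop_process),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", toupper(x$model), "\n")
  f <- x$facilitation
  cat(sprintf("  facilitation: a = %.3f (%.3f), b = %.3f (%.3f), c = %.3f (%.3f)\n",
              f$amplitude[1], f$amplitude[2], f$peak_time[1], f$peak_time[2],
              f$width[1], f$width[2]))
  th <- x$threshold
  cat("  threshold:", th$kind)
  if (th$kind == "fixed-decision") cat(sprintf(" = %.3f\n", th$fixed_value))
  else cat(sprintf(", tonic = %.3f (%.3f)\n", th$tonic[1], th$tonic[2]))
  if (th$kind == "step")
    cat(sprintf("  step: k = %.3f, tau = %.3f, step_t = %.3f (%.3f)\n",
                th$k_inh, th$tau_inh, th$step_t[1], th$step_t[2]))
  if (!is.null(x$secondary_peak_time))
    cat(sprintf("  secondary peak time: %.3f (%.3f)\n",
                x$secondary_peak_time[1], x$secondary_peak_time[2]))
  if (!is.null(x$stop_process)) {
    s <- x$stop_process
    cat(sprintf("  stop process: a = %.3f (%.3f), b = %.3f (%.3f), c = %.3f (%.3f)\n",
                s$amplitude[1], s$amplitude[2], s$peak_time[1], s$peak_time[2],
                s$width[1], s$width[2]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reference parameter sets.  These are the best-fit estimates for the
# nondominant-hand anticipatory response inhibition dataset the models were
# developed against; they double as sensible defaults and as optimisation
# starting points.

#' Reference model specifications
#'
#' Best-fit parameter sets for the anticipatory response inhibition (ARI)
#' task (nondominant hand, aggregated group data) under each model and trial
#' type, and for go trials of the stop-signal task (SST).  `atm_go_spec()`
#' and `hrm_go_spec()` describe go trials; `atm_gs_spec()` and
#' `hrm_gs_spec()` describe partial (go-left / stop-right, "GS") trials;
#' `sst_go_spec()` reuses the ATM go amplitude, width and tonic threshold
#' with an SST-specific peak-time distribution.
#'
#' @return A [model_spec()].
#' @name reference_specs
NULL

#' @rdname reference_specs
#' @export
atm_go_spec <- function() {
  model_spec("atm",
             facilitation = gaussian_process_spec(amplitude = c(2.576, 0.053),
                                                  peak_time = c(0.006, 0.008),
                                                  width = c(0.064, 0.011)),
             threshold = threshold_spec("tonic-sampled",
                                        tonic = c(1.798, 0.246)))
}

#' @rdname reference_specs
#' @export
hrm_go_spec <- function() {
  model_spec("hrm",
             facilitation = gaussian_process_spec(amplitude = c(2.342, 0.323),
                                                  peak_time = c(0.007, 0.021),
                                                  width = c(0.066, 0.010)),
             threshold = threshold_spec("fixed-decision", fixed_value = 1.659))
}

#' @rdname reference_specs
#' @export
atm_gs_spec <- function() {
  model_spec("atm",
             facilitation = gaussian_process_spec(amplitude = c(2.576, 0.053),
                                                  peak_time = c(0.006, 0.008),
                                                  width = c(0.064, 0.011)),
             threshold = threshold_spec("step", tonic = c(1.798, 0.246),
                                        k_inh = 1.887, tau_inh = 0.060,
                                        step_t = c(0.133, 0.018)),
             secondary_peak_time = c(0.108, 0.002))
}

#' @rdname reference_specs
#' @export
hrm_gs_spec <- function() {
  model_spec("hrm",
             facilitation = gaussian_process_spec(amplitude = c(2.342, 0.323),
                                                  peak_time = c(0.007, 0.021),
                                                  width = c(0.066, 0.010)),
             threshold = threshold_spec("fixed-decision", fixed_value = 1.659),
             stop_process = gaussian_process_spec(amplitude = c(1.644, 0.177),
                                                  peak_time = c(0.015, 0.008),
                                                  width = c(0.087, 0.009)))
}

#' @rdname reference_specs
#' @export
sst_go_spec <- function() {
  model_spec("atm",
             facilitation = gaussian_process_spec(amplitude = c(2.576, 0),
                                                  peak_time = c(0.129, 0.048),
                                                  width = c(0.064, 0)),
             threshold = threshold_spec("tonic-sampled", tonic = c(1.798, 0)))
}

#' Simulation configuration
#'
#' Settings shared by all Monte-Carlo simulators.
#'
#' @param n_trials Number of simulated trials (default 100,000).
#' @param seed Integer seed; every simulator is bit-reproducible under a
#'   fixed seed.  `NULL` uses the current RNG state.
#' @param grid An [onset_constants()] object defining the time window and
#'   grid resolution.
#' @param stimulation_times_go Stimulation times (s, relative to target) at
#'   which go-trial MEP amplitudes are predicted.
#' @param stimulation_times_gs Stimulation times for partial (GS) trials.
#' @param burst_duration Empirical mean EMG burst duration in seconds, used
#'   when `offset_mode = "onset-plus-duration"`.
#' @param offset_mode How predicted EMG offsets are generated: the time the
#'   drive recrosses the threshold (`"recross"`, default) or onset plus the
#'   fixed empirical burst duration (`"onset-plus-duration"`).
#' @param rate_calibration Scalar mapping the model's drive slope at
#'   threshold crossing onto EMG onset rates in mV/s; see
#'   [default_rate_calibration()].
#' @param stop_signal_time Stop-signal time on partial trials (s, relative
#'   to target); fixed at -0.250.
#' @param chunk_size Trials per block in the grid-based simulators (memory
#'   / speed trade-off only; no effect on results).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_trials = 100000L, seed = NULL,
                              grid = onset_constants(),
                              stimulation_times_go = c(-0.150, -0.125, -0.100),
                              stimulation_times_gs = c(-0.075, -0.050, -0.025),
                              burst_duration = 0.107,
                              offset_mode = c("recross", "onset-plus-duration"),
                              rate_calibration = default_rate_calibration(),
                              stop_signal_time = -0.250,
                              chunk_size = 5000L) {
  offset_mode <- match.arg(offset_mode)
  stopifnot(is_number(n_trials), n_trials >= 1,
            inherits(grid, "onset_constants"),
            is.numeric(stimulation_times_go), length(stimulation_times_go) >= 1,
            is.numeric(stimulation_times_gs), length(stimulation_times_gs) >= 1,
            is_number(burst_duration), burst_duration > 0,
            is_number(rate_calibration), rate_calibration > 0,
            is_number(stop_signal_time), is_number(chunk_size), chunk_size >= 1)
  rng <- grid$time_range
  if (any(stimulation_times_go < rng[1] | stimulation_times_go > rng[2]) ||
      any(stimulation_times_gs < rng[1] | stimulation_times_gs > rng[2]))
    stop("stimulation times must lie within the grid time range")
  if (!is.null(seed)) stopifnot(is_number(seed))
  structure(list(n_trials = as.integer(n_trials), seed = seed, grid = grid,
                 stimulation_times_go = stimulation_times_go,
                 stimulation_times_gs = stimulation_times_gs,
                 burst_duration = burst_duration, offset_mode = offset_mode,
                 rate_calibration = rate_calibration,
                 stop_signal_time = stop_signal_time,
                 chunk_size = as.integer(chunk_size)),
            class = "simulation_config")
}

#' Default EMG onset-rate calibration
#'
#' The models predict the rate of EMG onset as the slope of the facilitatory
#' drive where it crosses the threshold, in activation units per second.
#' Empirical rates are measured in mV/s, so a single scalar bridges the two
#' scales.  The default maps the mean-parameter ATM go-trial slope at
#' threshold crossing onto the empirical mean go-trial onset rate of
#' 5.6 mV/s; the same scalar is applied to partial trials, so the predicted
#' partial/go rate ratio is a genuine model output.
#'
#' @param target_go_rate Empirical mean go-trial EMG onset rate in mV/s.
#' @return The calibration scalar (mV/s per model slope unit).
#' @export
default_rate_calibration <- function(target_go_rate = 5.6) {
  spec <- atm_go_spec()
  a <- spec$facilitation$amplitude[1]
  c <- spec$facilitation$width[1]
  thr <- spec$threshold$tonic[1]
  w <- sqrt(-2 * c^2 * log(thr / a))
  slope <- thr * w / c^2  # drive slope at the upward crossing
  unname(target_go_rate / slope)
}
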