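# Closed-form evaluation of the facilitatory / inhibitory time-courses and
# threshold crossings.  All times are in seconds relative to the response
# target (negative = before the target); activation is in mV-equivalent
# units.

# bare-vector Gaussian helpers used throughout the simulators
gauss_val <- function(a, b, c, t) a * exp(-((t - b)^2) / (2 * c^2))
gauss_slope_val <- function(a, b, c, t) -((t - b) / c^2) * gauss_val(a, b, c, t)

# half-width of a Gaussian above level `thr`: distance from the peak to the
# level-thr crossing.  NA where the curve never reaches thr.
gauss_halfwidth <- function(a, c, thr) {
  w <- sqrt(pmax(-2 * c^2 * log(thr / a), 0))
  w[thr > a] <- NA_real_
  w
}

#' Evaluate a Gaussian drive curve
#'
#' @param params A [gaussian_params()] object.
#' @param t Time(s) in seconds relative to the target; vectorised.
#' @return Activation value(s), in `(0, amplitude]`.
#' @examples
#' p <- gaussian_params(2.576, 0.006, 0.064)
#' eval_gaussian(p, 0.006)   # peak: equals the amplitude
#' eval_gaussian(p, -0.150)  # early rise above resting excitability
#' @export
eval_gaussian <- function(params, t) {
  stopifnot(inherits(params, "gaussian_params"), is.numeric(t))
  gauss_val(params$amplitude, params$peak_time, params$width, t)
}

#' Slope of a Gaussian drive curve
#'
#' Analytic time-derivative of [eval_gaussian()].  The drive slope where the
#' curve meets the threshold indexes the gain of the response (the EMG onset
#' rate, after calibration to mV/s).
#'
#' @inheritParams eval_gaussian
#' @return Slope(s) in activation units per second: zero at the peak,
#'   positive before it, negative after.
#' @export
gaussian_slope <- function(params, t) {
  stopifnot(inherits(params, "gaussian_params"), is.numeric(t))
  gauss_slope_val(params$amplitude, params$peak_time, params$width, t)
}

#' Onset time of a Gaussian drive
#'
#' A Gaussian has infinite support, so the nominal onset of a drive is
#' defined as the earlier of the two times at which it reaches a minimum
#' activation level (0.1 by convention, denoting a rise above resting
#' corticomotor excitability).  In closed form,
#' `t0 = b - sqrt(-2 c^2 ln(threshold / a))`.
#'
#' @inheritParams eval_gaussian
#' @param threshold Activation level, `0 < threshold <= amplitude`.
#' @return The onset time in seconds.  When `threshold == amplitude` the
#'   peak just touches the level and the peak time is returned.
#' @examples
#' onset_time(gaussian_params(2.576, 0.006, 0.064), 0.1)  # about -0.157 s
#' @export
onset_time <- function(params, threshold = 0.1) {
  stopifnot(inherits(params, "gaussian_params"), is_number(threshold),
            threshold > 0)
  if (threshold > params$amplitude)
    stop("curve never reaches threshold (threshold > amplitude)")
  params$peak_time -
    sqrt(max(-2 * params$width^2 * log(threshold / params$amplitude), 0))
}

#' Evaluate the step-inhibition curve
#'
#' Inhibition rises from its tonic baseline in response to a step input
#' triggered by the stop cue: for `t > -step_t` the level is
#' `baseline + k_inh * (1 - exp(-(t + step_t) / tau_inh))`; before the step
#' onset it is clamped at the baseline (inhibition is a rise triggered by
#' the stop signal, not a decay before it).  The curve is monotone
#' non-decreasing and bounded above by `baseline + k_inh`.
#'
#' @param params A [step_inhibition_params()] object.
#' @param t Time(s) in seconds relative to the target; vectorised.
#' @return Inhibition level(s) in activation units.
#' @examples
#' p <- step_inhibition_params(1.798, 1.887, 0.060, 0.133)
#' eval_step_inhibition(p, -0.133)          # step onset: still baseline
#' eval_step_inhibition(p, -0.133 + 0.060)  # one time constant later
#' @export
eval_step_inhibition <- function(params, t) {
  stopifnot(inherits(params, "step_inhibition_params"), is.numeric(t))
  rise <- params$k_inh * (1 - exp(-(t + params$step_t) / params$tau_inh))
  rise[t <= -params$step_t] <- 0
  params$baseline + rise
}

#' Latency of the inhibitory step after the stop signal
#'
#' The step rise begins at `t = -step_t`; relative to a stop signal
#' presented at `stop_signal_time` the neural braking latency is
#' `-step_t - stop_signal_time`.
#'
#' @param params A [step_inhibition_params()] object.
#' @param stop_signal_time Stop-signal time in seconds relative to the
#'   target (default -0.250, the partial-trial stop time of the ARI task).
#' @return Latency in seconds.
#' @examples
#' step_onset_latency(step_inhibition_params(1.798, 1.887, 0.060, 0.133))
#' @export
step_onset_latency <- function(params, stop_signal_time = -0.250) {
  stopifnot(inherits(params, "step_inhibition_params"),
            is_number(stop_signal_time))
  -params$step_t - stop_signal_time
}

#' Combined primary and secondary facilitation
#'
#' On partial trials the activation threshold model adds a secondary
#' facilitatory drive (the reprogrammed unimanual response) to the
#' pre-existing primary (bimanual) drive at the level of the alpha
#' motoneuron pool.  The secondary curve shares its amplitude and width
#' with the primary; only its peak time differs.
#'
#' @param primary,secondary [gaussian_params()] objects.
#' @param t Time(s) in seconds; vectorised.
#' @return The summed activation, everywhere at least as large as either
#'   component alone.
#' @export
eval_combined_facilitation <- function(primary, secondary, t) {
  eval_gaussian(primary, t) + eval_gaussian(secondary, t)
}

#' First threshold crossing of a drive
#'
#' Finds the earliest time in the grid window at which a facilitatory drive
#' rises through a threshold (the predicted EMG onset), and the later time
#' at which it falls back through it (the predicted EMG offset).  The drive
#' and threshold may each be a vectorised function of time or a constant;
#' crossings are located on the grid and refined by linear interpolation, so
#' the error is well below the grid step.
#'
#' @param drive,threshold Vectorised functions of time, or single numeric
#'   constants.
#' @param constants An [onset_constants()] object defining the grid.
#' @return A list with elements `crossed` (logical), `onset` and `offset`
#'   (seconds, `NA` when absent).  `offset` is `NA` when the drive has not
#'   recrossed by the end of the window.
#' @examples
#' p <- gaussian_params(2.576, 0.006, 0.064)
#' first_crossing(function(t) eval_gaussian(p, t), 1.798)
#' @export
first_crossing <- function(drive, threshold, constants = onset_constants()) {
  stopifnot(inherits(constants, "onset_constants"))
  times <- time_grid(constants)
  ev <- function(f) {
    if (is.function(f)) {
      v <- f(times)
      if (length(v) != length(times))
        stop("drive/threshold functions must be vectorised over time")
      v
    } else {
      stopifnot(is_number(f))
      rep(f, length(times))
    }
  }
  d <- ev(drive) - ev(threshold)
  m <- length(d)
  h <- constants$grid_step
  up <- which(d[-1] > 0 & d[-m] <= 0)
  if (!length(up))
    return(list(crossed = FALSE, onset = NA_real_, offset = NA_real_))
  j <- up[1]
  onset <- times[j] + h * (-d[j]) / (d[j + 1] - d[j])
  dn <- which(d[-1] <= 0 & d[-m] > 0)
  dn <- dn[dn > j]
  offset <- if (length(dn)) {
    k <- dn[1]
    times[k] + h * d[k] / (d[k] - d[k + 1])
  } else NA_real_
  list(crossed = TRUE, onset = onset, offset = offset)
}

# Vectorised crossing finder for the grid-based simulators.  `d` is an
# n_trials x n_times matrix of (drive - threshold); returns interpolated
# onset (first upward sign change) and offset (first downward change after
# the onset) per row.
first_crossing_mat <- function(d, times) {
  n <- nrow(d)
  m <- ncol(d)
  h <- times[2] - times[1]
  idx <- seq_len(n)
  up <- d[, -1, drop = FALSE] > 0 & d[, -m, drop = FALSE] <= 0
  has_up <- rowSums(up) > 0
  j <- max.col(up, ties.method = "first")
  d0 <- d[cbind(idx, j)]
  d1 <- d[cbind(idx, j + 1L)]
  onset <- times[j] + h * (-d0) / (d1 - d0)
  onset[!has_up] <- NA_real_
  dn <- d[, -1, drop = FALSE] <= 0 & d[, -m, drop = FALSE] > 0
  jmat <- matrix(seq_len(m - 1L), n, m - 1L, byrow = TRUE)
  dn <- dn & (jmat > j)
  has_dn <- rowSums(dn) > 0 & has_up
  k <- max.col(dn, ties.method = "first")
  dk0 <- d[cbind(idx, k)]
  dk1 <- d[cbind(idx, k + 1L)]
  offset <- times[k] + h * dk0 / (dk0 - dk1)
  offset[!has_dn] <- NA_real_
  list(crossed = has_up, onset = onset, offset = offset)
}
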