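# Forward models of the per-event neural response amplitude.
#
# Both models map an event timing (duration, period) to a relative response
# amplitude placed at the event offset. Internally all timing is in seconds
# and frequency in Hz; interfaces report ms.

#' Parameters of the monotonic response model
#'
#' The monotonic model sums a duration component and a frequency component,
#' each compressed by an exponent in (0, 1]:
#' `amplitude = beta_dur * duration^exp_dur + beta_freq * frequency^(exp_freq - 1)`.
#' The per-event frequency amplitude carries the `- 1` because per-event
#' responses accumulate over the `frequency` events occurring each second, so
#' the summed-per-second response grows as `frequency^exp_freq`. Component
#' amplitudes are non-negative (monotonically decreasing responses are not
#' allowed); their ratio `beta_dur / beta_freq` is the amplitude ratio
#' reported at interfaces.
#'
#' @param exp_dur,exp_freq Compressive exponents in (0, 1].
#' @param beta_dur,beta_freq Non-negative component amplitudes.
#' @return An object of class `monotonic_params`.
#' @examples
#' monotonic_params(0.5, 0.5, 2, 1)
#' @export
monotonic_params <- function(exp_dur, exp_freq, beta_dur = 1, beta_freq = 1) {
  stopifnot(length(exp_dur) == 1, length(exp_freq) == 1)
  if (exp_dur <= 0 || exp_dur > 1 || exp_freq <= 0 || exp_freq > 1)
    stop("exponents must lie in (0, 1]")
  if (beta_dur < 0 || beta_freq < 0)
    stop("component amplitudes must be non-negative")
  structure(list(exp_dur = exp_dur, exp_freq = exp_freq,
                 beta_dur = beta_dur, beta_freq = beta_freq,
                 amplitude_ratio = if (beta_freq > 0) beta_dur / beta_freq
                                   else NA_real_),
            class = "monotonic_params")
}

#' Parameters of the timing-tuned response model
#'
#' The tuned model is a two-dimensional anisotropic Gaussian over event
#' (duration, period), centred on a preferred timing, with standard
#' deviations `sigma_major >= sigma_minor` along orthogonal axes rotated by
#' `theta`, multiplied by a compressive per-event frequency term
#' `frequency^(exp_freq - 1)`. Six free parameters.
#'
#' @param pref_duration_ms,pref_period_ms Preferred event duration/period (ms).
#' @param sigma_major_ms,sigma_minor_ms Gaussian extents (ms),
#'   `sigma_major_ms >= sigma_minor_ms > 0`.
#' @param theta_rad Major-axis orientation; the response is pi-periodic in
#'   theta, which is normalized to `[0, pi)`.
#' @param exp_freq Compressive exponent on frequency, in (0, 1].
#' @return An object of class `tuned_params`.
#' @examples
#' tuned_params(400, 700, 300, 150, 0.5, 0.4)
#' @export
tuned_params <- function(pref_duration_ms, pref_period_ms, sigma_major_ms,
                         sigma_minor_ms, theta_rad = 0, exp_freq = 1) {
  if (sigma_major_ms <= 0 || sigma_minor_ms <= 0)
    stop("sigma_major_ms and sigma_minor_ms must be positive")
  if (sigma_minor_ms > sigma_major_ms)
    stop("sigma_minor_ms must not exceed sigma_major_ms")
  if (exp_freq <= 0 || exp_freq > 1) stop("exp_freq must lie in (0, 1]")
  structure(list(pref_duration_ms = pref_duration_ms,
                 pref_period_ms = pref_period_ms,
                 sigma_major_ms = sigma_major_ms,
                 sigma_minor_ms = sigma_minor_ms,
                 theta_rad = theta_rad %% pi,
                 exp_freq = exp_freq),
            class = "tuned_params")
}

#' Per-event amplitude under the monotonic model
#'
#' @param timing A data.frame with `duration_ms` and `period_ms` columns
#'   (any number of rows), e.g. from [event_timing()] or [event_offsets()].
#' @param params A [monotonic_params()] object.
#' @return Numeric vector of non-negative relative amplitudes, one per row.
#' @examples
#' monotonic_event_amplitude(event_timing(250, 500),
#'                           monotonic_params(0.5, 0.5, 2, 1))
#' @export
monotonic_event_amplitude <- function(timing, params) {
  stopifnot(inherits(params, "monotonic_params"))
  if (any(timing$duration_ms <= 0) || any(timing$period_ms <= 0))
    stop("nonpositive duration or period")
  dur_s <- timing$duration_ms / 1000
  freq <- 1000 / timing$period_ms
  params$beta_dur * dur_s^params$exp_dur +
    params$beta_freq * freq^(params$exp_freq - 1)
}

#' Per-event amplitude under the tuned model
#'
#' Rotates the (duration, period) offset from the preferred timing into the
#' Gaussian's axes and evaluates
#' `exp(-0.5 * ((Y/sigma_major)^2 + (X/sigma_minor)^2)) * frequency^(exp_freq - 1)`.
#' The default `rotation_mode = "corrected"` uses the proper rotation
#' `X = dDur*cos(theta) - dPer*sin(theta)`, `Y = dDur*sin(theta) + dPer*cos(theta)`
#' so the major and minor axes are orthogonal; `"as_printed"` instead uses
#' `Y = dDur*sin(theta) - dPer*cos(theta)` (a reflection, not a rotation),
#' retained for literal comparison with the published formula.
#'
#' @param timing Data.frame with `duration_ms` and `period_ms` columns.
#' @param params A [tuned_params()] object.
#' @param rotation_mode `"corrected"` (default) or `"as_printed"`.
#' @return Numeric vector of non-negative relative amplitudes. The Gaussian
#'   factor lies in (0, 1] and equals 1 exactly at the preferred timing.
#' @examples
#' p <- tuned_params(400, 700, 300, 150, 0, 1)
#' tuned_event_amplitude(event_timing(400, 700), p)  # 1 at the peak
#' @export
tuned_event_amplitude <- function(timing, params,
                                  rotation_mode = c("corrected", "as_printed")) {
  stopifnot(inherits(params, "tuned_params"))
  rotation_mode <- match.arg(rotation_mode)
  if (any(timing$duration_ms <= 0) || any(timing$period_ms <= 0))
    stop("nonpositive duration or period")
  d_dur <- (timing$duration_ms - params$pref_duration_ms) / 1000
  d_per <- (timing$period_ms - params$pref_period_ms) / 1000
  th <- params$theta_rad
  x <- d_dur * cos(th) - d_per * sin(th)
  y <- if (rotation_mode == "corrected")
         d_dur * sin(th) + d_per * cos(th)
       else
         d_dur * sin(th) - d_per * cos(th)
  s_maj <- params$sigma_major_ms / 1000
  s_min <- params$sigma_minor_ms / 1000
  freq <- 1000 / timing$period_ms
  exp(-0.5 * ((y / s_maj)^2 + (x / s_min)^2)) * freq^(params$exp_freq - 1)
}

#' Per-event amplitude dispatch
#'
#' @param timing Data.frame with `duration_ms` and `period_ms` columns.
#' @param params A `monotonic_params` or `tuned_params` object.
#' @param ... Passed to the model-specific evaluator.
#' @return Numeric amplitude vector.
#' @export
event_amplitude <- function(timing, params, ...) {
  if (inherits(params, "monotonic_params"))
    monotonic_event_amplitude(timing, params)
  else if (inherits(params, "tuned_params"))
    tuned_event_amplitude(timing, params, ...)
  else stop("params must be monotonic_params or tuned_params")
}

#' Neural impulse train of a schedule under a response model
#'
#' One impulse per scheduled event, placed at the event offset, with the
#' model-predicted per-event amplitude.
#'
#' @param schedule A `condition_schedule` or `run_schedule`.
#' @param params A `monotonic_params` or `tuned_params` object.
#' @param ... Passed to [event_amplitude()].
#' @return Data.frame with `time_ms` and `amplitude` columns, in event order.
#' @export
neural_impulse_train <- function(schedule, params, ...) {
  off <- event_offsets(schedule)
  data.frame(time_ms = off$offset_ms,
             amplitude = event_amplitude(off, params, ...))
}

#' Serialize model parameter tables to TSV
#'
#' @param params_list List of `monotonic_params` or `tuned_params` objects
#'   (one kind per call).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params_tsv <- function(params_list, path) {
  rows <- lapply(params_list, function(p) as.data.frame(unclass(p)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
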