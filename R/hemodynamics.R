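# Hemodynamic forward step: two-gamma HRF kernel, impulse-train convolution,
# and the participant-level HRF refit.

HRF_SUPPORT_MS <- 30000

#' Two-gamma HRF parameters
#'
#' Difference-of-gammas impulse response: a positive peak gamma density minus
#' an undershoot gamma density divided by `undershoot_ratio`, normalized to
#' unit peak amplitude. Each gamma has shape `delay/dispersion` and scale
#' `dispersion`, so its mean equals the delay. Defaults are the canonical
#' peak 6 s / undershoot 16 s / dispersions 1 s / ratio 6 set.
#'
#' @param peak_delay_s Mean of the peak gamma (s).
#' @param undershoot_delay_s Mean of the undershoot gamma (s); must exceed
#'   `peak_delay_s`.
#' @param peak_dispersion_s,undershoot_dispersion_s Gamma scales (s).
#' @param undershoot_ratio Peak/undershoot amplitude ratio (> 0).
#' @return An object of class `hrf_params`.
#' @examples
#' hrf_params()
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                       undershoot_ratio = 6) {
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 ||
      peak_dispersion_s <= 0 || undershoot_dispersion_s <= 0 ||
      undershoot_ratio <= 0)
    stop("HRF delays, dispersions and ratio must be positive")
  if (undershoot_delay_s <= peak_delay_s)
    stop("undershoot_delay_s must exceed peak_delay_s")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 undershoot_ratio = undershoot_ratio),
            class = "hrf_params")
}

#' Sampled two-gamma HRF kernel
#'
#' Samples the difference-of-gammas kernel on a `dt_ms` grid over 0--30 s and
#' rescales it to unit maximum.
#'
#' @param params An [hrf_params()] object.
#' @param dt_ms Sampling step in ms; must divide the TR (2100 ms) evenly.
#' @return Numeric vector of kernel samples at `t = 0, dt, 2*dt, ...` (s
#'   support 0--30), with `max(kernel) == 1`.
#' @export
two_gamma_hrf <- function(params = hrf_params(), dt_ms = 10) {
  stopifnot(inherits(params, "hrf_params"))
  if (dt_ms <= 0 || (2100 %% dt_ms) != 0)
    stop("dt_ms must be positive and divide 2100 evenly")
  t_s <- seq(0, HRF_SUPPORT_MS / 1000, by = dt_ms / 1000)
  k <- stats::dgamma(t_s, shape = params$peak_delay_s / params$peak_dispersion_s,
                     scale = params$peak_dispersion_s) -
       stats::dgamma(t_s, shape = params$undershoot_delay_s /
                            params$undershoot_dispersion_s,
                     scale = params$undershoot_dispersion_s) /
         params$undershoot_ratio
  k / max(k)
}

#' Predicted BOLD time course from a neural impulse train
#'
#' Bins impulses on the `dt_ms` grid, convolves with the sampled two-gamma
#' kernel, and samples the result at TR onsets. The operator is linear in
#' the impulse amplitudes; internally both this function and the fitting
#' machinery route through the same kernel-lookup matrix
#' ([convolution_matrix()]), so simulated and fitted predictions share one
#' code path.
#'
#' @param impulses Data.frame with `time_ms` and `amplitude` columns.
#' @param hrf An [hrf_params()] object.
#' @param tr_ms Repetition time (ms).
#' @param n_tr Number of TRs in the run.
#' @param dt_ms Convolution grid step (ms).
#' @return Numeric vector of length `n_tr`.
#' @export
predict_bold <- function(impulses, hrf = hrf_params(), tr_ms = 2100,
                         n_tr, dt_ms = 10) {
  if (any(impulses$time_ms < 0) || any(impulses$time_ms >= n_tr * tr_ms))
    stop("impulses must lie within [0, n_tr * tr_ms)")
  if (nrow(impulses) == 0) return(numeric(n_tr))
  m <- convolution_matrix(impulses$time_ms, hrf, tr_ms = tr_ms, n_tr = n_tr,
                          dt_ms = dt_ms)
  as.numeric(m %*% impulses$amplitude)
}

#' Kernel-lookup convolution matrix
#'
#' Matrix `M` with `M[j, i] = h(t_j - floor(time_i / dt) * dt)` where `t_j`
#' are TR onsets and `h` the sampled kernel (zero outside 0--30 s). For any
#' amplitude vector `a`, `M %*% a` equals binning the impulses on the dt grid
#' and convolving with the kernel, sampled at TR onsets. This is the single
#' prediction path shared by the simulator and the fitter.
#'
#' @param time_ms Impulse times (ms).
#' @inheritParams predict_bold
#' @return `n_tr` x `length(time_ms)` matrix.
#' @export
convolution_matrix <- function(time_ms, hrf = hrf_params(), tr_ms = 2100,
                               n_tr, dt_ms = 10) {
  kernel <- two_gamma_hrf(hrf, dt_ms)
  tr_onsets <- (seq_len(n_tr) - 1) * tr_ms
  bin_ms <- floor(time_ms / dt_ms) * dt_ms
  lag <- outer(tr_onsets, bin_ms, "-")
  idx <- lag / dt_ms + 1
  ok <- idx >= 1 & idx <= length(kernel)
  m <- matrix(0, n_tr, length(time_ms))
  m[ok] <- kernel[idx[ok]]
  m
}

#' Refit HRF parameters for one participant
#'
#' Holds each voxel's fitted neural model fixed and searches HRF parameters
#' maximizing the summed variance explained over all voxels whose neural
#' model explained more than `ve_gate` of the variance, via coordinate-wise
#' pattern search from the current parameters. After this refit the neural
#' models should themselves be refit with the new HRF (one cycle).
#'
#' @param voxel_fits List of entries, each with `params` (a fitted
#'   `monotonic_params` or `tuned_params`), `data` (per-TR signal) and
#'   `ve_train` (training VE under the current HRF).
#' @param design A [timing_design()] (condition set and TR framing).
#' @param start An [hrf_params()] starting point (defaults).
#' @param ve_gate Training-VE gate for a voxel to inform the refit (0.10).
#' @param step_frac Initial search step as a fraction of each parameter.
#' @param tol Stop when all relative steps fall below this.
#' @return List with `hrf` (the refit [hrf_params()]), `converged`, and
#'   `n_voxels` used. If no voxel passes the gate, returns `start` with a
#'   warning.
#' @export
refit_hrf <- function(voxel_fits, design, start = hrf_params(),
                      ve_gate = 0.10, step_frac = 0.25, tol = 0.02) {
  keep <- vapply(voxel_fits, function(v) v$ve_train > ve_gate, logical(1))
  if (!any(keep)) {
    warning("no voxels pass the training-VE gate; returning starting HRF")
    return(list(hrf = start, converged = FALSE, n_voxels = 0L))
  }
  vf <- voxel_fits[keep]
  objective <- function(par) {
    hp <- try(hrf_params(par[1], par[2], par[3], par[4], par[5]),
              silent = TRUE)
    if (inherits(hp, "try-error")) return(-Inf)
    dm <- design_matrices(design, hp)
    sum(vapply(vf, function(v) {
      pred <- predict_from_params(v$params, dm)
      variance_explained(pred, v$data)
    }, numeric(1)))
  }
  par <- unlist(unclass(start))
  steps <- abs(par) * step_frac
  best <- objective(par)
  while (max(steps / pmax(abs(par), 1e-6)) > tol) {
    moved <- FALSE
    for (i in seq_along(par)) {
      for (s in c(steps[i], -steps[i])) {
        cand <- par
        cand[i] <- cand[i] + s
        val <- objective(cand)
        if (val > best + 1e-10) {
          par <- cand; best <- val; moved <- TRUE
          break
        }
      }
    }
    if (!moved) steps <- steps / 2
  }
  list(hrf = hrf_params(par[1], par[2], par[3], par[4], par[5]),
       converged = TRUE, n_voxels = length(vf))
}
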