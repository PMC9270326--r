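# Voxel-level model fitting: canonical design construction, variance
# explained, non-negative component amplitude solves, grid + pattern-search
# fitting of both forward models, split-half cross-validation and voxel
# classification.

#' Canonical fitting design
#'
#' The unit of analysis is the per-condition average time course: one 56-TR
#' block per condition, concatenated in a fixed canonical order. Each block's
#' prediction is convolved independently (averaging across counterbalanced
#' run orders washes out cross-block spillover).
#'
#' @param conditions Conditions included, in concatenation order.
#' @param dt_ms Convolution grid step (ms).
#' @return A `timing_design`: list with `conditions`, `blocks` (condition
#'   schedules), `events` (with `block` column), `tr_ms`, `n_tr`, `dt_ms`.
#' @export
timing_design <- function(conditions = TIMING_CONDITIONS, dt_ms = 10) {
  blocks <- lapply(conditions, build_condition_schedule)
  names(blocks) <- conditions
  ev <- lapply(seq_along(blocks), function(i)
    cbind(block = i, blocks[[i]]$events))
  structure(list(conditions = conditions, blocks = blocks,
                 events = do.call(rbind, ev), tr_ms = TR_MS,
                 n_tr = length(conditions) * BLOCK_N_TR, dt_ms = dt_ms),
            class = "timing_design")
}

.design_cache <- new.env(parent = emptyenv())

#' Design matrices for fitting
#'
#' Precomputes, for a design and HRF, the kernel-lookup matrix `K` mapping
#' per-event amplitudes to the predicted per-TR time course (block-restarted
#' convolution), and its column-collapsed form `R` mapping one amplitude per
#' *unique* event timing to the same prediction. All model predictions in
#' the package are `R %*% w` for a timing-amplitude vector `w`, so the
#' simulator and the fitter share one code path. Results are cached.
#'
#' @param design A [timing_design()].
#' @param hrf An [hrf_params()] object.
#' @return List with `K`, `R`, `timings` (unique timing table), `timing_of`
#'   (per-event index into `timings`), plus the design fields.
#' @export
design_matrices <- function(design, hrf = hrf_params()) {
  stopifnot(inherits(design, "timing_design"))
  key <- paste(c(design$conditions, design$dt_ms,
                 signif(unlist(unclass(hrf)), 12)), collapse = "|")
  hit <- .design_cache[[key]]
  if (!is.null(hit)) return(hit)
  ev <- design$events
  n_tr <- design$n_tr
  k <- matrix(0, n_tr, nrow(ev))
  for (b in unique(ev$block)) {
    rows <- (b - 1) * BLOCK_N_TR + seq_len(BLOCK_N_TR)
    sel <- ev$block == b
    k[rows, sel] <- convolution_matrix(ev$offset_ms[sel],
                                       hrf, tr_ms = design$tr_ms,
                                       n_tr = BLOCK_N_TR, dt_ms = design$dt_ms)
  }
  key_t <- paste(ev$duration_ms, ev$period_ms)
  timings <- unique(data.frame(duration_ms = ev$duration_ms,
                               period_ms = ev$period_ms))
  rownames(timings) <- NULL
  timing_of <- match(key_t, paste(timings$duration_ms, timings$period_ms))
  r <- matrix(0, n_tr, nrow(timings))
  for (u in seq_len(nrow(timings)))
    r[, u] <- rowSums(k[, timing_of == u, drop = FALSE])
  out <- list(K = k, R = r, timings = timings, timing_of = timing_of,
              conditions = design$conditions, tr_ms = design$tr_ms,
              n_tr = n_tr, dt_ms = design$dt_ms, hrf = hrf, design = design)
  .design_cache[[key]] <- out
  out
}

#' Variance explained between a prediction and data
#'
#' Squared Pearson correlation; with the free gain and offset that every fit
#' and cross-validation refits, this equals `1 - RSS/TSS`.
#'
#' @param prediction,data Equal-length numeric vectors (length >= 3).
#' @return VE in `[0, 1]`; 0 when either series is constant.
#' @export
variance_explained <- function(prediction, data) {
  stopifnot(length(prediction) == length(data), length(data) >= 3)
  ps <- stats::sd(prediction)
  ds <- stats::sd(data)
  if (!is.finite(ps) || !is.finite(ds) || ps == 0 || ds == 0) return(0)
  stats::cor(prediction, data)^2
}

#' Solve component amplitudes with non-negativity fallback
#'
#' Two-regressor (plus intercept) least squares for the duration and
#' frequency component amplitudes. Monotonically decreasing responses are
#' disallowed: a negative amplitude is set to zero and the other component
#' refit alone; if that one is also negative, both are zero and the model
#' explains no variance. Collinear regressors fall back to the
#' single-component path.
#'
#' @param dur_regressor,freq_regressor HRF-convolved component predictions.
#' @param data Observed per-TR signal.
#' @return List with `beta_dur`, `beta_freq`, `ve`.
#' @export
solve_component_amplitudes <- function(dur_regressor, freq_regressor, data) {
  n <- length(data)
  stopifnot(length(dur_regressor) == n, length(freq_regressor) == n)
  dc <- data - mean(data)
  xd <- dur_regressor - mean(dur_regressor)
  xf <- freq_regressor - mean(freq_regressor)
  sdd <- sum(xd^2); sff <- sum(xf^2); sdf <- sum(xd * xf)
  syd <- sum(xd * dc); syf <- sum(xf * dc)
  det <- sdd * sff - sdf^2
  single <- function(sxx, sxy) if (sxx <= 0) 0 else sxy / sxx
  finish <- function(bd, bf) {
    pred <- bd * dur_regressor + bf * freq_regressor
    ve <- if (bd == 0 && bf == 0) 0 else variance_explained(pred, data)
    list(beta_dur = bd, beta_freq = bf, ve = ve)
  }
  collinear <- sdd <= 0 || sff <= 0 || det <= 1e-12 * sdd * sff
  if (!collinear) {
    bd <- (sff * syd - sdf * syf) / det
    bf <- (sdd * syf - sdf * syd) / det
    if (bd >= 0 && bf >= 0) return(finish(bd, bf))
    if (bd < 0 && bf >= 0) {
      bf2 <- single(sff, syf)
      return(if (bf2 < 0) finish(0, 0) else finish(0, bf2))
    }
    if (bf < 0 && bd >= 0) {
      bd2 <- single(sdd, syd)
      return(if (bd2 < 0) finish(0, 0) else finish(bd2, 0))
    }
    return(finish(0, 0))  # both negative
  }
  # collinear: try each single component, keep the better admissible one
  bd2 <- single(sdd, syd)
  bf2 <- single(sff, syf)
  cand <- list()
  if (bd2 > 0) cand <- c(cand, list(finish(bd2, 0)))
  if (bf2 > 0) cand <- c(cand, list(finish(0, bf2)))
  if (length(cand) == 0) return(finish(0, 0))
  cand[[which.max(vapply(cand, `[[`, numeric(1), "ve"))]]
}

#' Candidate grids and search control
#'
#' Candidate parameter values for the exhaustive stage of each model fit,
#' plus the pattern-search (local descent) control. Tuned preferred-timing
#' candidates extend beyond the presented 50--1000 ms range so out-of-range
#' optima are reachable. `density = "default"` is the standard grid;
#' `"coarse"` is the reduced grid used by the large simulation studies.
#'
#' @param density `"default"` or `"coarse"`, or override fields directly.
#' @param exp_dur,exp_freq Monotonic exponent candidates, in (0, 1].
#' @param pref_ms Tuned preferred duration and period candidates (ms).
#' @param sigma_major_ms Tuned major-axis extent candidates (ms).
#' @param sigma_ratio Candidates for `sigma_minor / sigma_major`, in (0, 1].
#' @param theta_rad Orientation candidates in `[0, pi)`.
#' @param exp_freq_tuned Tuned frequency-exponent candidates.
#' @param descent_tol VE improvement tolerance ending the pattern search.
#' @param descent_max_eval Evaluation budget of the pattern search.
#' @param n_starts Number of distinct grid candidates (separated in
#'   preferred-timing space) from which the local refinement is restarted.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(density = c("default", "coarse"),
                      exp_dur = NULL, exp_freq = NULL, pref_ms = NULL,
                      sigma_major_ms = NULL, sigma_ratio = NULL,
                      theta_rad = NULL, exp_freq_tuned = NULL,
                      descent_tol = 1e-4, descent_max_eval = 400,
                      n_starts = 3) {
  density <- match.arg(density)
  if (density == "default") {
    if (is.null(exp_dur)) exp_dur <- seq(0.05, 1, by = 0.05)
    if (is.null(exp_freq)) exp_freq <- seq(0.05, 1, by = 0.05)
    if (is.null(pref_ms)) pref_ms <- seq(50, 1450, by = 100)
    if (is.null(sigma_major_ms))
      sigma_major_ms <- exp(seq(log(50), log(2000), length.out = 6))
    if (is.null(sigma_ratio)) sigma_ratio <- c(0.35, 0.65, 1)
    if (is.null(theta_rad)) theta_rad <- pi * (0:3) / 4
    if (is.null(exp_freq_tuned)) exp_freq_tuned <- c(0.1, 0.4, 0.7, 1)
  } else {
    if (is.null(exp_dur)) exp_dur <- seq(0.1, 1, by = 0.1)
    if (is.null(exp_freq)) exp_freq <- seq(0.1, 1, by = 0.1)
    if (is.null(pref_ms)) pref_ms <- seq(50, 1450, by = 200)
    if (is.null(sigma_major_ms))
      sigma_major_ms <- exp(seq(log(75), log(1600), length.out = 4))
    if (is.null(sigma_ratio)) sigma_ratio <- c(0.4, 1)
    if (is.null(theta_rad)) theta_rad <- pi * (0:3) / 4
    if (is.null(exp_freq_tuned)) exp_freq_tuned <- c(0.25, 0.6, 1)
  }
  if (min(pref_ms) >= 60 || max(pref_ms) <= 990)
    stop("pref_ms candidates must extend beyond [60, 990] ms")
  structure(list(exp_dur = exp_dur, exp_freq = exp_freq, pref_ms = pref_ms,
                 sigma_major_ms = sigma_major_ms, sigma_ratio = sigma_ratio,
                 theta_rad = theta_rad, exp_freq_tuned = exp_freq_tuned,
                 descent_tol = descent_tol,
                 descent_max_eval = descent_max_eval, n_starts = n_starts),
            class = "grid_spec")
}

# Column-wise VE of many candidate predictions against one data vector.
ve_columns <- function(p, data) {
  dc <- data - mean(data)
  ssd <- sum(dc^2)
  if (ssd == 0) return(numeric(ncol(p)))
  num <- as.numeric(crossprod(dc, p))
  den <- colSums(p^2) - length(data) * colMeans(p)^2
  ve <- numeric(ncol(p))
  ok <- den > 1e-12
  ve[ok] <- num[ok]^2 / (den[ok] * ssd)
  pmin(ve, 1)
}

#' Fit the monotonic response model to one split
#'
#' Exhaustive search over the exponent candidate pairs; for each pair the
#' two component amplitudes are solved linearly with the non-negativity
#' fallback. Pinning either exponent grid to 1 yields the linear comparison
#' variants.
#'
#' @param data Per-TR signal for one cross-validation split.
#' @param dm [design_matrices()] output.
#' @param grid A [grid_spec()].
#' @return List (class `fit_result`) with `model_kind = "monotonic"`,
#'   `params` ([monotonic_params()]), `ve_train`.
#' @export
fit_monotonic <- function(data, dm, grid = grid_spec()) {
  tim <- dm$timings
  dur_s <- tim$duration_ms / 1000
  freq <- 1000 / tim$period_ms
  dreg <- dm$R %*% outer(dur_s, grid$exp_dur, `^`)
  freg <- dm$R %*% exp(outer(log(freq), grid$exp_freq - 1))
  best <- list(ve = -1)
  for (i in seq_along(grid$exp_dur)) {
    for (j in seq_along(grid$exp_freq)) {
      s <- solve_component_amplitudes(dreg[, i], freg[, j], data)
      if (s$ve > best$ve) best <- c(s, list(i = i, j = j))
    }
  }
  params <- monotonic_params(grid$exp_dur[best$i], grid$exp_freq[best$j],
                             max(best$beta_dur, 0), max(best$beta_freq, 0))
  structure(list(model_kind = "monotonic", params = params,
                 ve_train = max(best$ve, 0)),
            class = "fit_result")
}

# Tuned candidate amplitudes over the unique timings, vectorized over
# candidates: returns n_timings x n_candidates matrix.
tuned_amplitude_matrix <- function(tim, cand, rotation_mode = "corrected") {
  n_u <- nrow(tim)
  m <- nrow(cand)
  dur <- tim$duration_ms / 1000
  per <- tim$period_ms / 1000
  lfreq <- log(1000 / tim$period_ms)
  rep_row <- function(v) matrix(v, n_u, m, byrow = TRUE)
  d_dur <- outer(dur, cand$pref_duration_ms / 1000, `-`)
  d_per <- outer(per, cand$pref_period_ms / 1000, `-`)
  ct <- rep_row(cos(cand$theta_rad)); st <- rep_row(sin(cand$theta_rad))
  x <- d_dur * ct - d_per * st
  y <- if (rotation_mode == "corrected") d_dur * st + d_per * ct
       else d_dur * st - d_per * ct
  g <- exp(-0.5 * ((y / rep_row(cand$sigma_major_ms / 1000))^2 +
                   (x / rep_row(cand$sigma_minor_ms / 1000))^2))
  g * exp(outer(lfreq, cand$exp_freq - 1))
}

# Neighbor bounds of value v within sorted candidate vector vals; edges are
# extended by one grid gap so boundary optima remain expressible.
neighbor_bounds <- function(v, vals) {
  vals <- sort(unique(vals))
  i <- which.min(abs(vals - v))
  gap_lo <- if (i > 1) vals[i] - vals[i - 1] else vals[2] - vals[1]
  gap_hi <- if (i < length(vals)) vals[i + 1] - vals[i]
            else vals[length(vals)] - vals[length(vals) - 1]
  c(v - gap_lo, v + gap_hi)
}

#' Fit the tuned response model to one split
#'
#' Grid search over the six tuned parameters (batched matrix evaluation of
#' all candidates), followed by local refinement restarted from the best
#' grid point and up to `grid$n_starts - 1` runner-up candidates in other
#' preferred-timing basins. Each refinement is a coordinate-wise pattern
#' search confined between the start's grid neighbors, with halving steps
#' until the VE gain falls below `grid$descent_tol`, finished by a bounded
#' quasi-Newton polish. Sets `out_of_range` when the fitted preferred
#' duration or period falls below 60 ms or above 990 ms.
#'
#' @inheritParams fit_monotonic
#' @param rotation_mode Passed to [tuned_event_amplitude()].
#' @return List (class `fit_result`) with `model_kind = "tuned"`, `params`
#'   ([tuned_params()]), `ve_train`, `out_of_range`.
#' @export
fit_tuned <- function(data, dm, grid = grid_spec(),
                      rotation_mode = "corrected") {
  tim <- dm$timings
  cand <- expand.grid(pref_duration_ms = grid$pref_ms,
                      pref_period_ms = grid$pref_ms,
                      sigma_major_ms = grid$sigma_major_ms,
                      sigma_ratio = grid$sigma_ratio,
                      theta_rad = grid$theta_rad,
                      exp_freq = grid$exp_freq_tuned,
                      KEEP.OUT.ATTRS = FALSE)
  cand$sigma_minor_ms <- cand$sigma_major_ms * cand$sigma_ratio
  ve_all <- numeric(nrow(cand))
  chunk <- 10000L
  for (s in seq(1, nrow(cand), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(cand))
    w <- tuned_amplitude_matrix(tim, cand[idx, ], rotation_mode)
    ve_all[idx] <- ve_columns(dm$R %*% w, data)
  }
  best_i <- which.max(ve_all)
  best_ve <- ve_all[best_i]
  # refinement starts: the best grid point plus runners-up in other
  # preferred-timing basins (the VE landscape couples the preferred
  # timings, extents and orientation, so a single basin can trap the
  # local search)
  ord <- order(ve_all, decreasing = TRUE)[seq_len(min(400, nrow(cand)))]
  n_starts <- if (is.null(grid$n_starts)) 3L else grid$n_starts
  starts <- best_i
  for (j in ord) {
    if (length(starts) >= n_starts) break
    far <- all(vapply(starts, function(s0)
      abs(cand$pref_duration_ms[j] - cand$pref_duration_ms[s0]) +
        abs(cand$pref_period_ms[j] - cand$pref_period_ms[s0]) >= 200,
      logical(1)))
    if (far) starts <- c(starts, j)
  }
  obj <- function(p) {
    prm <- tuned_params(p[1], p[2], exp(p[3]), exp(p[3]) * p[4], p[5], p[6])
    variance_explained(as.numeric(dm$R %*% tuned_event_amplitude(tim, prm,
                                                                 rotation_mode)),
                       data)
  }
  # local refinement from one grid point: coordinate-wise pattern search in
  # (pref_dur, pref_per, log sigma_major, ratio, theta, expf), confined
  # between the point's grid neighbors, then a bounded quasi-Newton polish
  # (the coordinate search can stall in valleys coupling the preferred
  # timings with theta)
  refine <- function(b) {
    par <- c(b$pref_duration_ms, b$pref_period_ms, log(b$sigma_major_ms),
             b$sigma_ratio, b$theta_rad, b$exp_freq)
    lo <- c(neighbor_bounds(par[1], grid$pref_ms)[1],
            neighbor_bounds(par[2], grid$pref_ms)[1],
            neighbor_bounds(par[3], log(grid$sigma_major_ms))[1],
            neighbor_bounds(par[4], grid$sigma_ratio)[1],
            par[5] - pi / length(grid$theta_rad),
            neighbor_bounds(par[6], grid$exp_freq_tuned)[1])
    hi <- c(neighbor_bounds(par[1], grid$pref_ms)[2],
            neighbor_bounds(par[2], grid$pref_ms)[2],
            neighbor_bounds(par[3], log(grid$sigma_major_ms))[2],
            neighbor_bounds(par[4], grid$sigma_ratio)[2],
            par[5] + pi / length(grid$theta_rad),
            neighbor_bounds(par[6], grid$exp_freq_tuned)[2])
    lo[1:2] <- pmax(lo[1:2], 1)          # prefs stay positive
    lo[4] <- max(lo[4], 0.02); hi[4] <- min(hi[4], 1)
    lo[6] <- max(lo[6], 0.02); hi[6] <- min(hi[6], 1)
    steps <- (hi - lo) / 4
    cur <- pmin(pmax(par, lo), hi)
    cur_ve <- obj(cur)
    evals <- 1L
    while (evals < grid$descent_max_eval && max(steps / (hi - lo)) > 1 / 128) {
      improved <- FALSE
      for (i in seq_along(cur)) {
        for (sg in c(1, -1)) {
          p2 <- cur
          p2[i] <- min(max(cur[i] + sg * steps[i], lo[i]), hi[i])
          if (p2[i] == cur[i]) next
          v2 <- obj(p2); evals <- evals + 1L
          if (v2 > cur_ve + grid$descent_tol * 1e-2) {
            cur <- p2; cur_ve <- v2; improved <- TRUE
            break
          }
        }
      }
      if (!improved) steps <- steps / 2
    }
    pol <- try(stats::optim(cur, function(p) -obj(p), method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 100, factr = 1e10)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && -pol$value > cur_ve) {
      cur <- pol$par
      cur_ve <- -pol$value
    }
    list(par = cur, ve = cur_ve)
  }
  cur <- NULL; cur_ve <- -1
  for (s0 in starts) {
    r <- refine(cand[s0, ])
    if (r$ve > cur_ve) { cur <- r$par; cur_ve <- r$ve }
  }
  params <- tuned_params(cur[1], cur[2], exp(cur[3]), exp(cur[3]) * cur[4],
                         cur[5], cur[6])
  oor <- params$pref_duration_ms < 60 || params$pref_duration_ms > 990 ||
         params$pref_period_ms < 60 || params$pref_period_ms > 990
  structure(list(model_kind = "tuned", params = params,
                 ve_train = max(cur_ve, best_ve), out_of_range = oor),
            class = "fit_result")
}

#' Prediction time course from fitted parameters
#'
#' Regenerates the (gain-free) predicted per-TR time course of a fitted
#' model on the design: the shared forward path `R %*% w`.
#'
#' @param params `monotonic_params` or `tuned_params`.
#' @param dm [design_matrices()] output.
#' @param ... Passed to [event_amplitude()].
#' @return Numeric vector of length `dm$n_tr`.
#' @export
predict_from_params <- function(params, dm, ...) {
  as.numeric(dm$R %*% event_amplitude(dm$timings, params, ...))
}

#' Cross-validated variance explained of a fit
#'
#' Regenerates the prediction from the fitted parameters and scores it
#' against the held-out split; the squared-correlation VE implicitly refits
#' the gain and offset, as response amplitudes vary arbitrarily between
#' scan sessions. A tuned fit whose preferred duration or period lies
#' outside the presented stimulus range scores 0.
#'
#' @param fit A `fit_result` from [fit_monotonic()] or [fit_tuned()].
#' @param dm [design_matrices()] output.
#' @param heldout Per-TR signal of the complementary split.
#' @param ... Passed to [event_amplitude()].
#' @return VE in `[0, 1]`.
#' @export
crossvalidate <- function(fit, dm, heldout, ...) {
  stopifnot(inherits(fit, "fit_result"))
  if (identical(fit$model_kind, "tuned") && isTRUE(fit$out_of_range))
    return(0)
  variance_explained(predict_from_params(fit$params, dm, ...), heldout)
}

#' Classify a voxel as monotonic, tuned, or excluded
#'
#' A voxel is excluded when both models' training VE is at or below
#' `threshold` in both splits. Otherwise the label is the model with the
#' higher mean cross-validated VE across the two splits; the tuned model is
#' eligible only if at least one split's preferred timing is inside the
#' presented range (out-of-range splits already score 0), and ties go to the
#' more parsimonious monotonic model.
#'
#' @param ve_train_mono,ve_train_tuned Length-2 training VE (splits A, B).
#' @param ve_cv_mono,ve_cv_tuned Length-2 cross-validated VE.
#' @param out_of_range Length-2 logical, tuned fits' out-of-range flags.
#' @param threshold Training-VE exclusion cutoff (default 0.2).
#' @return `"monotonic"`, `"tuned"`, or `"excluded"`.
#' @export
classify_voxel <- function(ve_train_mono, ve_train_tuned, ve_cv_mono,
                           ve_cv_tuned, out_of_range, threshold = 0.2) {
  if (all(c(ve_train_mono, ve_train_tuned) <= threshold)) return("excluded")
  tuned_ok <- !all(out_of_range)
  if (tuned_ok && mean(ve_cv_tuned) > mean(ve_cv_mono)) "tuned"
  else "monotonic"
}

#' Fit both models to one voxel's split-half time courses
#'
#' Fits the monotonic and tuned models independently on each split,
#' cross-validates each fit on the complementary split, and classifies the
#' voxel.
#'
#' @param tc_a,tc_b Per-TR signals of the two split-half averages.
#' @param dm [design_matrices()] output.
#' @param grid A [grid_spec()].
#' @param threshold Training-VE exclusion cutoff.
#' @param rotation_mode Passed to the tuned model.
#' @return List with `mono` and `tuned` (each a list of per-split
#'   `fit_result`s plus `ve_cv`), and `classification`.
#' @export
fit_voxel <- function(tc_a, tc_b, dm, grid = grid_spec(), threshold = 0.2,
                      rotation_mode = "corrected") {
  m_a <- fit_monotonic(tc_a, dm, grid)
  m_b <- fit_monotonic(tc_b, dm, grid)
  t_a <- fit_tuned(tc_a, dm, grid, rotation_mode)
  t_b <- fit_tuned(tc_b, dm, grid, rotation_mode)
  cv_m <- c(crossvalidate(m_a, dm, tc_b), crossvalidate(m_b, dm, tc_a))
  cv_t <- c(crossvalidate(t_a, dm, tc_b, rotation_mode = rotation_mode),
            crossvalidate(t_b, dm, tc_a, rotation_mode = rotation_mode))
  cls <- classify_voxel(c(m_a$ve_train, m_b$ve_train),
                        c(t_a$ve_train, t_b$ve_train),
                        cv_m, cv_t, c(t_a$out_of_range, t_b$out_of_range),
                        threshold)
  list(mono = list(a = m_a, b = m_b, ve_cv = cv_m),
       tuned = list(a = t_a, b = t_b, ve_cv = cv_t),
       classification = cls)
}

#' Fit a whole cohort and return a tidy fit table
#'
#' @param cohort A cohort from [generate_cohort()] or [read_fixtures()], or
#'   any list with `annotations`, `tc_a`, `tc_b`.
#' @param dm [design_matrices()] output matching the cohort's design.
#' @param grid A [grid_spec()].
#' @param threshold Training-VE exclusion cutoff.
#' @param rotation_mode Passed to the tuned model.
#' @param progress Print a dot every 50 voxels.
#' @return Data.frame, one row per voxel x model x split, with `voxel_id`,
#'   `model`, `split`, `ve_train`, `ve_cv`, `out_of_range`,
#'   `classification`, and the fitted parameter columns.
#' @export
fit_cohort <- function(cohort, dm, grid = grid_spec(), threshold = 0.2,
                       rotation_mode = "corrected", progress = FALSE) {
  ann <- cohort$annotations
  rows <- vector("list", nrow(ann))
  for (v in seq_len(nrow(ann))) {
    f <- fit_voxel(cohort$tc_a[v, ], cohort$tc_b[v, ], dm, grid, threshold,
                   rotation_mode)
    rows[[v]] <- fit_table_rows(ann$voxel_id[v], f)
    if (progress && v %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Long-format rows (voxel x model x split) from one fit_voxel() result.
fit_table_rows <- function(voxel_id, f) {
  row1 <- function(model, split, fr, cv) {
    p <- fr$params
    data.frame(voxel_id = voxel_id, model = model, split = split,
               ve_train = fr$ve_train, ve_cv = cv,
               out_of_range = isTRUE(fr$out_of_range),
               classification = f$classification,
               exp_dur = if (model == "monotonic") p$exp_dur else NA_real_,
               exp_freq = p$exp_freq,
               beta_dur = if (model == "monotonic") p$beta_dur else NA_real_,
               beta_freq = if (model == "monotonic") p$beta_freq else NA_real_,
               amplitude_ratio = if (model == "monotonic") p$amplitude_ratio
                                 else NA_real_,
               pref_duration_ms = if (model == "tuned") p$pref_duration_ms
                                  else NA_real_,
               pref_period_ms = if (model == "tuned") p$pref_period_ms
                                else NA_real_,
               sigma_major_ms = if (model == "tuned") p$sigma_major_ms
                                else NA_real_,
               sigma_minor_ms = if (model == "tuned") p$sigma_minor_ms
                                else NA_real_,
               theta_rad = if (model == "tuned") p$theta_rad else NA_real_)
  }
  rbind(row1("monotonic", "A", f$mono$a, f$mono$ve_cv[1]),
        row1("monotonic", "B", f$mono$b, f$mono$ve_cv[2]),
        row1("tuned", "A", f$tuned$a, f$tuned$ve_cv[1]),
        row1("tuned", "B", f$tuned$b, f$tuned$ve_cv[2]))
}
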