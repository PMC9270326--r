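# Independent scalar oracles written directly from the model formulas.
# These deliberately do not reuse package code paths.

# Monotonic per-event amplitude: beta_dur * Duration^expDur +
# beta_freq * Frequency^expFreq / Frequency, in seconds / Hz.
oracle_monotonic <- function(duration_ms, period_ms, exp_dur, exp_freq,
                             beta_dur, beta_freq) {
  duration <- duration_ms / 1000
  frequency <- 1000 / period_ms
  beta_dur * duration^exp_dur + beta_freq * frequency^exp_freq / frequency
}

# Tuned per-event amplitude: rotated anisotropic Gaussian times the
# compressive frequency term, written out coordinate by coordinate.
oracle_tuned <- function(duration_ms, period_ms, pref_duration_ms,
                         pref_period_ms, sigma_major_ms, sigma_minor_ms,
                         theta, exp_freq, printed = FALSE) {
  duration <- duration_ms / 1000
  period <- period_ms / 1000
  frequency <- 1000 / period_ms
  d1 <- duration - pref_duration_ms / 1000
  d2 <- period - pref_period_ms / 1000
  x <- d1 * cos(theta) - d2 * sin(theta)
  y <- if (printed) d1 * sin(theta) - d2 * cos(theta)
       else d1 * sin(theta) + d2 * cos(theta)
  gauss <- exp(-0.5 * ((y / (sigma_major_ms / 1000))^2 +
                       (x / (sigma_minor_ms / 1000))^2))
  gauss * frequency^exp_freq / frequency
}

# Brute-force prediction: loop over impulses and dt bins, summing shifted
# kernel values at TR onsets.
oracle_convolve <- function(time_ms, amplitude, kernel, tr_ms, n_tr, dt_ms) {
  out <- numeric(n_tr)
  bins <- floor(time_ms / dt_ms) * dt_ms
  for (j in seq_len(n_tr)) {
    t_j <- (j - 1) * tr_ms
    for (i in seq_along(bins)) {
      lag <- t_j - bins[i]
      idx <- lag / dt_ms + 1
      if (idx >= 1 && idx <= length(kernel))
        out[j] <- out[j] + amplitude[i] * kernel[idx]
    }
  }
  out
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the (nonzero) absolute differences: twice the smaller tail of the
# positive-rank sum under the null.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-12),
                 mean(w_all >= w_obs - 1e-12)))
}

# Stated fallback procedure for the component amplitudes, implemented with
# lm() branch by branch.
oracle_solve_amplitudes <- function(d_reg, f_reg, y) {
  cf <- stats::coef(stats::lm(y ~ d_reg + f_reg))
  bd <- cf[2]; bf <- cf[3]
  refit_single <- function(x) stats::coef(stats::lm(y ~ x))[2]
  if (is.na(bd) || is.na(bf)) {
    bd <- refit_single(d_reg); bf <- 0
    if (bd < 0) { bd <- 0; bf <- max(refit_single(f_reg), 0) }
  } else if (bd < 0) {
    bd <- 0
    bf <- refit_single(f_reg)
    if (bf < 0) bf <- 0
  } else if (bf < 0) {
    bf <- 0
    bd <- refit_single(d_reg)
    if (bd < 0) bd <- 0
  }
  pred <- bd * d_reg + bf * f_reg
  ve <- if (bd == 0 && bf == 0 || stats::sd(pred) == 0) 0
        else stats::cor(pred, y)^2
  list(beta_dur = unname(bd), beta_freq = unname(bf), ve = ve)
}
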