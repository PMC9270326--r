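test_that("variance explained is affine-invariant squared correlation", {
  x <- sin(seq_len(50))
  expect_equal(variance_explained(x, x), 1)
  expect_equal(variance_explained(x, 3 * x + 7), 1)
  y <- cos(seq_len(50))
  yo <- y - mean(y)
  xo <- x - mean(x)
  yo <- yo - sum(yo * xo) / sum(xo^2) * xo  # orthogonal to centered x
  expect_equal(variance_explained(x, yo + mean(y)), 0, tolerance = 1e-12)
  expect_equal(variance_explained(x, rep(2, 50)), 0)
  expect_error(variance_explained(x, x[1:10]))
})

test_that("component amplitude solve applies the non-negativity fallback", {
  dm <- test_dm()
  tim <- dm$timings
  d_reg <- as.numeric(dm$R %*% (tim$duration_ms / 1000)^0.4)
  f_reg <- as.numeric(dm$R %*% (1000 / tim$period_ms)^(0.7 - 1))
  s <- solve_component_amplitudes(d_reg, f_reg, d_reg)
  expect_equal(s$beta_dur, 1, tolerance = 1e-8)
  expect_equal(s$beta_freq, 0, tolerance = 1e-8)
  expect_equal(s$ve, 1, tolerance = 1e-12)
  # data anti-correlated with both regressors: everything zeroed, VE 0
  s2 <- solve_component_amplitudes(d_reg, f_reg, -d_reg - 0.5 * f_reg)
  expect_equal(c(s2$beta_dur, s2$beta_freq, s2$ve), c(0, 0, 0))
  # random mixed cases match the stated branch-by-branch procedure
  set.seed(99)
  for (i in 1:50) {
    y <- rnorm(1) * d_reg + rnorm(1) * f_reg + rnorm(length(d_reg), 0, 0.5)
    got <- solve_component_amplitudes(d_reg, f_reg, y)
    want <- oracle_solve_amplitudes(d_reg, f_reg, y)
    expect_equal(got$beta_dur, want$beta_dur, tolerance = 1e-6)
    expect_equal(got$beta_freq, want$beta_freq, tolerance = 1e-6)
    expect_equal(got$ve, want$ve, tolerance = 1e-8)
  }
  # collinear regressors take the single-component path
  s3 <- solve_component_amplitudes(d_reg, 2 * d_reg, d_reg)
  expect_equal(s3$ve, 1, tolerance = 1e-9)
})

test_that("monotonic fits recover noiseless generating exponents", {
  dm <- test_dm()
  g <- grid_spec("default")
  truth <- monotonic_params(0.3, 0.6, 0.7, 0.5)
  fit <- fit_monotonic(simulate_noiseless(truth, dm), dm, g)
  expect_lte(abs(fit$params$exp_dur - 0.3), 0.05 + 1e-9)
  expect_lte(abs(fit$params$exp_freq - 0.6), 0.05 + 1e-9)
  expect_gt(fit$ve_train, 0.999)
  expect_equal(fit$params$amplitude_ratio, 0.7 / 0.5, tolerance = 0.2)
  # flat time course explains nothing
  expect_equal(fit_monotonic(rep(1, dm$n_tr), dm, g)$ve_train, 0)
})

test_that("the free-exponent monotonic fit dominates the linear variants", {
  dm <- test_dm()
  g <- grid_spec("coarse")
  g_lin_dur <- grid_spec("coarse", exp_dur = 1)
  g_lin_both <- grid_spec("coarse", exp_dur = 1, exp_freq = 1)
  set.seed(3)
  for (i in 1:4) {
    truth <- monotonic_params(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
                              runif(1, 0.3, 1), runif(1, 0.3, 1))
    y <- degrade(simulate_noiseless(truth, dm), 1, seed = i)$a
    full <- fit_monotonic(y, dm, g)$ve_train
    expect_gte(full, fit_monotonic(y, dm, g_lin_dur)$ve_train - 1e-12)
    expect_gte(full, fit_monotonic(y, dm, g_lin_both)$ve_train - 1e-12)
  }
})

test_that("tuned fits recover noiseless parameters and flag out-of-range", {
  dm <- test_dm()
  g <- grid_spec("coarse")
  truth <- tuned_params(400, 700, 300, 150, 0.5, 0.4)
  fit <- fit_tuned(simulate_noiseless(truth, dm), dm, g)
  expect_lt(abs(fit$params$pref_duration_ms - 400), 50)
  expect_lt(abs(fit$params$pref_period_ms - 700), 50)
  expect_gt(fit$ve_train, 0.99)
  expect_false(fit$out_of_range)
  # descent never falls below the best grid point
  g1 <- grid_spec("coarse", descent_max_eval = 1)
  expect_gte(fit$ve_train, fit_tuned(simulate_noiseless(truth, dm), dm,
                                     g1)$ve_train - 1e-12)
  # a preferred duration beyond the presented range is flagged
  far <- tuned_params(1200, 1400, 400, 200, 0, 0.8)
  fit_far <- fit_tuned(simulate_noiseless(far, dm), dm, g)
  expect_true(fit_far$out_of_range)
})

test_that("cross-validation refits the gain and zeroes out-of-range tuned fits", {
  dm <- test_dm()
  g <- grid_spec("coarse")
  truth <- tuned_params(400, 700, 300, 150, 0.5, 0.4)
  tc <- simulate_noiseless(truth, dm)
  fit <- fit_tuned(tc, dm, g)
  # identical noiseless splits: cv equals training VE
  expect_equal(crossvalidate(fit, dm, tc), fit$ve_train, tolerance = 1e-9)
  # affine change of the held-out split changes nothing
  expect_equal(crossvalidate(fit, dm, 5 * tc + 100), fit$ve_train,
               tolerance = 1e-9)
  fit$out_of_range <- TRUE
  expect_equal(crossvalidate(fit, dm, tc), 0)
  # with independent noise, cv VE does not beat training VE on average
  set.seed(21)
  gap <- replicate(30, {
    p <- monotonic_params(runif(1, 0.1, 0.9), runif(1, 0.1, 0.9),
                          runif(1, 0.3, 1), runif(1, 0.3, 1))
    pair <- degrade(simulate_noiseless(p, dm), 1,
                    seed = sample.int(1e6, 1))
    f <- fit_monotonic(pair$a, dm, g)
    f$ve_train - crossvalidate(f, dm, pair$b)
  })
  expect_gt(mean(gap), 0)
})

test_that("voxel classification follows threshold, eligibility and argmax", {
  expect_equal(classify_voxel(c(0.15, 0.15), c(0.15, 0.15), c(0.5, 0.5),
                              c(0.9, 0.9), c(FALSE, FALSE), 0.2),
               "excluded")
  expect_equal(classify_voxel(c(0.5, 0.5), c(0.6, 0.6), c(0.4, 0.4),
                              c(0, 0), c(TRUE, TRUE), 0.2),
               "monotonic")
  expect_equal(classify_voxel(c(0.5, 0.5), c(0.5, 0.5), c(0.25, 0.25),
                              c(0.30, 0.30), c(FALSE, FALSE), 0.2),
               "tuned")
  # tie goes to the more parsimonious monotonic model
  expect_equal(classify_voxel(c(0.5, 0.5), c(0.5, 0.5), c(0.3, 0.3),
                              c(0.3, 0.3), c(FALSE, FALSE), 0.2),
               "monotonic")
})

test_that("fit_cohort returns a tidy voxel x model x split table", {
  dm <- test_dm()
  cfg <- cohort_config(n_participants = 1, n_hemispheres = 1,
                       maps = c("V1", "TO1"), voxels_per_map = 2,
                       seed = 4)
  coh <- generate_cohort(cfg, dm)
  fits <- fit_cohort(coh, dm, grid_spec("coarse"))
  expect_equal(nrow(fits), nrow(coh$annotations) * 4)
  expect_setequal(unique(fits$model), c("monotonic", "tuned"))
  expect_setequal(unique(fits$split), c("A", "B"))
  expect_true(all(fits$ve_train >= 0 & fits$ve_train <= 1))
  expect_true(all(fits$ve_cv >= 0 & fits$ve_cv <= 1))
  expect_true(all(fits$classification %in%
                    c("monotonic", "tuned", "excluded")))
  expect_true(all(is.na(fits$pref_duration_ms[fits$model == "monotonic"])))
  expect_true(all(!is.na(fits$exp_dur[fits$model == "monotonic"])))
})
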