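test_that("signed-rank normal approximation matches exact enumeration", {
  cases <- list(c(1.2, -0.5, 2.1, 0.3, -1.8, 0.9, 2.5, -0.2),
                c(3, 1, 4, 1.5, 9, -2.6, 5.3, -5.8, 9.7, -9.3),
                c(0.5, 0.25, 1, 2, -3, 1.5, 0.75),
                c(-1, -2, -3, 4, 5, 0.5, -0.25, 0.125, 6))
  for (d in cases) {
    approx <- wilcoxon_signed_rank(d)
    exact <- oracle_wilcoxon_exact(d)
    expect_lt(abs(approx$p - exact), 0.01)
    # agreement with the stats package on the statistic
    sw <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(approx$W, unname(sw$statistic))
  }
  expect_equal(wilcoxon_signed_rank(rep(1, 6), rep(1, 6)),
               list(Z = 0, p = 1, n = 0L, W = 0))
  allpos <- wilcoxon_signed_rank(seq_len(20) / 10)
  expect_gt(allpos$Z, 0)
  expect_lt(allpos$p, 0.001)
  expect_equal(allpos$W, 20 * 21 / 2)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.005, 0.049, 0.02, 0.9)
  expect_true(all(fdr_bh(p) >= p))
  expect_false(is.unsorted(fdr_bh(p)[order(p)]))
})

test_that("effect size r is Z over root n", {
  expect_equal(effect_size_r(0, 10), 0)
  expect_equal(effect_size_r(2, 16), 0.5)
  expect_equal(effect_size_r(-1.5, 25), -0.3)
})

test_that("bootstrap median CI is seeded, bracketing, and tight for constants", {
  expect_equal(bootstrap_median_ci(rep(3.5, 20), seed = 1), c(3.5, 3.5))
  set.seed(8)
  x <- rexp(40)
  ci <- bootstrap_median_ci(x, n_iter = 500, seed = 2)
  expect_lte(ci[1], median(x))
  expect_gte(ci[2], median(x))
  expect_identical(bootstrap_median_ci(x, n_iter = 200, seed = 7),
                   bootstrap_median_ci(x, n_iter = 200, seed = 7))
})

test_that("one-factor ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  d <- data.frame(g = rep(c("a", "b"), each = 12),
                  y = c(rnorm(12), rnorm(12, 0.8)))
  a <- anova_nfactor(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  # constant response: all F zero
  d$y <- 1
  expect_true(all(anova_nfactor(d, "y", "g")$F == 0))
})

test_that("two-factor ANOVA matches a hand-computed balanced decomposition", {
  # balanced 2x2 with 2 replicates
  d <- expand.grid(f1 = c("a", "b"), f2 = c("u", "v"), rep = 1:2)
  d$y <- c(3, 5, 6, 10, 4, 6, 7, 9)
  a <- anova_nfactor(d, "y", c("f1", "f2"), list(c("f1", "f2")))
  gm <- mean(d$y)
  ss <- function(groups) sum(tapply(d$y, groups, function(v)
    length(v) * (mean(v) - gm)^2))
  ss1 <- ss(d$f1); ss2 <- ss(d$f2)
  ss_cells <- ss(interaction(d$f1, d$f2))
  ss_int <- ss_cells - ss1 - ss2
  ss_err <- sum((d$y - ave(d$y, interaction(d$f1, d$f2)))^2)
  expect_equal(a$F, c(ss1, ss2, ss_int) / (ss_err / 4), tolerance = 1e-10)
  expect_equal(a$partial_eta_sq,
               c(ss1, ss2, ss_int) / (c(ss1, ss2, ss_int) + ss_err),
               tolerance = 1e-10)
})

test_that("Dunn z statistics match a manual rank computation", {
  g <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(20, 30, 40))
  got <- dunn_holm_sidak(g)
  x <- unlist(g)
  r <- rank(x)
  n_tot <- 9
  se <- sqrt(n_tot * (n_tot + 1) / 12 * (1 / 3 + 1 / 3))
  z_ab <- (mean(r[1:3]) - mean(r[4:6])) / se
  expect_equal(got$z[got$group1 == "a" & got$group2 == "b"], z_ab)
  # identical groups: adjusted p near 1
  same <- dunn_holm_sidak(list(a = 1:6, b = 1:6))
  expect_gt(same$p_adj, 0.95)
  expect_error(dunn_holm_sidak(list(a = 1:3)), "2")
})

test_that("Holm-Sidak follows the step-down formula", {
  adj <- holm_sidak(c(0.01, 0.04))
  expect_equal(adj[1], 1 - (1 - 0.01)^2)
  expect_equal(adj[2], max(adj[1], 0.04))
  expect_equal(holm_sidak(0.2), 0.2)
  p <- c(0.04, 0.001, 0.2, 0.012)
  a <- holm_sidak(p)
  expect_false(is.unsorted(a[order(p)]))
})

test_that("Jarque-Bera matches its formula and detects skew", {
  # symmetric sample engineered to have exactly zero excess kurtosis:
  # kurtosis of {8 zeros, +/-a x2} is n/(2m) = 12/4 = 3
  flat <- c(rep(0, 8), 2, 2, -2, -2)
  jb0 <- jarque_bera(flat)
  expect_equal(jb0$statistic, 0, tolerance = 1e-12)
  expect_equal(jb0$p, 1)
  # hand-computed 10-point sample
  x <- c(0.3, -1.2, 2.5, 0.1, -0.4, 1.7, -2.2, 0.9, -0.6, 0.5)
  m <- mean(x); m2 <- mean((x - m)^2)
  sk <- mean((x - m)^3) / m2^1.5
  ku <- mean((x - m)^4) / m2^2 - 3
  expect_equal(jarque_bera(x)$statistic, 10 / 6 * (sk^2 + ku^2 / 4),
               tolerance = 1e-12)
  # strongly skewed draws are rejected in at least 19 of 20 seeded runs
  hits <- vapply(1:20, function(i) {
    set.seed(i)
    jarque_bera(rexp(200))$p < 0.01
  }, logical(1))
  expect_gte(sum(hits), 19)
  expect_error(jarque_bera(1:5), ">= 8")
})

test_that("map medians honor thresholds, splits and voxel order", {
  tabs <- fake_fit_tables(ve_mono = c(0.5, 0.6, 0.1),
                          ve_tuned = c(0.3, 0.7, 0.05),
                          ecc = c(0.5, 1, 2),
                          ve_train = c(0.5, 0.7, 0.1))
  mm <- map_median_ve(tabs$fits, tabs$annotations, threshold = 0.2)
  expect_equal(sort(unique(mm$model)), c("monotonic", "tuned"))
  # voxel 3 fails the threshold; medians over voxels 1 and 2
  expect_equal(mm$median_ve_cv[mm$model == "monotonic" & mm$split == "A"],
               median(c(0.5, 0.6)))
  expect_equal(unique(mm$n_voxels), 2)
  # single passing voxel: the median is that voxel
  one <- fake_fit_tables(0.5, 0.3, 1, ve_train = 0.5)
  m1 <- map_median_ve(one$fits, one$annotations, threshold = 0.2)
  expect_equal(m1$median_ve_cv[m1$model == "tuned"][1], 0.3)
  # all voxels below threshold: the cell is absent
  low <- fake_fit_tables(0.1, 0.1, 1, ve_train = 0.1)
  expect_equal(nrow(map_median_ve(low$fits, low$annotations, 0.2)), 0)
  # permutation invariance
  perm <- sample(nrow(tabs$fits))
  mm2 <- map_median_ve(tabs$fits[perm, ], tabs$annotations, threshold = 0.2)
  expect_equal(mm2[order(mm2$model, mm2$split), "median_ve_cv"],
               mm[order(mm$model, mm$split), "median_ve_cv"])
})

test_that("eccentricity bins are half-open, counted and averaged correctly", {
  set.seed(13)
  n <- 260
  ecc <- c(0.05, runif(n - 1, 0, 1.4))
  tabs <- fake_fit_tables(ve_mono = runif(n, 0.2, 0.8),
                          ve_tuned = runif(n, 0.2, 0.8), ecc = ecc)
  b <- eccentricity_bins(tabs$fits, tabs$annotations, min_count = 50)
  expect_true(0.1 %in% b$center_deg)
  # voxel at 0.05 deg sits in the bin centered at 0.1 deg
  sel <- tabs$annotations$eccentricity_deg >= 0 &
    tabs$annotations$eccentricity_deg < 0.2
  expect_equal(b$n[b$center_deg == 0.1], 2 * sum(sel))  # two splits
  # direct mean/SEM oracle for one bin
  ids <- tabs$annotations$voxel_id[sel]
  vals <- tabs$fits$ve_cv[tabs$fits$model == "monotonic" &
                            tabs$fits$voxel_id %in% ids]
  expect_equal(b$mean_mono[b$center_deg == 0.1], mean(vals))
  expect_equal(b$sem_mono[b$center_deg == 0.1],
               sd(vals) / sqrt(length(vals)))
  # a 49-measurement bin is dropped
  b2 <- eccentricity_bins(tabs$fits, tabs$annotations,
                          min_count = 2 * sum(sel) + 1)
  expect_false(0.1 %in% b2$center_deg)
})

test_that("eccentricity progressions select the right curve family", {
  x <- seq(0.1, 5.5, by = 0.2)
  set.seed(17)
  y_sig <- 0.65 - 0.45 * pnorm(1.8 * (x - 2.2)) + rnorm(length(x), 0, 0.005)
  f1 <- fit_eccentricity_progression(x, y_sig, n_boot = 200, seed = 3)
  expect_equal(f1$chosen, "sigmoid")
  expect_lt(abs(abs(f1$sigmoid$params["inflection"]) - 2.2), 0.3)
  expect_true(all(f1$sigmoid$ci[1, ] <= f1$sigmoid$ci[2, ] + 1e-12))
  # exactly linear means: the quadratic (which nests a line) wins the tie
  y_lin <- 0.1 + 0.05 * x
  f2 <- fit_eccentricity_progression(x, y_lin, n_boot = 50, seed = 4)
  expect_equal(f2$chosen, "quadratic")
  expect_lt(abs(f2$quadratic$coef[3]), 1e-8)
  # constant means: deterministic fallback to the quadratic
  f3 <- fit_eccentricity_progression(x, rep(0.4, length(x)), n_boot = 50,
                                     seed = 5)
  expect_equal(f3$chosen, "quadratic")
})

test_that("near/far comparison finds engineered effects and null effects", {
  set.seed(23)
  n <- 120
  ecc <- runif(n, 0, 5.5)
  # monotonic VE decays with eccentricity, tuned VE flat
  tabs <- list()
  for (pt in 1:2) for (hm in 1:2) {
    ve_m <- pmax(0.05, 0.7 - 0.12 * ecc + rnorm(n, 0, 0.03))
    ve_t <- 0.4 + rnorm(n, 0, 0.03)
    tabs[[length(tabs) + 1]] <- fake_fit_tables(ve_m, ve_t, ecc,
                                                participant = pt,
                                                hemisphere = hm)
  }
  fits <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    f <- tabs[[i]]$fits; f$voxel_id <- f$voxel_id + (i - 1) * n; f
  }))
  ann <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    a <- tabs[[i]]$annotations; a$voxel_id <- a$voxel_id + (i - 1) * n; a
  }))
  nf <- near_far_compare(fits, ann)
  w <- nf$wilcoxon
  expect_lt(w$p_fdr[w$measure == "ve_mono"], 0.05)
  expect_gt(w$mean_near[w$measure == "ve_mono"],
            w$mean_far[w$measure == "ve_mono"])
  expect_gt(w$p_fdr[w$measure == "ve_tuned"], 0.05)
  # single-map cohort reduces to the two-factor ANOVA
  expect_named(nf$anova, c("ve_mono", "ve_tuned", "ve_diff"))
  expect_true(all(c("participant_id", "range") %in% nf$anova$ve_mono$term))
})

test_that("parameter medians exclude non-positive amplitude ratios", {
  tabs <- fake_fit_tables(c(0.5, 0.6), c(0.3, 0.4), c(1, 2))
  f <- tabs$fits
  f$amplitude_ratio[f$model == "monotonic" & f$voxel_id == 1] <- 0
  mp <- map_median_params(f, tabs$annotations, params = "amplitude_ratio",
                          threshold = 0.2)
  expect_equal(unique(mp$median_value), 1)  # only voxel 2's ratio remains
})

test_that("parameter comparisons across maps combine ANOVA, JB and Dunn", {
  set.seed(41)
  med <- expand.grid(participant_id = 1:4, hemisphere_id = 1:2,
                     split = c("A", "B"), map = c("V1", "V3", "TO1"))
  shift <- c(V1 = 0.2, V3 = 0.5, TO1 = 0.9)
  med$median_value <- shift[as.character(med$map)] + rnorm(nrow(med), 0, 0.05)
  med$parameter <- "exp_dur"
  cmp <- compare_params_across_maps(med, "exp_dur")
  expect_lt(cmp$anova$p[cmp$anova$term == "map"], 0.001)
  expect_equal(nrow(cmp$dunn), 3)  # three map pairs
  expect_lt(cmp$dunn$p_adj[cmp$dunn$group1 == "TO1" |
                             cmp$dunn$group2 == "TO1"][1], 0.05)
  expect_true(all(cmp$dunn$p_adj >= cmp$dunn$p - 1e-12))
})
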