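# Map-level aggregation and the statistical comparisons: model-vs-model
# within maps, parameter differences across maps, and eccentricity analyses.

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Map-level median variance explained
#'
#' Per map x hemisphere x split medians of each model's cross-validated VE
#' over voxels passing the training-VE threshold (a voxel passes when either
#' model's training VE in that split exceeds `threshold`). Cells with no
#' passing voxel are absent.
#'
#' @param fits Fit table from [fit_cohort()].
#' @param annotations Cohort annotations (must share `voxel_id`).
#' @param threshold Training-VE cutoff (0, 0.2 and 0.4 are the standard
#'   sensitivity settings).
#' @return Data.frame: `map`, `hierarchy_index`, `participant_id`,
#'   `hemisphere_id`, `split`, `model`, `median_ve_cv`, `median_ve_train`,
#'   `n_voxels`.
#' @export
map_median_ve <- function(fits, annotations, threshold = 0.2) {
  d <- merge(fits, annotations, by = "voxel_id")
  if (nrow(d) == 0) return(d[, 0])
  # per voxel x split: passes if either model's training VE > threshold
  pass <- stats::aggregate(ve_train ~ voxel_id + split, d, max)
  names(pass)[3] <- "max_ve_train"
  d <- merge(d, pass, by = c("voxel_id", "split"))
  d <- d[d$max_ve_train > threshold, , drop = FALSE]
  if (nrow(d) == 0) return(d[, 0])
  agg <- function(col) stats::aggregate(
    d[[col]],
    by = list(map = d$map, hierarchy_index = d$hierarchy_index,
              participant_id = d$participant_id,
              hemisphere_id = d$hemisphere_id, split = d$split,
              model = d$model),
    FUN = stats::median)
  out <- agg("ve_cv"); names(out)[7] <- "median_ve_cv"
  out$median_ve_train <- agg("ve_train")$x
  cnt <- stats::aggregate(
    d$ve_cv,
    by = list(map = d$map, hierarchy_index = d$hierarchy_index,
              participant_id = d$participant_id,
              hemisphere_id = d$hemisphere_id, split = d$split,
              model = d$model),
    FUN = length)
  out$n_voxels <- cnt$x
  out
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided test. Zero differences are dropped. For small samples
#' without ties (`n <= 25`) the p value comes from the exact signed-rank
#' null distribution; otherwise from the normal approximation with midrank
#' tie correction and a 0.5 continuity correction. The Z statistic is
#' always the (corrected) normal deviate, the quantity reported alongside
#' the effect size `r = Z/sqrt(n)`. All-zero differences return
#' `Z = 0, p = 1` by convention.
#'
#' @param x,y Paired numeric vectors, or a single vector of differences in
#'   `x` with `y` missing.
#' @param exact_max Largest tie-free n for which the exact distribution is
#'   used.
#' @return List with `Z`, `p`, `n` (informative pairs), `W` (positive-rank
#'   sum).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(Z = 0, p = 1, n = 0L, W = 0))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(Z = 0, p = 1, n = n, W = w))
  cc <- sign(w - mu) * 0.5
  z <- (w - mu - cc) / sqrt(sig2)
  if (w == mu) z <- 0
  if (n <= exact_max && !any(duplicated(r))) {
    p <- min(1, 2 * min(stats::psignrank(w, n),
                        stats::psignrank(w - 1, n, lower.tail = FALSE)))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(Z = z, p = p, n = as.integer(n), W = w)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values (monotone, never smaller than the input).
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Effect size r from a Z statistic
#'
#' `r = Z / sqrt(n)`, the standard effect size for the signed-rank Z.
#'
#' @param Z Z statistic.
#' @param n Number of paired measurements.
#' @return Effect size r.
#' @export
effect_size_r <- function(Z, n) {
  stopifnot(n > 0)
  Z / sqrt(n)
}

#' Bootstrap percentile confidence interval of the median
#'
#' @param values Numeric vector (nonempty).
#' @param n_iter Bootstrap iterations (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling stream.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_median_ci <- function(values, n_iter = 1000, level = 0.95,
                                seed = 1) {
  stopifnot(length(values) > 0)
  meds <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i)
      stats::median(sample(values, length(values), replace = TRUE)),
      numeric(1))
  })
  a <- (1 - level) / 2
  as.numeric(stats::quantile(meds, c(a, 1 - a), type = 7, names = FALSE))
}

#' Fixed-effects n-factor ANOVA with chosen interactions
#'
#' Type III sums of squares on sum-to-zero contrasts (the convention of the
#' originating MATLAB anovan workflow), with partial eta squared
#' `SS_effect / (SS_effect + SS_error)` per term.
#'
#' @param table Data.frame with the response and factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (main effects).
#' @param interactions List of character vectors, each one interaction term.
#' @return Data.frame: `term`, `df`, `F`, `p`, `partial_eta_sq`.
#' @export
anova_nfactor <- function(table, response, factors, interactions = list()) {
  stopifnot(all(c(response, factors) %in% names(table)))
  d <- table
  for (f in factors) d[[f]] <- factor(d[[f]])
  terms <- c(factors, vapply(interactions, paste, "", collapse = ":"))
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  if (stats::var(d[[response]]) == 0) {
    return(data.frame(term = terms, df = NA_real_, F = 0, p = 1,
                      partial_eta_sq = 0))
  }
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: aliased coefficients in ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  a <- car::Anova(fit, type = 3)
  keep <- !(rownames(a) %in% c("(Intercept)", "Residuals"))
  ss_err <- a[rownames(a) == "Residuals", "Sum Sq"]
  data.frame(term = rownames(a)[keep], df = a$Df[keep],
             F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
             partial_eta_sq = a$`Sum Sq`[keep] /
               (a$`Sum Sq`[keep] + ss_err))
}

#' Dunn's rank-based post hoc test with Holm-Sidak correction
#'
#' Pairwise z statistics on pooled midranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))`, followed by step-down Sidak
#' adjustment of the two-sided p values.
#'
#' @param groups Named list of numeric vectors, one per group (each
#'   nonempty).
#' @return Data.frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_holm_sidak <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 1)) stop("each group needs >= 1 value")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  n_tot <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  prs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[k] <- min(1, 2 * stats::pnorm(-abs(z[k])))
  }
  data.frame(group1 = prs[1, ], group2 = prs[2, ], z = z, p = p,
             p_adj = holm_sidak(p))
}

#' Holm-Sidak step-down adjustment
#'
#' Orders p ascending; the i-th smallest becomes
#' `1 - (1 - p_(i))^(m - i + 1)`, with a running maximum to keep the
#' adjustment monotone.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values in the input order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 (skew^2 + excess_kurtosis^2 / 4)` with a chi-squared(2)
#' reference distribution; used as the gate before falling back to
#' nonparametric post hoc tests.
#'
#' @param values Numeric vector, `n >= 8`.
#' @return List with `statistic` and `p`.
#' @export
jarque_bera <- function(values) {
  n <- length(values)
  stopifnot(n >= 8)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(list(statistic = 0, p = 1))
  skew <- mean((values - m)^3) / m2^1.5
  kurt <- mean((values - m)^4) / m2^2 - 3
  jb <- n / 6 * (skew^2 + kurt^2 / 4)
  list(statistic = jb, p = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Model-vs-model comparison per map
#'
#' For each map, a paired two-sided Wilcoxon signed-rank test of the tuned
#' vs monotonic median cross-validated VE, pairing hemisphere x split x
#' participant measurements, with BH-FDR correction across maps, effect
#' size `r = Z/sqrt(n)` and bootstrap CIs of each model's median. The
#' `bayes_factor` column is a placeholder (not computed) so the table
#' layout matches downstream expectations.
#'
#' @param map_medians Output of [map_median_ve()].
#' @param n_boot Bootstrap iterations for the median CIs.
#' @param seed Seed for the bootstrap.
#' @return Data.frame, one row per map, with medians, CIs, `Z`, `p`,
#'   `p_fdr`, `effect_r`, `n_pairs`, `bayes_factor` (NA).
#' @export
compare_models_by_map <- function(map_medians, n_boot = 1000, seed = 1) {
  mm <- map_medians
  maps <- unique(mm[, c("map", "hierarchy_index")])
  maps <- maps[order(maps$hierarchy_index), ]
  rows <- vector("list", nrow(maps))
  for (i in seq_len(nrow(maps))) {
    d <- mm[mm$map == maps$map[i], ]
    id_cols <- c("participant_id", "hemisphere_id", "split")
    wide <- merge(d[d$model == "tuned", c(id_cols, "median_ve_cv")],
                  d[d$model == "monotonic", c(id_cols, "median_ve_cv")],
                  by = id_cols, suffixes = c("_tuned", "_mono"))
    tun <- wide$median_ve_cv_tuned
    mon <- wide$median_ve_cv_mono
    wt <- wilcoxon_signed_rank(tun, mon)
    ci_t <- bootstrap_median_ci(tun, n_boot, seed = seed + i)
    ci_m <- bootstrap_median_ci(mon, n_boot, seed = seed + 1000 + i)
    rows[[i]] <- data.frame(
      map = maps$map[i], hierarchy_index = maps$hierarchy_index[i],
      median_tuned = stats::median(tun), ci_tuned_lo = ci_t[1],
      ci_tuned_hi = ci_t[2], median_mono = stats::median(mon),
      ci_mono_lo = ci_m[1], ci_mono_hi = ci_m[2],
      median_diff = stats::median(tun - mon),
      Z = wt$Z, p = wt$p, n_pairs = wt$n,
      effect_r = effect_size_r(wt$Z, max(wt$n, 1)),
      bayes_factor = NA_real_)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p)
  out
}

#' Eccentricity-binned variance explained
#'
#' Pools voxels within a map across hemispheres and splits, bins them by
#' preferred eccentricity (half-open bins `[center - w/2, center + w/2)`),
#' and returns the per-bin mean cross-validated VE and SEM for each model
#' and for the tuned - monotonic difference. Voxels where both models'
#' training VE is at or below `ve_floor` are excluded; bins with fewer than
#' `min_count` voxel-split measurements are dropped.
#'
#' @param fits Fit table from [fit_cohort()].
#' @param annotations Cohort annotations with `eccentricity_deg`.
#' @param bin_width Bin width in degrees (0.2).
#' @param centers Bin centers (0.1 to 5.5 by 0.2).
#' @param min_count Minimum measurements per bin (50).
#' @param ve_floor Exclusion floor on both models' training VE (0).
#' @return Data.frame: `map`, `center_deg`, `n`, `mean_mono`, `sem_mono`,
#'   `mean_tuned`, `sem_tuned`, `mean_diff`, `sem_diff`.
#' @export
eccentricity_bins <- function(fits, annotations, bin_width = 0.2,
                              centers = seq(0.1, 5.5, by = 0.2),
                              min_count = 50, ve_floor = 0) {
  d <- merge(fits, annotations, by = "voxel_id")
  pass <- stats::aggregate(ve_train ~ voxel_id + split, d, max)
  names(pass)[3] <- "max_ve_train"
  d <- merge(d, pass, by = c("voxel_id", "split"))
  d <- d[d$max_ve_train > ve_floor, , drop = FALSE]
  wide <- merge(
    d[d$model == "monotonic",
      c("voxel_id", "split", "map", "eccentricity_deg", "ve_cv")],
    d[d$model == "tuned", c("voxel_id", "split", "ve_cv")],
    by = c("voxel_id", "split"), suffixes = c("_mono", "_tuned"))
  lo <- centers - bin_width / 2
  hi <- centers + bin_width / 2
  rows <- list()
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  for (m in unique(wide$map)) {
    dm <- wide[wide$map == m, ]
    for (b in seq_along(centers)) {
      sel <- dm$eccentricity_deg >= lo[b] & dm$eccentricity_deg < hi[b]
      if (sum(sel) < min_count) next
      db <- dm[sel, ]
      diff <- db$ve_cv_tuned - db$ve_cv_mono
      rows[[length(rows) + 1]] <- data.frame(
        map = m, center_deg = centers[b], n = nrow(db),
        mean_mono = mean(db$ve_cv_mono), sem_mono = sem(db$ve_cv_mono),
        mean_tuned = mean(db$ve_cv_tuned), sem_tuned = sem(db$ve_cv_tuned),
        mean_diff = mean(diff), sem_diff = sem(diff))
    }
  }
  if (length(rows) == 0)
    return(data.frame(map = character(), center_deg = numeric(),
                      n = integer(), mean_mono = numeric(),
                      sem_mono = numeric(), mean_tuned = numeric(),
                      sem_tuned = numeric(), mean_diff = numeric(),
                      sem_diff = numeric()))
  do.call(rbind, rows)
}

#' Fit the eccentricity progression of bin means
#'
#' Fits a cumulative-Gaussian sigmoid (inflection, slope, maximum, minimum)
#' and a quadratic (intercept, slope, quadratic term) to per-bin means, and
#' selects the curve whose fitted values correlate best with the bin means.
#' Sigmoid CIs come from bootstrap resampling of the bins; the quadratic CI
#' is the analytic pointwise band from the linear fit.
#'
#' @param centers Bin centers (degrees).
#' @param means Per-bin mean values.
#' @param n_boot Bootstrap iterations for the sigmoid CI (default 10000;
#'   reduce for exploratory use).
#' @param level CI level.
#' @param seed Bootstrap seed.
#' @return List with `chosen` ("sigmoid" or "quadratic"), `sigmoid`
#'   (parameters, `r`, bootstrap CI matrix or NULL), `quadratic`
#'   (coefficients, `r`, confidence band), `converged` (sigmoid fit
#'   succeeded).
#' @export
fit_eccentricity_progression <- function(centers, means, n_boot = 10000,
                                         level = 0.95, seed = 1) {
  stopifnot(length(centers) == length(means), length(means) >= 5)
  d <- data.frame(x = centers, y = means)
  qfit <- stats::lm(y ~ x + I(x^2), data = d)
  q_r <- if (stats::sd(stats::fitted(qfit)) == 0 || stats::sd(d$y) == 0) 0
         else stats::cor(stats::fitted(qfit), d$y)
  q_band <- stats::predict(qfit, interval = "confidence", level = level)
  sig_fml <- y ~ minimum + (maximum - minimum) *
    stats::pnorm(slope * (x - inflection))
  xy_cor <- if (stats::sd(d$y) == 0) 0 else stats::cor(d$x, d$y)
  start <- list(inflection = stats::median(centers),
                slope = if (xy_cor < 0) -1 else 1,
                maximum = max(means), minimum = min(means))
  sfit <- try(suppressWarnings(
    minpack.lm::nlsLM(sig_fml, data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))),
    silent = TRUE)
  converged <- !inherits(sfit, "try-error")
  s_r <- -Inf
  s_par <- NULL
  s_ci <- NULL
  if (converged) {
    s_par <- stats::coef(sfit)
    fv <- stats::fitted(sfit)
    s_r <- if (stats::sd(fv) == 0 || stats::sd(d$y) == 0) 0
           else stats::cor(fv, d$y)
    boots <- with_seed(seed, {
      n <- nrow(d)
      out <- matrix(NA_real_, n_boot, 4)
      for (i in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        bf <- try(suppressWarnings(
          minpack.lm::nlsLM(sig_fml, data = d[idx, ], start = as.list(s_par),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100))), silent = TRUE)
        if (!inherits(bf, "try-error")) out[i, ] <- stats::coef(bf)
      }
      out
    })
    a <- (1 - level) / 2
    s_ci <- apply(boots, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE)
    colnames(s_ci) <- names(s_par)
  }
  chosen <- if (!converged || q_r >= s_r) "quadratic" else "sigmoid"
  list(chosen = chosen, converged = converged,
       sigmoid = list(params = s_par, r = s_r, ci = s_ci),
       quadratic = list(coef = stats::coef(qfit), r = q_r, band = q_band))
}

#' Near vs far eccentricity comparison of model fits
#'
#' Computes, per hemisphere x split x map, the mean cross-validated VE over
#' voxels in a near (`< near_deg`) and a far (`> far_min_deg` and
#' `< far_max_deg`) eccentricity range (excluding voxels where both models'
#' training VE is at or below `ve_floor`), then runs a fixed-effects ANOVA
#' (participant, map, eccentricity range; interaction map x range) and
#' per-map paired Wilcoxon tests with BH-FDR and effect size r, for the
#' monotonic VE, the tuned VE, and the tuned - monotonic difference.
#'
#' @param fits Fit table from [fit_cohort()].
#' @param annotations Cohort annotations with `eccentricity_deg`.
#' @param near_deg Near-range upper bound (1 degree).
#' @param far_min_deg,far_max_deg Far-range bounds (2 and 5.6 degrees).
#' @param ve_floor Exclusion floor on both models' training VE (0).
#' @return List with `cells` (the per-range mean VE table), `anova` (per
#'   measure), and `wilcoxon` (per map x measure, with `p_fdr` within
#'   measure and a `bayes_factor` NA placeholder).
#' @export
near_far_compare <- function(fits, annotations, near_deg = 1,
                             far_min_deg = 2, far_max_deg = 5.6,
                             ve_floor = 0) {
  d <- merge(fits, annotations, by = "voxel_id")
  pass <- stats::aggregate(ve_train ~ voxel_id + split, d, max)
  names(pass)[3] <- "max_ve_train"
  d <- merge(d, pass, by = c("voxel_id", "split"))
  d <- d[d$max_ve_train > ve_floor, , drop = FALSE]
  d$range <- ifelse(d$eccentricity_deg < near_deg, "near",
                    ifelse(d$eccentricity_deg > far_min_deg &
                           d$eccentricity_deg < far_max_deg, "far", NA))
  d <- d[!is.na(d$range), , drop = FALSE]
  wide <- merge(
    d[d$model == "monotonic",
      c("voxel_id", "split", "participant_id", "hemisphere_id", "map",
        "range", "ve_cv")],
    d[d$model == "tuned", c("voxel_id", "split", "ve_cv")],
    by = c("voxel_id", "split"), suffixes = c("_mono", "_tuned"))
  wide$diff <- wide$ve_cv_tuned - wide$ve_cv_mono
  cells <- stats::aggregate(
    cbind(ve_mono = wide$ve_cv_mono, ve_tuned = wide$ve_cv_tuned,
          ve_diff = wide$diff),
    by = list(participant_id = wide$participant_id,
              hemisphere_id = wide$hemisphere_id, split = wide$split,
              map = wide$map, range = wide$range),
    FUN = mean)
  measures <- c("ve_mono", "ve_tuned", "ve_diff")
  anovas <- lapply(measures, function(m) {
    n_map <- length(unique(cells$map))
    facs <- c("participant_id", "map", "range")
    ints <- list(c("map", "range"))
    if (n_map < 2) { facs <- c("participant_id", "range"); ints <- list() }
    anova_nfactor(cells, m, facs, ints)
  })
  names(anovas) <- measures
  wil <- list()
  for (m in measures) {
    for (mp in unique(cells$map)) {
      cm <- cells[cells$map == mp, ]
      wv <- merge(cm[cm$range == "near",
                     c("participant_id", "hemisphere_id", "split", m)],
                  cm[cm$range == "far",
                     c("participant_id", "hemisphere_id", "split", m)],
                  by = c("participant_id", "hemisphere_id", "split"),
                  suffixes = c("_near", "_far"))
      if (nrow(wv) == 0) next
      wt <- wilcoxon_signed_rank(wv[[paste0(m, "_near")]],
                                 wv[[paste0(m, "_far")]])
      wil[[length(wil) + 1]] <- data.frame(
        measure = m, map = mp, mean_near = mean(wv[[paste0(m, "_near")]]),
        mean_far = mean(wv[[paste0(m, "_far")]]), Z = wt$Z, p = wt$p,
        n_pairs = wt$n, effect_r = effect_size_r(wt$Z, max(wt$n, 1)),
        bayes_factor = NA_real_)
    }
  }
  wil <- do.call(rbind, wil)
  if (!is.null(wil)) {
    wil$p_fdr <- NA_real_
    for (m in measures) {
      sel <- wil$measure == m
      wil$p_fdr[sel] <- fdr_bh(wil$p[sel])
    }
  }
  list(cells = cells, anova = anovas, wilcoxon = wil)
}

#' Per-map median model parameters
#'
#' Median fitted parameter values per map x hemisphere x split, over voxels
#' whose training VE for that model and split exceeds `threshold`. For the
#' monotonic amplitude ratio, voxels without a positive response to one
#' component (ratio 0 or infinite/undefined) are excluded.
#'
#' @param fits Fit table from [fit_cohort()].
#' @param annotations Cohort annotations.
#' @param params Parameter columns to summarize.
#' @param threshold Per-model, per-split training-VE cutoff (0.2).
#' @return Long data.frame: map, hierarchy_index, participant, hemisphere,
#'   split, model, parameter, median value, n.
#' @export
map_median_params <- function(fits, annotations,
                              params = c("exp_dur", "exp_freq",
                                         "amplitude_ratio",
                                         "pref_duration_ms",
                                         "pref_period_ms", "sigma_major_ms",
                                         "sigma_minor_ms", "theta_rad"),
                              threshold = 0.2) {
  d <- merge(fits, annotations, by = "voxel_id")
  d <- d[d$ve_train > threshold, , drop = FALSE]
  rows <- list()
  for (pcol in params) {
    dp <- d[!is.na(d[[pcol]]), , drop = FALSE]
    if (pcol == "amplitude_ratio")
      dp <- dp[is.finite(dp$amplitude_ratio) & dp$amplitude_ratio > 0, ,
               drop = FALSE]
    if (nrow(dp) == 0) next
    ag <- stats::aggregate(
      dp[[pcol]],
      by = list(map = dp$map, hierarchy_index = dp$hierarchy_index,
                participant_id = dp$participant_id,
                hemisphere_id = dp$hemisphere_id, split = dp$split,
                model = dp$model),
      FUN = stats::median)
    names(ag)[7] <- "median_value"
    ag$parameter <- pcol
    rows[[length(rows) + 1]] <- ag
  }
  do.call(rbind, rows)
}

#' Compare a parameter's per-map medians across maps
#'
#' Two-factor fixed-effects ANOVA (participant, map) on the per-map median
#' parameter values, gated by Jarque-Bera normality, followed by Dunn's
#' test with Holm-Sidak correction across maps.
#'
#' @param medians Output of [map_median_params()] filtered to one model.
#' @param parameter Which parameter column to compare.
#' @return List with `anova`, `jarque_bera`, and `dunn` tables.
#' @export
compare_params_across_maps <- function(medians, parameter) {
  d <- medians[medians$parameter == parameter, , drop = FALSE]
  stopifnot(nrow(d) > 0)
  an <- anova_nfactor(d, "median_value", c("participant_id", "map"))
  jb <- jarque_bera(d$median_value - stats::ave(d$median_value, d$map))
  groups <- split(d$median_value, d$map)
  list(anova = an, jarque_bera = jb, dunn = dunn_holm_sidak(groups))
}
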