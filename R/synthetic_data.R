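# Synthetic cohort generator: participants x hemispheres x maps with
# per-map mixtures of ground-truth monotonic and tuned voxels, an
# eccentricity-dependent monotonic SNR, and split-half noise realizations.

#' Cohort generation configuration
#'
#' Defines the cohort structure the analysis assumes: a set of visual field
#' maps ordered by a hierarchy index, a tuned-voxel fraction that rises
#' logistically along that hierarchy, foveally-weighted eccentricity
#' sampling, and an eccentricity-dependent loss of monotonic signal
#' strength (realized as a rising noise SD, since every signal is
#' z-normalized before noise is added).
#'
#' @param n_participants Participants (experiment cohort: 8).
#' @param n_hemispheres Hemispheres per participant (2).
#' @param maps Map labels, ordered posterior to anterior; hierarchy index is
#'   their rank.
#' @param voxels_per_map Voxels per map per hemisphere.
#' @param tuned_fraction_range Tuned fraction at the bottom / top of the
#'   hierarchy; the fraction follows a logistic curve in the rank between
#'   these endpoints.
#' @param ecc_range_deg Eccentricity support in degrees (0 to 5.6).
#' @param ecc_rate_deg Scale of the truncated-exponential eccentricity
#'   sampling (denser near the fovea).
#' @param mono_ecc_decay_deg Eccentricity scale over which the monotonic
#'   component's effective SNR decays (noise SD multiplied by
#'   `exp(ecc / scale)`); tuned voxels are unaffected.
#' @param noise_sd_range Per-voxel base noise SD band (uniform draw).
#' @param amplitude_mean,amplitude_sd Affine output scaling (see
#'   [degrade()]).
#' @param seed Master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 8, n_hemispheres = 2,
                          maps = c("V1", "V2", "V3", "hV4", "LO1", "TO1",
                                   "IPS0", "IPS1", "sPCS1", "iPCS"),
                          voxels_per_map = 100,
                          tuned_fraction_range = c(0.1, 0.9),
                          ecc_range_deg = c(0, 5.6), ecc_rate_deg = 2,
                          mono_ecc_decay_deg = 1.5,
                          noise_sd_range = c(0.4, 1.6),
                          amplitude_mean = 100, amplitude_sd = 2,
                          seed = 1) {
  stopifnot(n_participants > 0, n_hemispheres > 0, voxels_per_map > 0,
            length(maps) >= 1, all(tuned_fraction_range >= 0),
            all(tuned_fraction_range <= 1),
            diff(tuned_fraction_range) >= 0, ecc_rate_deg > 0,
            mono_ecc_decay_deg > 0, diff(noise_sd_range) >= 0)
  structure(list(n_participants = n_participants,
                 n_hemispheres = n_hemispheres, maps = maps,
                 voxels_per_map = voxels_per_map,
                 tuned_fraction_range = tuned_fraction_range,
                 ecc_range_deg = ecc_range_deg,
                 ecc_rate_deg = ecc_rate_deg,
                 mono_ecc_decay_deg = mono_ecc_decay_deg,
                 noise_sd_range = noise_sd_range,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, seed = seed),
            class = "cohort_config")
}

# Logistic tuned fraction over hierarchy ranks, scaled between the
# configured endpoints; non-decreasing by construction.
tuned_fraction_curve <- function(n_maps, range) {
  if (n_maps == 1) return(mean(range))
  r <- seq_len(n_maps)
  z <- stats::plogis((r - (n_maps + 1) / 2) / (n_maps / 8))
  z01 <- (z - min(z)) / (max(z) - min(z))
  range[1] + z01 * diff(range)
}

# Truncated-exponential eccentricity draw on [lo, hi].
draw_eccentricity <- function(n, lo, hi, rate_deg) {
  u <- stats::runif(n)
  lim <- 1 - exp(-(hi - lo) / rate_deg)
  lo - rate_deg * log(1 - u * lim)
}

#' Generate a synthetic cohort
#'
#' Each voxel draws a ground-truth kind from its map's tuned fraction and
#' ground-truth parameters from the broad distributions of
#' [draw_ground_truth()] (tuned preferences restricted to the presented
#' range so map-level tuning is recoverable), simulates the noiseless
#' signal with the shared forward path, and produces two split-half
#' realizations with independent noise via [degrade()]. A monotonic voxel's
#' noise SD is multiplied by `exp(ecc / mono_ecc_decay_deg)` so its
#' effective SNR falls with eccentricity; tuned voxels' SNR is
#' eccentricity-independent.
#'
#' @param config A [cohort_config()].
#' @param dm [design_matrices()] output.
#' @return List (class `timing_cohort`) with `annotations` (voxel_id,
#'   participant_id, hemisphere_id, map, hierarchy_index, timing_map,
#'   eccentricity_deg, polar_angle_deg), `tc_a` / `tc_b` (voxel x TR
#'   matrices), `ground_truth` (true kind, true parameters, effective noise
#'   SD), and `config`.
#' @export
generate_cohort <- function(config, dm) {
  stopifnot(inherits(config, "cohort_config"))
  n_maps <- length(config$maps)
  frac <- tuned_fraction_curve(n_maps, config$tuned_fraction_range)
  ann <- list(); gt <- list(); tcs_a <- list(); tcs_b <- list()
  vid <- 0L
  for (pt in seq_len(config$n_participants)) {
    for (hm in seq_len(config$n_hemispheres)) {
      for (mi in seq_len(n_maps)) {
        nv <- config$voxels_per_map
        vseed <- (config$seed * 104729 + pt * 9973 + hm * 7919 + mi * 104) %%
          .Machine$integer.max
        draws <- with_seed(vseed, list(
          kind = ifelse(stats::runif(nv) < frac[mi], "tuned", "monotonic"),
          ecc = draw_eccentricity(nv, config$ecc_range_deg[1],
                                  config$ecc_range_deg[2],
                                  config$ecc_rate_deg),
          ang = stats::runif(nv, 0, 360),
          nsd = stats::runif(nv, config$noise_sd_range[1],
                             config$noise_sd_range[2])))
        p_mono <- draw_ground_truth("monotonic", nv, seed = vseed + 1)
        p_tuned <- draw_ground_truth("tuned", nv, seed = vseed + 2,
                                     ranges = list(pref = c(100, 900)))
        for (v in seq_len(nv)) {
          vid <- vid + 1L
          kind <- draws$kind[v]
          pars <- if (kind == "tuned") p_tuned[[v]] else p_mono[[v]]
          nsd_eff <- if (kind == "monotonic")
            draws$nsd[v] * exp(draws$ecc[v] / config$mono_ecc_decay_deg)
          else draws$nsd[v]
          nsd_eff <- min(nsd_eff, 6)
          tc <- simulate_noiseless(pars, dm)
          pair <- degrade(tc, nsd_eff, config$amplitude_mean,
                          config$amplitude_sd,
                          seed = (vseed + 7907 * v) %% .Machine$integer.max)
          ann[[vid]] <- data.frame(
            voxel_id = vid, participant_id = pt, hemisphere_id = hm,
            map = config$maps[mi], hierarchy_index = mi,
            timing_map = NA_character_, eccentricity_deg = draws$ecc[v],
            polar_angle_deg = draws$ang[v])
          gt[[vid]] <- data.frame(
            voxel_id = vid, true_kind = kind, noise_sd = nsd_eff,
            exp_dur = if (kind == "monotonic") pars$exp_dur else NA_real_,
            exp_freq = pars$exp_freq,
            beta_dur = if (kind == "monotonic") pars$beta_dur else NA_real_,
            beta_freq = if (kind == "monotonic") pars$beta_freq else NA_real_,
            pref_duration_ms = if (kind == "tuned") pars$pref_duration_ms
                               else NA_real_,
            pref_period_ms = if (kind == "tuned") pars$pref_period_ms
                             else NA_real_,
            sigma_major_ms = if (kind == "tuned") pars$sigma_major_ms
                             else NA_real_,
            sigma_minor_ms = if (kind == "tuned") pars$sigma_minor_ms
                             else NA_real_,
            theta_rad = if (kind == "tuned") pars$theta_rad else NA_real_)
          tcs_a[[vid]] <- pair$a
          tcs_b[[vid]] <- pair$b
        }
      }
    }
  }
  structure(list(annotations = do.call(rbind, ann),
                 tc_a = do.call(rbind, tcs_a),
                 tc_b = do.call(rbind, tcs_b),
                 ground_truth = do.call(rbind, gt),
                 config = config),
            class = "timing_cohort")
}

#' Write cohort fixtures as plain-text tables
#'
#' Writes `annotations.tsv`, `timecourses_a.tsv`, `timecourses_b.tsv`,
#' `ground_truth.tsv` and `config.json` into a directory.
#'
#' @param cohort A `timing_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixtures <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$annotations, "annotations.tsv")
  wt(as.data.frame(cohort$tc_a), "timecourses_a.tsv")
  wt(as.data.frame(cohort$tc_b), "timecourses_b.tsv")
  wt(cohort$ground_truth, "ground_truth.tsv")
  jsonlite::write_json(unclass(cohort$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read cohort fixtures back from a directory
#'
#' Inverse of [write_fixtures()]; validates that the annotation table has
#' the required columns and that the time-course matrices match it.
#'
#' @param in_dir Directory written by [write_fixtures()].
#' @return A `timing_cohort`.
#' @export
read_fixtures <- function(in_dir) {
  rd <- function(f) utils::read.delim(file.path(in_dir, f),
                                      check.names = FALSE)
  ann <- rd("annotations.tsv")
  req <- c("voxel_id", "participant_id", "hemisphere_id", "map",
           "hierarchy_index", "eccentricity_deg", "polar_angle_deg")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop("annotations.tsv is missing column(s): ",
         paste(miss, collapse = ", "))
  tc_a <- as.matrix(rd("timecourses_a.tsv"))
  tc_b <- as.matrix(rd("timecourses_b.tsv"))
  dimnames(tc_a) <- dimnames(tc_b) <- NULL
  if (nrow(tc_a) != nrow(ann) || nrow(tc_b) != nrow(ann))
    stop("time-course matrices do not match the annotation table")
  cfgl <- jsonlite::read_json(file.path(in_dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(cohort_config, cfgl[names(cfgl) %in%
                                       names(formals(cohort_config))])
  structure(list(annotations = ann, tc_a = tc_a, tc_b = tc_b,
                 ground_truth = rd("ground_truth.tsv"), config = cfg),
            class = "timing_cohort")
}
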