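# Shared fixtures built once per test session (design_matrices caches by
# HRF, so repeated calls are cheap).

test_dm <- local({
  dm <- NULL
  function() {
    if (is.null(dm)) dm <<- design_matrices(timing_design())
    dm
  }
})

# Small fabricated fit + annotation tables for statistics unit tests:
# `n` voxels whose monotonic and tuned VEs are supplied per voxel and
# replicated over the two splits.
fake_fit_tables <- function(ve_mono, ve_tuned, ecc, map = "V1",
                            hierarchy_index = 1, participant = 1,
                            hemisphere = 1, ve_train = NULL) {
  n <- length(ve_mono)
  if (is.null(ve_train)) ve_train <- pmax(ve_mono, ve_tuned)
  mk <- function(model, ve, split) data.frame(
    voxel_id = seq_len(n), model = model, split = split,
    ve_train = ve_train, ve_cv = ve, out_of_range = FALSE,
    classification = ifelse(ve_tuned > ve_mono, "tuned", "monotonic"),
    exp_dur = 0.5, exp_freq = 0.5, beta_dur = 1, beta_freq = 1,
    amplitude_ratio = 1, pref_duration_ms = 400, pref_period_ms = 700,
    sigma_major_ms = 300, sigma_minor_ms = 150, theta_rad = 0)
  fits <- rbind(mk("monotonic", ve_mono, "A"), mk("monotonic", ve_mono, "B"),
                mk("tuned", ve_tuned, "A"), mk("tuned", ve_tuned, "B"))
  ann <- data.frame(voxel_id = seq_len(n), participant_id = participant,
                    hemisphere_id = hemisphere, map = map,
                    hierarchy_index = hierarchy_index,
                    timing_map = NA_character_, eccentricity_deg = ecc,
                    polar_angle_deg = 0)
  list(fits = fits, annotations = ann)
}
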