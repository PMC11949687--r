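# Shared fixtures and small builders. Everything is generated in code; the
# only file I/O is through temporary files.

quick_ctrl <- function(...) mbma_control(n_starts = 1L, ...)

# PTH truth with switchable variability (defaults = reported final model)
pth_truth <- function(omega_emax = 0.193, omega_et50 = 0.677,
                      sigma = 1.463, slope = 0.503) {
  covs <- if (!is.null(slope)) {
    list(covariate_effect("baseline", slope = slope, reference = 636))
  } else {
    list()
  }
  model_spec("PTH", "emax_et50", emax = 308, et50 = 0.46,
             covariates = covs,
             iiv = list(emax = list(sd = omega_emax, scale = "proportional"),
                        et50 = list(sd = omega_et50, scale = "proportional")),
             residual_sd = sigma)
}

# neutral initial values for PTH fits (away from the truth)
pth_init <- function(slope = 0.3) {
  covs <- if (!is.null(slope)) {
    list(covariate_effect("baseline", slope = slope, reference = 636))
  } else {
    list()
  }
  model_spec("PTH", "emax_et50", emax = 250, et50 = 0.3,
             covariates = covs,
             iiv = list(emax = list(sd = 0.3, scale = "proportional"),
                        et50 = list(sd = 0.3, scale = "proportional")),
             residual_sd = 1)
}

# dataset of `n_studies` byte-identical noiseless studies (exchangeable in
# the strictest sense); baselines differ across the arms within a study so
# the covariate slope stays identified
identical_noiseless_data <- function(n_studies = 10L) {
  truth <- pth_truth(omega_emax = 0, omega_et50 = 0, sigma = 1e-9)
  rows <- do.call(rbind, lapply(seq_len(n_studies), function(s) {
    do.call(rbind, lapply(c(A1 = 450, A2 = 800), function(b) {
      t <- c(3, 6, 12, 24)
      data.frame(study_id = sprintf("S%02d", s), arm_id = paste0("A", b),
                 treatment = "cinacalcet", n = 100L, dose_low_mg = 30,
                 dose_high_mg = 180, outcome = "PTH", time_weeks = t,
                 observed_mean = b - effect_at(truth, weeks_to_months(t),
                                               baseline = b),
                 baseline_mean = b, is_change_from_baseline = FALSE,
                 vd_pct = 60, pb_pct = 90, dialysis_months = 50,
                 white_pct = 65, female_pct = 40, age_years = 55,
                 blinded = 1, region = "western",
                 stringsAsFactors = FALSE)
    }))
  }))
  trial_data(rows, outcome = "PTH")
}

# hand-built 3-arm dataset exercising change-from-baseline rows and missing
# covariates
three_arm_df <- function() {
  data.frame(
    study_id = c(rep("S1", 4), rep("S2", 2), rep("S3", 2)),
    arm_id = c(rep("A1", 2), rep("A2", 2), rep("A1", 2), rep("A1", 2)),
    treatment = c(rep("cinacalcet", 6), rep("control", 2)),
    n = c(120L, 120L, 80L, 80L, 45L, 45L, 50L, 50L),
    dose_low_mg = 30, dose_high_mg = 180, outcome = "PTH",
    time_weeks = rep(c(3, 12), 4),
    observed_mean = c(420.6, 348.5, -179.4, -251.4, 500.1, 430.2,
                      598.0, 597.5),
    baseline_mean = c(600, 600, 600, 600, 700, 700, 600, 600),
    is_change_from_baseline = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                                FALSE, FALSE),
    vd_pct = c(rep(66, 4), NA, NA, 50, 50),
    pb_pct = 90.3, dialysis_months = c(rep(49.2, 4), rep(80, 4)),
    white_pct = 65, female_pct = 40.8, age_years = 55.7,
    blinded = c(rep(1, 4), rep(0, 4)),
    region = c(rep("western", 4), rep("asia", 4)),
    stringsAsFactors = FALSE
  )
}
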