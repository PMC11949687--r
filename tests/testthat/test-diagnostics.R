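# Diagnostics on small, fast fixtures. Nominal-coverage and replicate-scale
# properties are in test-acceptance.R.

# shared exchangeable fixture: 10 byte-identical noiseless studies
ident <- identical_noiseless_data(10L)
ident_truth <- pth_truth(omega_emax = 0, omega_et50 = 0, sigma = 1e-6)
ident_fit <- suppressMessages(mbma(ident, ident_truth,
                                   quick_ctrl(se = FALSE)))

test_that("bootstrap over identical studies collapses to zero-width intervals", {
  expect_error(mbma_bootstrap(ident_fit, B = 1), "at least 2")
  bt <- mbma_bootstrap(ident_fit, B = 10, seed = 4)
  expect_identical(bt$n_failed, 0L)
  # every resample is the same dataset, so every refit is the same fit
  expect_equal(max(bt$ci95_high - bt$ci95_low), 0, tolerance = 1e-10)
  expect_equal(unname(bt$median), unname(coef(ident_fit)), tolerance = 1e-10)
})

test_that("bootstrap is reproducible given the seed", {
  cfg <- shpt_scenario("PTH", seed = 23)
  cfg$n_studies <- 6L
  d <- simulate_trials(cfg)
  f <- suppressMessages(mbma(d, shpt_pth_model(), quick_ctrl(se = FALSE)))
  b1 <- mbma_bootstrap(f, B = 3, seed = 11)
  b2 <- mbma_bootstrap(f, B = 3, seed = 11)
  expect_identical(b1$samples, b2$samples)
})

test_that("VPC percentile curves collapse onto the typical curve without variability", {
  expect_error(vpc(ident_fit, n_sim = 100), "at least 200")
  # homogeneous design (one identical arm per study) so the pooled
  # exact-time bins carry a single typical curve
  spec0 <- model_spec("PTH", "emax_et50", emax = 290, et50 = 0.46,
                      iiv = list(emax = list(sd = 0, scale = "proportional")),
                      residual_sd = 1e-6)
  t <- c(3, 6, 12, 24)
  rows <- do.call(rbind, lapply(1:6, function(s) {
    data.frame(study_id = sprintf("S%02d", s), arm_id = "A1",
               treatment = "cinacalcet", n = 100L, dose_low_mg = 30,
               dose_high_mg = 180, outcome = "PTH", time_weeks = t,
               observed_mean = 600 - effect_at(spec0, weeks_to_months(t)),
               baseline_mean = 600, is_change_from_baseline = FALSE,
               vd_pct = 60, pb_pct = 90, dialysis_months = 50,
               white_pct = 65, female_pct = 40, age_years = 55, blinded = 1,
               region = "western", stringsAsFactors = FALSE)
  }))
  d0 <- trial_data(rows, outcome = "PTH")
  f0 <- suppressMessages(mbma(d0, spec0, quick_ctrl(se = FALSE)))
  v <- vpc(f0, n_sim = 200, seed = 2)
  # collapsed band: orders of magnitude below the typical decrease (~290)
  expect_lt(max(v$percentiles$p97.5 - v$percentiles$p2.5), 0.01)
  typ <- effect_at(f0$spec, weeks_to_months(v$percentiles$time_weeks))
  expect_equal(v$percentiles$p50, typ, tolerance = 1e-4)
})

test_that("leave-one-out on exchangeable studies is invariant to the dropped study", {
  loo <- leave_one_out(ident_fit)
  expect_identical(nrow(loo$estimates), 10L)
  expect_length(loo$failed, 0L)
  spread <- apply(as.matrix(loo$estimates), 2L, function(v) diff(range(v)))
  expect_lt(max(spread / abs(coef(ident_fit))), 1e-8)
  expect_lt(max(loo$max_rel_dev), 1e-6)

  small <- identical_noiseless_data(3L)
  f3 <- structure(ident_fit, class = "mbma")
  f3$data <- small
  expect_error(leave_one_out(f3), "at least 4")
})

test_that("weighted residuals are zero on noiseless data and standard-normal under the model", {
  g <- goodness_of_fit(ident_fit)
  expect_lt(max(abs(g$weighted_residual)), 1e-3)

  # residual-dominated regime: no inter-study variability, sigma as reported
  truth <- pth_truth(omega_emax = 0, omega_et50 = 0, sigma = 1.463)
  cfg <- trial_sim_config("PTH", truth, n_studies = 15L, arms_per_study = 2L,
                          baseline_sampler = list(low = 300, median = 636,
                                                  high = 1100),
                          seed = 31)
  d <- simulate_trials(cfg)
  f <- suppressMessages(mbma(d, truth, quick_ctrl(se = FALSE)))
  g <- goodness_of_fit(f)
  expect_lt(abs(mean(g$weighted_residual)), 0.1)
  expect_gt(sd(g$weighted_residual), 0.8)
  expect_lt(sd(g$weighted_residual), 1.2)

  # a mis-specified onset form leaves systematic weighted residuals
  wrong <- model_spec("PTH", "exp_onset", emax = 300, k = 2,
                      covariates = list(covariate_effect("baseline", 0.503,
                                                         636)),
                      iiv = list(emax = list(sd = 1e-6,
                                             scale = "proportional")),
                      residual_sd = 1.463)
  fw <- suppressMessages(mbma(d, wrong, quick_ctrl(se = FALSE)))
  gw <- goodness_of_fit(fw)
  # the structural mismatch is absorbed into an inflated residual sd and
  # leaves a systematic residual trend over time
  expect_gt(fw$spec$residual_sd, 10 * f$spec$residual_sd)
  trend <- function(g) max(abs(tapply(g$weighted_residual, g$t_months, mean)))
  expect_gt(trend(gw), 2 * trend(g))
})
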