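# Deterministic structural-model arithmetic: typical effects, onset times,
# target-attainment solver. Printed reference values are reproduced to 1%
# (the published parameters are rounded).

pth <- shpt_pth_model()
ca <- shpt_ca_model()
p <- shpt_p_model()

test_that("typical decreases reproduce the reported simulation values", {
  # PTH, baseline 600: 12-week level 348.5 pg/mL
  expect_equal(600 - effect_at(pth, 3, baseline = 600), 348.5,
               tolerance = 0.01)
  # no effect at treatment start
  expect_identical(effect_at(pth, 0, baseline = 600), 0)
  expect_identical(effect_at(ca, 0, covariates = list(vd_pct = 50)), 0)
  # calcium, 50% vitamin-D use, 3 weeks: decrease 0.87 mg/dL
  expect_equal(effect_at(ca, 0.75, covariates = list(vd_pct = 50)), 0.87,
               tolerance = 0.01)
  # phosphorus plateaus at its maximal decrease by 12 weeks
  expect_equal(effect_at(p, 3), 0.524, tolerance = 0.01)
  expect_error(effect_at(pth, -1, baseline = 600), "non-negative")
  expect_error(effect_at(ca, 1), "vd_pct")
})

test_that("individualized maximal decrease applies centered linear terms", {
  expect_equal(individual_emax(pth, baseline = 600), 290, tolerance = 0.001)
  expect_identical(individual_emax(pth, baseline = 636), 308) # centering
  expect_equal(individual_emax(ca, covariates = list(vd_pct = 100)), 0.611,
               tolerance = 1e-3)
  # extrapolation guard: clamped at zero with a warning
  expect_warning(e <- individual_emax(pth, baseline = 20), "clamped")
  expect_identical(e, 0)
})

test_that("onset is monotone and the asymptote equals the individual emax", {
  t <- seq(0, 60, by = 0.25)
  for (spec in list(pth, ca, p)) {
    covs <- list(vd_pct = 40)
    eff <- effect_at(spec, t, covariates = covs, baseline = 800)
    expect_false(is.unsorted(eff))
    em <- individual_emax(spec, covariates = covs, baseline = 800)
    lim <- if (spec$form == "emax_et50") {
      em * 1e9 / (spec$et50 + 1e9) # hyperbolic limit probed at large t
    } else {
      effect_at(spec, 50, covariates = covs, baseline = 800)
    }
    expect_equal(lim, em, tolerance = 1e-9)
  }
})

test_that("time_to_fraction matches the reported onset times and inverts the onset", {
  expect_equal(time_to_fraction(pth, 0.5), 0.46, tolerance = 1e-12)
  expect_equal(time_to_fraction(ca, 0.5), 0.15, tolerance = 0.005)
  expect_equal(time_to_fraction(p, 0.5), 0.29, tolerance = 0.005)
  expect_equal(time_to_fraction(pth, 0.9), 9 * 0.46, tolerance = 1e-12)
  for (spec in list(pth, ca, p)) {
    for (pr in c(0.1, 0.5, 0.9, 0.99)) {
      tt <- time_to_fraction(spec, pr)
      eff <- effect_at(spec, tt, covariates = list(vd_pct = 66),
                       baseline = 636)
      em <- individual_emax(spec, covariates = list(vd_pct = 66),
                            baseline = 636)
      expect_equal(eff / em, pr, tolerance = 1e-9)
    }
  }
  expect_error(time_to_fraction(pth, 0), "strictly between")
  expect_error(time_to_fraction(pth, 1), "strictly between")
})

test_that("simulated profiles reproduce the published typical-value table", {
  # PTH rows (levels at 3/6/12/24 weeks per baseline)
  ref_pth <- rbind(
    `300` = c(213.9, 193.6, 179.4, 170.9),
    `600` = c(420.6, 378.3, 348.5, 330.7),
    `800` = c(557.9, 501.1, 461.3, 437.2),
    `1200` = c(833.1, 747.5, 687.1, 650.6)
  )
  for (b in rownames(ref_pth)) {
    prof <- simulate_profile(pth, baseline = as.numeric(b),
                             times_weeks = c(3, 6, 12, 24))
    expect_equal(prof$typical, unname(ref_pth[b, ]), tolerance = 0.01)
  }
  # calcium rows at baseline 9.7 per vitamin-D usage
  ref_ca <- rbind(
    `0` = c(8.54, 8.50, 8.50, 8.50),
    `50` = c(8.83, 8.80, 8.80, 8.79),
    `100` = c(9.11, 9.09, 9.09, 9.09)
  )
  for (v in rownames(ref_ca)) {
    prof <- simulate_profile(ca, baseline = 9.7,
                             covariates = list(vd_pct = as.numeric(v)),
                             times_weeks = c(3, 6, 12, 24))
    expect_equal(prof$typical, unname(ref_ca[v, ]), tolerance = 0.01)
  }
  # phosphorus row at baseline 5.785
  prof <- simulate_profile(p, baseline = 5.785, times_weeks = c(3, 6, 12, 24))
  expect_equal(prof$typical, c(5.353, 5.280, 5.261, 5.261), tolerance = 0.01)
})

test_that("uncertainty bands honour their contract", {
  prof <- simulate_profile(pth, baseline = 600, times_weeks = c(3, 6, 12, 24))
  expect_false("lower95" %in% names(prof)) # no uncertainty -> no band
  prof <- simulate_profile(pth, baseline = 600, times_weeks = c(3, 6, 12, 24),
                           uncertainty = list(param_draws = 500, seed = 7))
  expect_true(all(prof$lower95 <= prof$typical + 1e-12))
  expect_true(all(prof$typical <= prof$upper95 + 1e-12))
  again <- simulate_profile(pth, baseline = 600,
                            times_weeks = c(3, 6, 12, 24),
                            uncertainty = list(param_draws = 500, seed = 7))
  expect_identical(prof$lower95, again$lower95) # deterministic given seed
  expect_error(
    simulate_profile(pth, 600, times_weeks = 3,
                     uncertainty = list(param_draws = 50, seed = 1)),
    "param_draws"
  )
})

test_that("baseline threshold solver matches the reported 1046 pg/mL and a bisection oracle", {
  expect_equal(baseline_threshold_for_target(pth, 600, 3), 1046,
               tolerance = 0.001)
  # infinite horizon: closed form B = (600 + 308 - 0.503*636) / (1 - 0.503)
  expect_equal(baseline_threshold_for_target(pth, 600, Inf),
               (600 + 308 - 0.503 * 636) / (1 - 0.503), tolerance = 1e-9)
  # self-consistency: the 3-month level for baseline 600 maps back to 600
  lvl <- 600 - effect_at(pth, 3, baseline = 600)
  expect_equal(baseline_threshold_for_target(pth, lvl, 3), 600,
               tolerance = 1e-6)
  # bisection oracle on the defining equation
  bisect <- function(target, horizon) {
    g <- function(b) {
      b - effect_at(pth, horizon, baseline = b) - target
    }
    lo <- target
    hi <- 5000
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (target in c(400, 600, 900)) {
    for (horizon in c(1.5, 3, 6)) {
      expect_lt(abs(baseline_threshold_for_target(pth, target, horizon) -
                      bisect(target, horizon)), 0.1)
    }
  }
  steep <- model_spec("PTH", "emax_et50", emax = 308, et50 = 0.46,
                      covariates = list(covariate_effect("baseline", 1.5, 636)),
                      residual_sd = 1.463)
  expect_error(baseline_threshold_for_target(steep, 600, 3), "unreachable")
})
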