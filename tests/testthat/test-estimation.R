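# Estimation: exact-recovery limit, likelihood identities, quadrature
# agreement, invariances. The heavier replicate-based operating
# characteristics live in test-acceptance.R.

test_that("noiseless data are recovered exactly from the generating values", {
  truth <- pth_truth(omega_emax = 0, omega_et50 = 0, sigma = 1e-6)
  cfg <- trial_sim_config("PTH", truth, n_studies = 6L, arms_per_study = 2L,
                          baseline_sampler = list(low = 300, median = 600,
                                                  high = 1100),
                          seed = 2)
  d <- simulate_trials(cfg)
  f <- suppressMessages(mbma(d, truth, quick_ctrl(se = FALSE)))
  est <- coef(f)[c("emax", "et50", "slope_baseline")]
  expect_equal(unname(est), c(308, 0.46, 0.503), tolerance = 1e-3)
  expect_identical(f$convergence, "converged")
})

test_that("with vanishing random effects the OFV equals the closed-form WLS likelihood", {
  spec <- pth_truth(omega_emax = 1e-8, omega_et50 = 1e-8)
  cfg <- shpt_scenario("PTH", seed = 6)
  cfg$n_studies <- 5L
  cfg$truth <- spec # data from the vanishing-variability model itself
  d <- simulate_trials(cfg)
  recs <- pdmbma:::.prep_studies(d, spec, quiet = TRUE)
  theta <- pdmbma:::.theta_from_spec(spec)
  ofv <- pdmbma:::.ofv(theta, spec, recs, new.env())
  # fixed-effect weighted least-squares likelihood, assembled independently
  sig <- spec$residual_sd
  ll <- 0
  for (rec in recs) {
    E <- spec$emax + drop(rec$X %*% spec$covariates[[1]]$slope)
    m <- E * rec$t / (spec$et50 + rec$t)
    ll <- ll + sum(stats::dnorm(rec$y, m, sig / sqrt(rec$w), log = TRUE))
  }
  expect_equal(ofv, -2 * ll, tolerance = 1e-6)
})

test_that("Laplace and 64-node adaptive Gauss-Hermite agree on a 2-study toy", {
  spec <- shpt_pth_model()
  cfg <- shpt_scenario("PTH", seed = 9)
  cfg$n_studies <- 2L
  d <- simulate_trials(cfg)
  recs <- pdmbma:::.prep_studies(d, spec, quiet = TRUE)
  theta <- pdmbma:::.theta_from_spec(spec)
  o_lap <- pdmbma:::.ofv(theta, spec, recs, new.env())
  o_agq <- pdmbma:::.ofv(theta, spec, recs, new.env(),
                         method = "gauss_hermite",
                         gh = pracma::gaussHermite(64))
  expect_lt(abs(o_lap - o_agq), 0.1)
  # and at a second, deliberately wrong, parameter point
  theta2 <- theta + 0.15
  o_lap2 <- pdmbma:::.ofv(theta2, spec, recs, new.env())
  o_agq2 <- pdmbma:::.ofv(theta2, spec, recs, new.env(),
                          method = "gauss_hermite",
                          gh = pracma::gaussHermite(64))
  expect_lt(abs(o_lap2 - o_agq2), 0.1)
})

test_that("the objective is invariant to study ordering and row shuffling", {
  cfg <- shpt_scenario("PTH", seed = 11)
  cfg$n_studies <- 6L
  d <- simulate_trials(cfg)
  df <- as.data.frame(d)
  set.seed(1)
  shuffled <- trial_data(df[sample(nrow(df)), ], outcome = "PTH")
  f1 <- suppressMessages(mbma(d, pth_init(), quick_ctrl(se = FALSE)))
  f2 <- suppressMessages(mbma(shuffled, pth_init(), quick_ctrl(se = FALSE)))
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-8)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("doubling arm sizes matches halving the residual variance (weighting identity)", {
  spec <- shpt_pth_model()
  cfg <- shpt_scenario("PTH", seed = 13)
  cfg$n_studies <- 4L
  d <- simulate_trials(cfg)
  df2 <- as.data.frame(d)
  df2$n <- 2L * df2$n
  d2 <- trial_data(df2, outcome = "PTH")
  spec_half <- spec
  spec_half$residual_sd <- spec$residual_sd / sqrt(2)
  r1 <- pdmbma:::.prep_studies(d2, spec, quiet = TRUE)
  r2 <- pdmbma:::.prep_studies(d, spec_half, quiet = TRUE)
  o1 <- pdmbma:::.ofv(pdmbma:::.theta_from_spec(spec), spec, r1, new.env())
  o2 <- pdmbma:::.ofv(pdmbma:::.theta_from_spec(spec_half), spec_half, r2,
                      new.env())
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("preconditions and failure modes are reported, not thrown", {
  cfg <- shpt_scenario("PTH", seed = 1)
  cfg$n_studies <- 2L
  d2 <- simulate_trials(cfg)
  expect_error(suppressMessages(mbma(d2, shpt_pth_model())), "3 studies")
  cfg$n_studies <- 5L
  d5 <- simulate_trials(cfg)
  f <- suppressMessages(mbma(d5, pth_init(),
                             mbma_control(n_starts = 1L, max_iter = 1L,
                                          se = FALSE)))
  expect_s3_class(f, "mbma")
  expect_true(f$convergence %in% c("max_iter", "failed"))
})

test_that("fit methods are mutually consistent", {
  cfg <- shpt_scenario("PTH", seed = 21)
  cfg$n_studies <- 6L
  d <- simulate_trials(cfg)
  f <- suppressMessages(mbma(d, shpt_pth_model(), quick_ctrl()))
  expect_equal(unname(-2 * as.numeric(logLik(f))), f$ofv)
  pr <- predict(f)
  expect_equal(nrow(pr), f$n_obs)
  lv <- predict(f, type = "level")
  expect_equal(lv$observed - lv$predicted,
               -(pr$observed - pr$predicted), tolerance = 1e-12)
  r <- residuals(f)
  rw <- residuals(f, type = "weighted")
  expect_equal(rw, r * sqrt(pr$n) / f$spec$residual_sd, tolerance = 1e-12)
  ci <- confint(f)
  expect_true(all(ci[, "lower"] <= coef(f) & coef(f) <= ci[, "upper"]))
  V <- vcov(f)
  expect_equal(unname(sqrt(diag(V))), unname(f$se), tolerance = 1e-8)
  sims <- simulate(f, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "trial_data")
  sims2 <- simulate(f, nsim = 2, seed = 5)
  expect_identical(as.data.frame(sims[[1]]), as.data.frame(sims2[[1]]))
})
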