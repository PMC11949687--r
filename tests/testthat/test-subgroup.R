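# Median-split subgroup analysis.

# base fixture: homogeneous 16-study dataset and its fit
cfg0 <- shpt_scenario("PTH", seed = 7)
cfg0$n_studies <- 16L
d0 <- simulate_trials(cfg0)
fit0 <- suppressMessages(mbma(d0, shpt_pth_model(), quick_ctrl()))

test_that("a homogeneous dataset gives an indeterminate direction", {
  sg <- suppressMessages(subgroup_effect(d0, fit0, "dialysis_months",
                                         control = quick_ctrl()))
  expect_identical(sg$direction, "indeterminate")
  # the two group estimates sit inside each other's CI
  expect_true(sg$groups$low$typical_change <= sg$groups$high$ci95[2] &&
                sg$groups$low$typical_change >= sg$groups$high$ci95[1] ||
              sg$groups$high$typical_change <= sg$groups$low$ci95[2] &&
                sg$groups$high$typical_change >= sg$groups$low$ci95[1])
})

test_that("a constructed dialysis-duration effect is flagged high_greater", {
  # studies with long dialysis get a 30% larger maximal effect
  mk_half <- function(seed, boost, dial_sampler, ids) {
    cfg <- shpt_scenario("PTH", seed = seed)
    cfg$n_studies <- 12L
    cfg$truth$emax <- cfg$truth$emax * boost
    cfg$truth$covariates[[1]]$slope <- cfg$truth$covariates[[1]]$slope * boost
    cfg$covariate_samplers$dialysis_months <- dial_sampler
    df <- as.data.frame(simulate_trials(cfg))
    df$study_id <- sprintf("%s%02d", ids, as.integer(factor(df$study_id)))
    df
  }
  # paired design: both halves share the seed (same baselines,
  # covariates and random effects) and differ only in the boost
  lo <- mk_half(101, 1.0, function(n) rtriangular(n, 6, 25, 48), "L")
  hi <- mk_half(101, 1.3, function(n) rtriangular(n, 50, 80, 120), "H")
  d <- trial_data(rbind(lo, hi), outcome = "PTH")
  f <- suppressMessages(mbma(d, shpt_pth_model(), quick_ctrl()))
  sg <- suppressMessages(subgroup_effect(d, f, "dialysis_months",
                                         control = quick_ctrl()))
  expect_identical(sg$direction, "high_greater")
  expect_gt(sg$groups$high$typical_change, sg$groups$low$typical_change)
  # every long-dialysis study is in the high half
  expect_identical(sg$groups$high$n_studies, 12L)
})

test_that("preconditions and tie handling are enforced", {
  df <- as.data.frame(d0)
  df$dialysis_months[!df$study_id %in% sprintf("S%02d", 1:5)] <- NA
  d_na <- trial_data(df, outcome = "PTH")
  expect_error(
    suppressMessages(subgroup_effect(d_na, fit0, "dialysis_months")),
    "fewer than 6"
  )
  expect_warning(
    suppressMessages(subgroup_effect(d0, fit0, "baseline",
                                     method = "stratify")),
    "already a covariate"
  )
  # ties at the median go to the low group
  df <- as.data.frame(d0)
  med_ids <- sprintf("S%02d", 1:16)
  for (i in seq_along(med_ids)) {
    df$dialysis_months[df$study_id == med_ids[i]] <-
      c(10, 20, 20, 20, 20, 20, 20, 20, 20, 20, 30, 40, 50, 60, 70, 80)[i]
  }
  d_tie <- trial_data(df, outcome = "PTH")
  sg <- suppressMessages(subgroup_effect(d_tie, fit0, "dialysis_months",
                                         method = "stratify"))
  expect_equal(sg$split_value, 20)
  expect_identical(sg$groups$low$n_studies, 10L) # all ties in "low"
  expect_identical(sg$groups$high$n_studies, 6L)
})

test_that("the split is invariant to monotone transformation of the factor", {
  sg1 <- suppressMessages(subgroup_effect(d0, fit0, "dialysis_months",
                                          method = "stratify", seed = 3))
  df <- as.data.frame(d0)
  df$dialysis_months <- sqrt(df$dialysis_months)
  d_sqrt <- trial_data(df, outcome = "PTH")
  f_sqrt <- structure(fit0, class = "mbma")
  f_sqrt$data <- d_sqrt
  sg2 <- suppressMessages(subgroup_effect(d_sqrt, f_sqrt, "dialysis_months",
                                          method = "stratify", seed = 3))
  expect_identical(sg1$groups$low$n_studies, sg2$groups$low$n_studies)
  expect_equal(sg1$groups$low$typical_change, sg2$groups$low$typical_change,
               tolerance = 1e-8)
  expect_identical(sg1$direction, sg2$direction)
})

test_that("permuting the factor across studies destroys a null direction", {
  # under the null, a permuted factor should almost never produce a
  # direction flag
  set.seed(77)
  hits <- 0L
  for (i in 1:20) {
    df <- as.data.frame(d0)
    ids <- unique(df$study_id)
    perm <- sample(ids)
    map <- stats::setNames(
      vapply(ids, function(s)
        df$dialysis_months[df$study_id == s][1L], numeric(1))[perm], ids)
    df$dialysis_months <- map[df$study_id]
    dp <- trial_data(df, outcome = "PTH")
    fp <- structure(fit0, class = "mbma")
    fp$data <- dp
    sg <- suppressMessages(subgroup_effect(dp, fp, "dialysis_months",
                                           method = "stratify", seed = i))
    if (sg$direction != "indeterminate") hits <- hits + 1L
  }
  expect_lte(hits, 2L) # >= 90% indeterminate
})
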