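# External predictive check: model predictions vs observed arms from trials
# outside the fitted dose range (e.g. 30-180 mg model vs 25-100 mg arms).

#' External predictive check against held-out trial arms
#'
#' For each arm of an external dataset, predicts the typical
#' decrease-from-baseline trajectory at that arm's baseline and covariates
#' and surrounds it with a 95% *prediction* band that combines parameter
#' uncertainty (multivariate-normal draws on the estimation scale) with
#' inter-study variability (fresh random-effect draws) — external arms are
#' new studies, so both sources apply. Observed points are counted inside or
#' outside the band; the efficacy under the external dosing is judged
#' `"comparable"` when the overall inside fraction reaches `threshold`.
#'
#' @param fit an [mbma()] fit.
#' @param external a [trial_data()] dataset of held-out arms (same outcome).
#' @param seed integer seed.
#' @param n_draws simulation draws for the band.
#' @param threshold inside-fraction needed for a `"comparable"` verdict
#'   (default 0.8).
#' @return an `mbma_epc` object: `arms` (per arm: times, observed and
#'   predicted decreases, band), `inside_fraction`, `verdict`
#'   (`"comparable"`/`"discordant"`), `skipped` (arms missing a required
#'   covariate).
#' @export
external_predictive_check <- function(fit, external, seed = 1L,
                                      n_draws = 1000L, threshold = 0.8) {
  stopifnot(inherits(fit, "mbma"), inherits(external, "trial_data"))
  if (attr(external, "outcome") != fit$spec$outcome) {
    stop("external dataset outcome differs from the fitted model",
         call. = FALSE)
  }
  arms <- .mbma_arms(external, quiet = TRUE)
  if (!length(arms)) stop("external dataset is empty", call. = FALSE)
  spec <- fit$spec
  info <- .iiv_info(spec)
  om <- vapply(spec$iiv, `[[`, numeric(1), "sd")

  Vf <- fit$vcov_theta[fit$free, fit$free, drop = FALSE]
  L <- if (!anyNA(Vf)) tryCatch(chol(Vf), error = function(e) NULL)
  out_arms <- list()
  skipped <- character(0)
  n_in <- 0L
  n_tot <- 0L
  res <- .with_seed(seed, {
    Z <- if (!is.null(L)) {
      matrix(stats::rnorm(n_draws * nrow(Vf)), n_draws) %*% L
    }
    Eta <- if (info$q) {
      matrix(stats::rnorm(n_draws * info$q, 0, rep(om, each = n_draws)),
             n_draws)
    }
    for (arm in arms) {
      rec <- tryCatch(
        .prep_one_arm(arm, spec),
        error = function(e) NULL
      )
      if (is.null(rec)) {
        skipped <- c(skipped, paste(arm$study_id, arm$arm_id, sep = "/"))
        next
      }
      pars0 <- list(emax = spec$emax, onset = .onset_val(spec),
                    beta = vapply(spec$covariates, `[[`, numeric(1), "slope"))
      typical <- .study_mean(rec, spec$form, pars0, numeric(info$q), info)$m
      sim <- vapply(seq_len(n_draws), function(i) {
        sp <- spec
        if (!is.null(Z)) {
          th <- fit$theta
          th[fit$free] <- th[fit$free] + Z[i, ]
          sp <- .spec_from_theta(spec, th)
        }
        pars <- list(emax = sp$emax, onset = .onset_val(sp),
                     beta = vapply(sp$covariates, `[[`, numeric(1), "slope"))
        eta <- if (info$q) Eta[i, ] else numeric(0)
        .study_mean(rec, sp$form, pars, eta, info)$m
      }, numeric(rec$n_obs))
      sim <- matrix(sim, nrow = rec$n_obs)
      lo <- apply(sim, 1L, stats::quantile, 0.025, names = FALSE)
      hi <- apply(sim, 1L, stats::quantile, 0.975, names = FALSE)
      inside <- arm$decrease >= lo & arm$decrease <= hi
      n_in <- n_in + sum(inside)
      n_tot <- n_tot + length(inside)
      out_arms[[paste(arm$study_id, arm$arm_id, sep = "/")]] <- data.frame(
        study_id = arm$study_id, arm_id = arm$arm_id,
        time_weeks = arm$time_weeks, observed = arm$decrease,
        predicted_typical = typical, band_low = lo, band_high = hi,
        inside = inside)
    }
    list(out_arms = out_arms, skipped = skipped, n_in = n_in, n_tot = n_tot)
  })
  if (res$n_tot == 0L) {
    stop("no external arm carries the covariates the model requires",
         call. = FALSE)
  }
  inside_fraction <- res$n_in / res$n_tot
  structure(
    list(arms = res$out_arms, inside_fraction = inside_fraction,
         verdict = if (inside_fraction >= threshold) "comparable"
                   else "discordant",
         threshold = threshold, n_draws = n_draws, seed = seed,
         skipped = res$skipped),
    class = "mbma_epc"
  )
}

# one-arm record in the .study_mean layout; errors if a covariate is missing
.prep_one_arm <- function(arm, spec) {
  cov_names <- vapply(spec$covariates, `[[`, character(1), "covariate")
  refs <- vapply(spec$covariates, `[[`, numeric(1), "reference")
  xv <- numeric(length(cov_names))
  for (j in seq_along(cov_names)) {
    v <- arm$covariates[[cov_names[j]]]
    if (is.null(v) || is.na(v)) stop("missing covariate ", cov_names[j])
    xv[j] <- v - refs[j]
  }
  k <- length(arm$t_months)
  list(t = arm$t_months, n_obs = k,
       X = matrix(xv, k, length(cov_names), byrow = TRUE))
}

#' @export
print.mbma_epc <- function(x, ...) {
  cat("External predictive check (", length(x$arms), " arms, ",
      x$n_draws, " draws)\n", sep = "")
  cat("  observed points inside 95% prediction band: ",
      round(100 * x$inside_fraction, 1), "%  ->  ", x$verdict,
      " (threshold ", x$threshold, ")\n", sep = "")
  if (length(x$skipped)) {
    cat("  skipped arms (missing covariates): ",
        paste(x$skipped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
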