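# Model diagnostics: study-level bootstrap, visual predictive check,
# leave-one-out sensitivity, goodness-of-fit table.

# subset a trial_data by study ids, optionally relabelling duplicates so a
# study drawn twice acts as two independent random-effect units
.subset_studies <- function(data, ids, relabel = FALSE) {
  df <- as.data.frame(data)
  pieces <- lapply(seq_along(ids), function(i) {
    sub <- df[df$study_id == ids[i], , drop = FALSE]
    if (relabel) sub$study_id <- sprintf("%s#%d", ids[i], i)
    sub
  })
  trial_data(do.call(rbind, pieces), outcome = attr(data, "outcome"))
}

#' Nonparametric bootstrap of an MBMA fit
#'
#' Resamples *studies* (each with all its arms) with replacement, refits the
#' model on every resample starting from the point estimates, and summarizes
#' the parameter distributions by their median and 2.5/97.5 percentiles.
#' Studies are the exchangeable unit of the hierarchical model, so they are
#' the resampling unit. Refits that fail are dropped and counted; a failure
#' rate above 20% flags the result as unreliable.
#'
#' @param fit an [mbma()] fit.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed; results are reproducible given the seed.
#' @param control fit control for the refits; defaults to a single start
#'   from the point estimates, without standard errors.
#' @return an `mbma_boot` object: `samples` (B_ok x parameters matrix),
#'   `median`, `ci95_low`, `ci95_high`, `B`, `n_failed`, `unreliable`.
#' @export
mbma_bootstrap <- function(fit, B, seed = 1L,
                           control = mbma_control(n_starts = 1L, se = FALSE)) {
  stopifnot(inherits(fit, "mbma"))
  if (B < 2L) stop("B must be at least 2", call. = FALSE)
  ids <- unique(as.data.frame(fit$data)$study_id)
  draws <- .with_seed(seed, {
    replicate(B, sample(ids, length(ids), replace = TRUE), simplify = FALSE)
  })
  p <- length(fit$coefficients)
  samples <- matrix(NA_real_, B, p,
                    dimnames = list(NULL, names(fit$coefficients)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      db <- .subset_studies(fit$data, draws[[b]], relabel = TRUE)
      rf <- suppressMessages(mbma(db, fit$spec, control = control,
                                  fixed = fit$fixed))
      if (rf$convergence == "failed" || !is.finite(rf$ofv)) NULL
      else rf$coefficients
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else samples[b, ] <- res
  }
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  structure(
    list(samples = samples,
         median = apply(samples, 2L, stats::median),
         ci95_low = apply(samples, 2L, stats::quantile, 0.025, names = FALSE),
         ci95_high = apply(samples, 2L, stats::quantile, 0.975, names = FALSE),
         B = B, seed = seed, n_failed = n_failed,
         unreliable = n_failed > 0.2 * B),
    class = "mbma_boot"
  )
}

#' @export
print.mbma_boot <- function(x, ...) {
  cat("Study-level bootstrap (B = ", x$B, ", failed = ", x$n_failed,
      if (x$unreliable) ", UNRELIABLE (>20% failures)", ")\n", sep = "")
  print(round(cbind(median = x$median, `2.5%` = x$ci95_low,
                    `97.5%` = x$ci95_high), 4))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design (same studies,
#' covariates, visit schedule and arm sizes), drawing study random effects
#' and residual errors from the fitted model, and summarizes the simulated
#' decrease-from-baseline at each time by its 2.5th, 50th and 97.5th
#' percentiles. Observed arm means are overlaid and the fraction inside the
#' 95% band is reported. Because aggregate data sit on a scheduled visit
#' grid, the default binning is by exact observed time; quantile binning is
#' available for irregular schedules.
#'
#' @param fit an [mbma()] fit.
#' @param n_sim number of simulated replicates (>= 200 for stable tail
#'   percentiles).
#' @param seed integer seed.
#' @param bins `"exact"` (default) or `"quantile"`.
#' @param n_bins number of bins when `bins = "quantile"`.
#' @param data optional [trial_data()] to check against instead of the
#'   fitting data (e.g. a fresh replicate simulated from the model).
#' @return an `mbma_vpc` object: `percentiles` (time, p2.5, p50, p97.5),
#'   `observed` (time, observed decrease, n, study, arm), `coverage`,
#'   `n_sim`.
#' @export
vpc <- function(fit, n_sim = 500L, seed = 1L,
                bins = c("exact", "quantile"), n_bins = 4L, data = NULL) {
  stopifnot(inherits(fit, "mbma"))
  bins <- match.arg(bins)
  if (n_sim < 200L) {
    stop("n_sim must be at least 200 for stable percentile bands",
         call. = FALSE)
  }
  df <- as.data.frame(data %||% fit$data)
  df <- df[df$treatment == "cinacalcet", , drop = FALSE]
  obs_dec <- df$baseline_mean - df$observed_mean
  bin_id <- if (bins == "exact") {
    df$time_weeks
  } else {
    br <- unique(stats::quantile(df$time_weeks,
                                 probs = seq(0, 1, length.out = n_bins + 1L)))
    mids <- (br[-1L] + br[-length(br)]) / 2
    mids[cut(df$time_weeks, br, include.lowest = TRUE, labels = FALSE)]
  }
  sims <- .with_seed(seed, {
    vapply(seq_len(n_sim), function(i) .simulate_decreases(fit$spec, df),
           numeric(nrow(df)))
  })
  times <- sort(unique(bin_id))
  perc <- t(vapply(times, function(tt) {
    v <- as.vector(sims[bin_id == tt, , drop = FALSE])
    stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  }, numeric(3)))
  percentiles <- data.frame(time_weeks = times, p2.5 = perc[, 1L],
                            p50 = perc[, 2L], p97.5 = perc[, 3L])
  lo <- percentiles$p2.5[match(bin_id, times)]
  hi <- percentiles$p97.5[match(bin_id, times)]
  coverage <- mean(obs_dec >= lo & obs_dec <= hi)
  structure(
    list(percentiles = percentiles,
         observed = data.frame(time_weeks = df$time_weeks, bin = bin_id,
                               observed = obs_dec, n = df$n,
                               study_id = df$study_id, arm_id = df$arm_id),
         coverage = coverage, n_sim = n_sim, seed = seed, bins = bins),
    class = "mbma_vpc"
  )
}

#' @export
print.mbma_vpc <- function(x, ...) {
  cat("Visual predictive check (", x$n_sim, " simulations, ", x$bins,
      " bins)\n", sep = "")
  print(round(x$percentiles, 3), row.names = FALSE)
  cat("observed inside 95% band: ", round(100 * x$coverage, 1), "%\n",
      sep = "")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the model excluding each study in turn and tabulates the resulting
#' estimates together with each parameter's maximum relative deviation from
#' the full-data estimate. Large deviations point to influential studies.
#'
#' @param fit an [mbma()] fit on >= 4 studies.
#' @param control fit control for the refits.
#' @return an `mbma_loo` object: `estimates` (one row per excluded study),
#'   `max_rel_dev` per parameter, `failed` (study ids whose refit failed).
#' @export
leave_one_out <- function(fit, control = mbma_control(n_starts = 1L,
                                                      se = FALSE)) {
  stopifnot(inherits(fit, "mbma"))
  ids <- unique(as.data.frame(fit$data)$study_id)
  if (length(ids) < 4L) {
    stop("leave-one-out needs at least 4 studies", call. = FALSE)
  }
  est <- matrix(NA_real_, length(ids), length(fit$coefficients),
                dimnames = list(ids, names(fit$coefficients)))
  failed <- character(0)
  for (sid in ids) {
    res <- tryCatch({
      db <- .subset_studies(fit$data, setdiff(ids, sid))
      rf <- suppressMessages(mbma(db, fit$spec, control = control,
                                  fixed = fit$fixed))
      if (rf$convergence == "failed") NULL else rf$coefficients
    }, error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, sid) else est[sid, ] <- res
  }
  ok <- stats::complete.cases(est)
  rel <- abs(sweep(est[ok, , drop = FALSE], 2L, fit$coefficients, "-"))
  rel <- sweep(rel, 2L, abs(fit$coefficients), "/")
  structure(
    list(estimates = as.data.frame(est), full = fit$coefficients,
         max_rel_dev = apply(rel, 2L, max), failed = failed),
    class = "mbma_loo"
  )
}

#' @export
print.mbma_loo <- function(x, ...) {
  cat("Leave-one-out sensitivity (", nrow(x$estimates), " refits",
      if (length(x$failed)) paste0(", failed: ",
                                   paste(x$failed, collapse = ", ")),
      ")\n", sep = "")
  cat("max relative deviation from full-data estimates:\n")
  print(round(x$max_rel_dev, 4))
  invisible(x)
}

#' Goodness-of-fit table
#'
#' Per-observation population predictions (random effects at zero),
#' residuals, and weighted residuals `residual * sqrt(n) / sigma`, which are
#' approximately standard normal under a correctly specified model with
#' small inter-study variability.
#'
#' @param fit a converged [mbma()] fit.
#' @return data frame with columns `study_id`, `arm_id`, `t_months`,
#'   `observed`, `predicted`, `residual`, `weighted_residual`, `n`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "mbma"))
  if (fit$convergence == "failed") {
    stop("goodness_of_fit requires a converged fit", call. = FALSE)
  }
  pr <- predict(fit)
  pr$residual <- pr$observed - pr$predicted
  w <- if (fit$spec$residual_weighting == "inverse_sqrt_n") pr$n else 1
  pr$weighted_residual <- pr$residual * sqrt(w) / fit$spec$residual_sd
  pr
}
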