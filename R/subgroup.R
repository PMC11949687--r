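# Median-split subgroup analysis for factors outside the covariate model.

#' Median-split subgroup analysis
#'
#' Splits the studies at the across-study median of a factor (ties go to the
#' "low" group), refits the model within each half with the base model's
#' covariate slopes held fixed, and reports each half's model-typical change
#' from baseline at `t_months` with a 95% CI, evaluating all covariates at
#' their overall across-study medians so the halves differ only through the
#' split factor. The direction flag is set only when the two CIs do not
#' overlap.
#'
#' @param data a [trial_data()] dataset.
#' @param fit_base an [mbma()] fit of the base model on `data`.
#' @param factor factor to split on: a schema covariate column
#'   (`"dialysis_months"`, `"pb_pct"`, ...) or `"baseline"` (the arm's own
#'   baseline level). Must be reported by at least 6 studies.
#' @param t_months evaluation time (default 3 months = 12 weeks).
#' @param method `"refit"` (default: re-estimate each half) or `"stratify"`
#'   (no refit: apply each half's mean empirical-Bayes maximal-effect
#'   deviation to the base fit).
#' @param n_draws parameter draws for the CI.
#' @param seed integer seed for the CI draws.
#' @param control fit control for the half refits.
#' @return a `subgroup_report`: `factor`, `split_value`, `groups` (per half:
#'   `n_studies`, `typical_change`, `ci95`, `insufficient` flag),
#'   `direction` (`"high_greater"`, `"low_greater"`, `"indeterminate"`),
#'   `n_missing` (studies excluded for a missing factor).
#' @export
subgroup_effect <- function(data, fit_base, factor, t_months = 3,
                            method = c("refit", "stratify"),
                            n_draws = 2000L, seed = 1L,
                            control = mbma_control(n_starts = 1L)) {
  stopifnot(inherits(data, "trial_data"), inherits(fit_base, "mbma"))
  method <- match.arg(method)
  spec <- fit_base$spec
  in_model <- vapply(spec$covariates, `[[`, character(1), "covariate")
  if (factor %in% in_model) {
    warning("factor '", factor, "' is already a covariate in the base ",
            "model; the split largely re-expresses that effect",
            call. = FALSE)
  }
  fv <- .study_covariate(data, factor)
  n_missing <- sum(is.na(fv))
  fv <- fv[!is.na(fv)]
  if (length(fv) < 6L) {
    stop("factor '", factor, "' reported by fewer than 6 studies",
         call. = FALSE)
  }
  split_value <- stats::median(fv)
  low_ids <- names(fv)[fv <= split_value]   # ties assigned to "low"
  high_ids <- names(fv)[fv > split_value]

  # overall-median covariate configuration shared by both halves
  med_cov <- list()
  for (cov in unique(c(in_model, "baseline"))) {
    v <- .study_covariate(data, cov)
    med_cov[[cov]] <- stats::median(v[!is.na(v)])
  }
  med_baseline <- med_cov$baseline

  fixed_slopes <- NULL
  if (length(in_model)) {
    fixed_slopes <- vapply(spec$covariates, `[[`, numeric(1), "slope")
    names(fixed_slopes) <- paste0("slope_", in_model)
  }

  eval_half <- function(ids, half_seed) {
    if (length(ids) < 3L) {
      return(list(n_studies = length(ids), typical_change = NA_real_,
                  ci95 = c(NA_real_, NA_real_), insufficient = TRUE))
    }
    if (method == "refit") {
      half_fit <- tryCatch(
        suppressMessages(mbma(.subset_studies(data, ids), spec,
                              control = control, fixed = fixed_slopes)),
        error = function(e) NULL)
      if (is.null(half_fit) || half_fit$convergence == "failed") {
        return(list(n_studies = length(ids), typical_change = NA_real_,
                    ci95 = c(NA_real_, NA_real_), insufficient = TRUE))
      }
      hspec <- half_fit$spec
      V <- half_fit$vcov_theta
      th <- half_fit$theta
      fr <- half_fit$free
    } else {
      hspec <- spec
      if (!is.null(fit_base$eta) && "emax" %in% colnames(fit_base$eta)) {
        e <- fit_base$eta[rownames(fit_base$eta) %in% ids, "emax"]
        sc <- spec$iiv$emax$scale
        hspec$emax <- if (identical(sc, "proportional")) {
          spec$emax * exp(mean(e))
        } else {
          spec$emax + mean(e)
        }
      }
      V <- fit_base$vcov_theta
      th <- fit_base$theta
      fr <- fit_base$free
    }
    typ <- effect_at(hspec, t_months, covariates = med_cov,
                     baseline = med_baseline)
    ci <- .change_ci(hspec, th, V, fr, t_months, med_cov, med_baseline,
                     n_draws, half_seed)
    list(n_studies = length(ids), typical_change = typ, ci95 = ci,
         insufficient = FALSE)
  }

  low <- eval_half(low_ids, seed)
  high <- eval_half(high_ids, seed + 1L)

  direction <- "indeterminate"
  if (!low$insufficient && !high$insufficient &&
      all(is.finite(c(low$ci95, high$ci95)))) {
    if (high$ci95[1L] > low$ci95[2L]) direction <- "high_greater"
    if (low$ci95[1L] > high$ci95[2L]) direction <- "low_greater"
  }
  structure(
    list(factor = factor, split_value = split_value,
         groups = list(low = low, high = high), direction = direction,
         t_months = t_months, method = method, n_missing = n_missing),
    class = "subgroup_report"
  )
}

# 95% CI of the typical change at t from multivariate-normal draws of the
# free unconstrained parameters
.change_ci <- function(spec, theta, V, free, t_months, covariates, baseline,
                       n_draws, seed) {
  Vf <- V[free, free, drop = FALSE]
  if (anyNA(Vf)) return(c(NA_real_, NA_real_))
  L <- tryCatch(chol(Vf), error = function(e) NULL)
  if (is.null(L)) {
    L <- diag(sqrt(pmax(diag(Vf), 0)), nrow(Vf))
  }
  vals <- .with_seed(seed, {
    Z <- matrix(stats::rnorm(n_draws * nrow(Vf)), n_draws)
    Th <- Z %*% L
    vapply(seq_len(n_draws), function(i) {
      th <- theta
      th[free] <- th[free] + Th[i, ]
      sp <- .spec_from_theta(spec, th)
      suppressWarnings(effect_at(sp, t_months, covariates = covariates,
                                 baseline = baseline))
    }, numeric(1))
  })
  stats::quantile(vals, c(0.025, 0.975), names = FALSE)
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Subgroup analysis on '", x$factor, "' (split at ",
      format(x$split_value, digits = 4), ", change from baseline at ",
      x$t_months, " months)\n", sep = "")
  for (g in c("low", "high")) {
    grp <- x$groups[[g]]
    cat(sprintf("  %-4s: %d studies  change %s  (95%% CI %s, %s)%s\n", g,
                grp$n_studies, format(grp$typical_change, digits = 4),
                format(grp$ci95[1L], digits = 4),
                format(grp$ci95[2L], digits = 4),
                if (grp$insufficient) "  [insufficient]" else ""))
  }
  cat("  direction: ", x$direction, "\n", sep = "")
  if (x$n_missing) {
    cat("  studies excluded (factor missing): ", x$n_missing, "\n", sep = "")
  }
  invisible(x)
}
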