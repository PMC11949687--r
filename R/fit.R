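#' Control options for MBMA model fitting
#'
#' @param integration `"laplace"` (default) or `"gauss_hermite"` (adaptive,
#'   centered and scaled at the per-study mode).
#' @param nodes quadrature nodes per random-effect dimension for
#'   `"gauss_hermite"`.
#' @param n_starts number of optimizer starts: the supplied initial values
#'   plus `n_starts - 1` jittered copies; the fit with the lowest objective
#'   value wins.
#' @param jitter_sd standard deviation of the normal jitter applied to the
#'   unconstrained parameter vector for restarts.
#' @param seed integer seed controlling the jitter (and nothing else); fits
#'   are deterministic given data, initial values and control.
#' @param rel_tol relative convergence tolerance on the objective value.
#' @param max_iter outer iteration cap.
#' @param se compute standard errors from the observed information (disable
#'   for refit loops that only need point estimates).
#' @return a list of class `mbma_control`.
#' @export
mbma_control <- function(integration = c("laplace", "gauss_hermite"),
                         nodes = 9L, n_starts = 5L, jitter_sd = 0.2,
                         seed = 1L, rel_tol = 1e-8, max_iter = 500L,
                         se = TRUE) {
  integration <- match.arg(integration)
  stopifnot(nodes >= 1L, n_starts >= 1L, jitter_sd >= 0, max_iter >= 1L)
  structure(list(integration = integration, nodes = as.integer(nodes),
                 n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
                 seed = as.integer(seed), rel_tol = rel_tol,
                 max_iter = as.integer(max_iter), se = isTRUE(se)),
            class = "mbma_control")
}

#' Fit a pharmacodynamic time-course model to arm-level meta-analytic data
#'
#' Maximum marginal likelihood estimation of an [model_spec()] model on a
#' [trial_data()] dataset. Each study contributes a vector of study-level
#' random effects on the parameters named in `spec$iiv`; these are integrated
#' out per study by a Laplace approximation (default) or adaptive
#' Gauss-Hermite quadrature. Arm-mean decreases are weighted by arm sample
#' size (`residual_weighting = "inverse_sqrt_n"`: residual variance
#' `sigma^2 / n`). Optimization is bounded quasi-Newton on an unconstrained
#' transform (log for positive parameters), restarted from jittered initials.
#'
#' @param data a [trial_data()] dataset (cinacalcet arms are modelled;
#'   control arms are dropped).
#' @param spec an [model_spec()] carrying the structural form and initial
#'   values.
#' @param control an [mbma_control()] list.
#' @param fixed optional named numeric vector of natural-scale parameters to
#'   hold fixed during optimization (names as in `coef()`, e.g.
#'   `c(slope_baseline = 0.503)`).
#' @return an object of class `mbma` with components `spec` (estimates filled
#'   in), `coefficients`, `se`, `rse_pct`, `ofv` (-2 log marginal
#'   likelihood), `vcov_theta`, `convergence` (`"converged"`, `"max_iter"`,
#'   `"failed"`), `eta` (empirical Bayes study effects), and sizes
#'   `n_studies`, `n_arms`, `n_obs`. Non-convergence is reported through
#'   `convergence`, not as an error.
#' @seealso [mbma_bootstrap()], [vpc()], [leave_one_out()],
#'   [goodness_of_fit()], [covariate_search()].
#' @export
mbma <- function(data, spec, control = mbma_control(), fixed = NULL) {
  stopifnot(inherits(data, "trial_data"), inherits(spec, "mbma_model"),
            inherits(control, "mbma_control"))
  recs <- .prep_studies(data, spec)
  if (length(recs) < 3L) {
    stop("at least 3 studies with usable arms are required (got ",
         length(recs), ")", call. = FALSE)
  }
  n_obs <- sum(vapply(recs, `[[`, numeric(1), "n_obs"))
  n_arms <- sum(vapply(recs, function(r) length(r$arm_ids), numeric(1)))

  theta0 <- .theta_from_spec(spec)
  p <- length(theta0)
  t_names <- names(theta0)
  nb <- length(spec$covariates)
  is_log <- rep(TRUE, p)
  if (nb) is_log[2L + seq_len(nb)] <- FALSE
  lower <- ifelse(is_log, log(1e-8), -1e4)
  upper <- ifelse(is_log, log(1e8), 1e4)

  free <- rep(TRUE, p)
  if (!is.null(fixed)) {
    nat_names <- .natural_names(spec)
    for (nm in names(fixed)) {
      j <- match(nm, nat_names)
      if (is.na(j)) stop("unknown fixed parameter: ", nm, call. = FALSE)
      theta0[j] <- if (is_log[j]) log(fixed[[nm]]) else fixed[[nm]]
      free[j] <- FALSE
    }
  }

  gh <- if (control$integration == "gauss_hermite") {
    pracma::gaussHermite(control$nodes)
  }
  cache <- new.env(parent = emptyenv())
  full_theta <- theta0
  obj <- function(th_free) {
    full_theta[free] <- th_free
    .ofv(full_theta, spec, recs, cache,
         method = control$integration, gh = gh)
  }

  starts <- list(theta0[free])
  if (control$n_starts > 1L) {
    rng <- .with_seed(control$seed, {
      lapply(seq_len(control$n_starts - 1L), function(i) {
        theta0[free] + stats::rnorm(sum(free), 0, control$jitter_sd)
      })
    })
    starts <- c(starts, rng)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(st, obj, lower = lower[free], upper = upper[free],
                    control = list(rel.tol = control$rel_tol,
                                   iter.max = control$max_iter,
                                   eval.max = 4L * control$max_iter)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  convergence <- if (best$convergence == 0) {
    "converged"
  } else if (grepl("iteration|evaluation", best$message %||% "")) {
    "max_iter"
  } else {
    # nlminb codes relative-convergence stops as 1 with an explanatory
    # message; treat x-/rel-convergence as converged
    if (grepl("converg", tolower(best$message %||% ""))) "converged"
    else "failed"
  }

  theta_hat <- theta0
  theta_hat[free] <- best$par
  spec_hat <- .spec_from_theta(spec, theta_hat)
  nat <- .natural_from_theta(spec, theta_hat)

  # refresh the mode cache at the optimum, then harvest study effects
  .ofv(theta_hat, spec, recs, cache, method = control$integration, gh = gh)
  q <- length(spec$iiv)
  eta <- if (q) {
    e <- vapply(recs, function(r) {
      v <- cache[[r$study_id]]
      if (is.null(v)) numeric(q) else v
    }, numeric(q))
    e <- if (q == 1L) matrix(e, ncol = 1L) else t(e)
    colnames(e) <- names(spec$iiv)
    rownames(e) <- names(recs)
    e
  }

  # observed information on the free unconstrained parameters
  nll <- function(th_free) obj(th_free) / 2
  se <- rep(NA_real_, p)
  names(se) <- names(nat)
  vcov_theta <- matrix(NA_real_, p, p, dimnames = list(t_names, t_names))
  H <- if (control$se) {
    tryCatch(.fd_hessian(nll, best$par), error = function(e) NULL)
  }
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      vcov_theta[free, free] <- V
      se_theta <- sqrt(diag(V))
      # delta method: log-scale se -> natural se
      se[free] <- se_theta * ifelse(is_log[free], nat[free], 1)
    }
  }
  rse_pct <- 100 * se / abs(nat)
  spec_hat$rse_pct <- {
    r <- rse_pct[c("emax", .onset_par(spec),
                   if (nb) paste0("slope_",
                                  vapply(spec$covariates, `[[`, character(1),
                                         "covariate")))]
    r[!is.na(r)]
  }

  structure(
    list(spec = spec_hat, coefficients = nat, se = se, rse_pct = rse_pct,
         ofv = best$objective, vcov_theta = vcov_theta, theta = theta_hat,
         free = free, is_log = is_log, convergence = convergence,
         eta = eta, n_studies = length(recs), n_arms = n_arms, n_obs = n_obs,
         excluded_arms = attr(recs, "excluded_arms"),
         data = data, control = control, fixed = fixed,
         message = best$message),
    class = "mbma"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.mbma <- function(x, ...) {
  cat("MBMA time-course model fit (", x$spec$outcome, ", ", x$spec$form,
      ", ", x$control$integration, ")\n", sep = "")
  cat("  studies: ", x$n_studies, "  arms: ", x$n_arms, "  observations: ",
      x$n_obs, "\n", sep = "")
  cat("  OFV (-2 log marginal likelihood): ", format(x$ofv, digits = 8),
      "\n  convergence: ", x$convergence, "\n", sep = "")
  print(round(cbind(estimate = x$coefficients, `rse%` = x$rse_pct), 4))
  invisible(x)
}

#' @export
summary.mbma <- function(object, ...) {
  ci <- confint(object)
  tab <- cbind(estimate = object$coefficients, se = object$se,
               `rse%` = object$rse_pct, ci)
  structure(list(table = tab, ofv = object$ofv,
                 convergence = object$convergence,
                 n_studies = object$n_studies, n_arms = object$n_arms,
                 n_obs = object$n_obs, outcome = object$spec$outcome,
                 excluded_arms = object$excluded_arms),
            class = "summary.mbma")
}

#' @export
print.summary.mbma <- function(x, ...) {
  cat("MBMA fit (", x$outcome, "): ", x$n_studies, " studies, ", x$n_arms,
      " arms, ", x$n_obs, " observations", sep = "")
  if (x$excluded_arms) cat(" (", x$excluded_arms, " arms excluded)", sep = "")
  cat("\nOFV: ", format(x$ofv, digits = 8), "   convergence: ",
      x$convergence, "\n\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.mbma <- function(object, ...) object$coefficients

#' @export
logLik.mbma <- function(object, ...) {
  structure(-object$ofv / 2, df = sum(object$free), class = "logLik")
}

#' @export
vcov.mbma <- function(object, ...) {
  # natural-scale covariance by the delta method from the unconstrained scale
  nat <- object$coefficients
  J <- diag(ifelse(object$is_log, nat, 1))
  V <- J %*% object$vcov_theta %*% t(J)
  dimnames(V) <- list(names(nat), names(nat))
  V
}

#' Wald confidence intervals for an MBMA fit
#'
#' Intervals are computed on the unconstrained estimation scale (log for
#' positive parameters) and back-transformed, so bounds for `emax`, `et50`,
#' `k`, variabilities and `sigma` are positive by construction.
#'
#' @param object an `mbma` fit.
#' @param parm parameters to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.mbma <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_theta <- sqrt(diag(object$vcov_theta))
  lo <- object$theta - z * se_theta
  hi <- object$theta + z * se_theta
  lo[object$is_log] <- exp(lo[object$is_log])
  hi[object$is_log] <- exp(hi[object$is_log])
  out <- cbind(lower = lo, upper = hi)
  rownames(out) <- names(object$coefficients)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Population predictions from an MBMA fit
#'
#' @param object an `mbma` fit.
#' @param newdata optional [trial_data()]; defaults to the fitting data.
#' @param type `"decrease"` (change from baseline, positive = fell) or
#'   `"level"` (absolute biomarker level).
#' @param ... unused.
#' @return data frame with one row per modelled observation: study, arm,
#'   time, observation and population prediction (random effects at zero).
#' @export
predict.mbma <- function(object, newdata = NULL,
                         type = c("decrease", "level"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  recs <- .prep_studies(data, object$spec, quiet = TRUE)
  info <- .iiv_info(object$spec)
  nb <- length(object$spec$covariates)
  pars <- list(emax = object$spec$emax, onset = .onset_val(object$spec),
               beta = vapply(object$spec$covariates, `[[`, numeric(1),
                             "slope"))
  rows <- lapply(recs, function(rec) {
    m <- .study_mean(rec, object$spec$form, pars, numeric(info$q), info)$m
    data.frame(study_id = rec$study_id, arm_id = rec$arm_ids[rec$arm_of],
               t_months = rec$t, observed = rec$y, predicted = m, n = rec$w)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (type == "level") {
    arms <- .mbma_arms(data, quiet = TRUE)
    bl <- vapply(arms, `[[`, numeric(1), "baseline")
    names(bl) <- vapply(arms, function(a) paste(a$study_id, a$arm_id,
                                                sep = "\r"), character(1))
    key <- paste(out$study_id, out$arm_id, sep = "\r")
    out$observed <- bl[key] - out$observed
    out$predicted <- bl[key] - out$predicted
  }
  out
}

#' @export
fitted.mbma <- function(object, ...) predict(object)$predicted

#' Residuals of an MBMA fit
#'
#' @param object an `mbma` fit.
#' @param type `"response"` (observed minus population-predicted decrease) or
#'   `"weighted"` (response residual times `sqrt(n) / sigma`, approximately
#'   standard normal under the model when inter-study variability is small).
#' @param ... unused.
#' @export
residuals.mbma <- function(object, type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  pr <- predict(object)
  r <- pr$observed - pr$predicted
  if (type == "weighted") {
    w <- if (object$spec$residual_weighting == "inverse_sqrt_n") pr$n else 1
    r <- r * sqrt(w) / object$spec$residual_sd
  }
  r
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new study random effects and residual errors at the observed design
#' (same studies, arms, covariates, times and sample sizes) and returns
#' complete [trial_data()] replicates. This is the engine behind [vpc()].
#'
#' @param object an `mbma` fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` `trial_data` objects.
#' @export
simulate.mbma <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(object$data)
  df <- df[df$treatment == "cinacalcet", , drop = FALSE]
  replicate(nsim, {
    sim <- .simulate_decreases(object$spec, df)
    out <- df
    out$observed_mean <- out$baseline_mean - sim
    out$is_change_from_baseline <- FALSE
    trial_data(out, outcome = attr(object$data, "outcome"))
  }, simplify = FALSE)
}

# Simulate decrease-from-baseline values for every row of a schema data
# frame, drawing study random effects and n-weighted residuals from `spec`.
# Uses the current RNG state.
.simulate_decreases <- function(spec, df) {
  info <- .iiv_info(spec)
  nb <- length(spec$covariates)
  pars <- list(emax = spec$emax, onset = .onset_val(spec),
               beta = vapply(spec$covariates, `[[`, numeric(1), "slope"))
  om <- vapply(spec$iiv, `[[`, numeric(1), "sd")
  out <- numeric(nrow(df))
  for (sid in unique(df$study_id)) {
    idx <- which(df$study_id == sid)
    eta <- if (info$q) stats::rnorm(info$q, 0, om) else numeric(0)
    sub <- df[idx, , drop = FALSE]
    # build a one-study record
    cov_names <- vapply(spec$covariates, `[[`, character(1), "covariate")
    refs <- vapply(spec$covariates, `[[`, numeric(1), "reference")
    X <- matrix(0, length(idx), nb)
    for (j in seq_len(nb)) {
      v <- if (cov_names[j] == "baseline") sub$baseline_mean
           else sub[[cov_names[j]]]
      X[, j] <- v - refs[j]
    }
    rec <- list(t = weeks_to_months(sub$time_weeks), X = X,
                n_obs = length(idx))
    m <- .study_mean(rec, spec$form, pars, eta, info)$m
    sd_res <- if (spec$residual_weighting == "inverse_sqrt_n") {
      spec$residual_sd / sqrt(sub$n)
    } else {
      rep(spec$residual_sd, length(idx))
    }
    out[idx] <- m + stats::rnorm(length(idx), 0, sd_res)
  }
  out
}
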