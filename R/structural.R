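# Structural time-course evaluation, typical-effect simulation and
# target-attainment solvers.

# Fraction of the maximal effect reached at time t (months):
# hyperbolic form t/(ET50+t), asymptotic form 1 - exp(-K t).
.time_fraction <- function(spec, t_months) {
  if (spec$form == "emax_et50") {
    t_months / (spec$et50 + t_months)
  } else {
    1 - exp(-spec$k * t_months)
  }
}

# Resolve the covariate values a spec needs. `covariates` is a named
# list/vector; the special name "baseline" falls back to the `baseline`
# argument (an arm's own baseline level is the covariate in the PTH model).
.resolve_covariates <- function(spec, covariates, baseline) {
  vals <- numeric(0)
  for (ce in spec$covariates) {
    v <- covariates[[ce$covariate]]
    if (is.null(v) || anyNA(v)) {
      if (ce$covariate == "baseline" && !is.null(baseline)) {
        v <- baseline
      } else {
        stop("covariate '", ce$covariate, "' required by the model but not ",
             "supplied", call. = FALSE)
      }
    }
    if (length(v) != 1L) {
      stop("covariate '", ce$covariate, "' must be a single value (one ",
           "arm's configuration)", call. = FALSE)
    }
    vals[ce$covariate] <- v
  }
  vals
}

#' Individualized maximal decrease for a covariate configuration
#'
#' Applies the model's linear centered covariate effects:
#' `emax + sum(slope * (value - reference))`. A negative result can only
#' arise outside the calibration range of the covariates; it is clamped to 0
#' with a warning, as a maximal *decrease* below zero is not interpretable.
#'
#' @param spec an [model_spec()] object.
#' @param covariates named list of covariate values; may be omitted when the
#'   only covariate is `"baseline"` and `baseline` is given.
#' @param baseline arm baseline level, used when the model's covariate is the
#'   baseline itself.
#' @return the individualized maximal decrease (outcome units).
#' @examples
#' individual_emax(shpt_pth_model(), baseline = 600) # about 290 pg/mL
#' @export
individual_emax <- function(spec, covariates = NULL, baseline = NULL) {
  stopifnot(inherits(spec, "mbma_model"))
  vals <- .resolve_covariates(spec, covariates, baseline)
  e <- spec$emax
  for (ce in spec$covariates) {
    e <- e + ce$slope * (vals[[ce$covariate]] - ce$reference)
  }
  if (e < 0) {
    warning("individualized emax negative (covariates outside the ",
            "calibration range); clamped to 0", call. = FALSE)
    e <- 0
  }
  e
}

#' Typical decrease from baseline at a given time
#'
#' Evaluates the structural model: the individualized maximal decrease (see
#' [individual_emax()]) times the onset fraction `t/(ET50+t)` (hyperbolic
#' form) or `1 - exp(-K t)` (asymptotic form). Time is in months (4 weeks);
#' the decrease is 0 at `t = 0`.
#'
#' @inheritParams individual_emax
#' @param t_months vector of non-negative times in months.
#' @return vector of typical decreases from baseline (outcome units).
#' @examples
#' # typical PTH level at 12 weeks from a baseline of 600 pg/mL:
#' 600 - effect_at(shpt_pth_model(), 3, baseline = 600)
#' @export
effect_at <- function(spec, t_months, covariates = NULL, baseline = NULL) {
  stopifnot(inherits(spec, "mbma_model"))
  if (any(t_months < 0)) {
    stop("t_months must be non-negative", call. = FALSE)
  }
  individual_emax(spec, covariates, baseline) * .time_fraction(spec, t_months)
}

#' Time to reach a fraction of the maximal effect
#'
#' Inverts the onset function: `ET50 * p / (1 - p)` for the hyperbolic form,
#' `-log(1 - p) / K` for the asymptotic form. The drug's onset time reported
#' as "time to 50% of maximal effect" is `time_to_fraction(spec, 0.5)`.
#'
#' @param spec an [model_spec()] object.
#' @param p fraction of the maximal effect, strictly between 0 and 1.
#' @return time in months.
#' @examples
#' time_to_fraction(shpt_ca_model(), 0.5) # 0.15 months
#' @export
time_to_fraction <- function(spec, p) {
  stopifnot(inherits(spec, "mbma_model"))
  if (any(p <= 0 | p >= 1)) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  if (spec$form == "emax_et50") {
    spec$et50 * p / (1 - p)
  } else {
    -log(1 - p) / spec$k
  }
}

#' Smallest baseline that fails to reach a target level by a horizon
#'
#' For models whose covariate is the baseline itself (the PTH model), solves
#' `B - f(horizon) * (emax + slope * (B - reference)) = target` for the
#' baseline `B`, where `f` is the onset fraction at the horizon. Baselines at
#' or above the returned value do not attain `target` by `horizon`; e.g. with
#' the 600 pg/mL guideline upper target and a 12-week horizon the PTH model
#' gives about 1046 pg/mL.
#'
#' @param spec an [model_spec()] object with a `"baseline"` covariate on emax.
#' @param target target biomarker level (outcome units), > 0.
#' @param horizon_months treatment horizon in months; `Inf` uses the full
#'   maximal effect (`f = 1`).
#' @param covariates values for any further covariates in the model.
#' @return the threshold baseline (outcome units).
#' @export
baseline_threshold_for_target <- function(spec, target, horizon_months,
                                          covariates = NULL) {
  stopifnot(inherits(spec, "mbma_model"), target > 0, horizon_months > 0)
  idx <- which(vapply(spec$covariates, function(ce) ce$covariate == "baseline",
                      logical(1)))
  if (length(idx) != 1L) {
    stop("spec must carry exactly one 'baseline' covariate effect on emax",
         call. = FALSE)
  }
  ce <- spec$covariates[[idx]]
  f <- if (is.infinite(horizon_months)) 1 else .time_fraction(spec, horizon_months)
  denom <- 1 - ce$slope * f
  if (denom <= 0) {
    stop("unreachable: covariate slope times the onset fraction is >= 1, ",
         "no finite baseline solves the target equation", call. = FALSE)
  }
  other <- 0
  for (oce in spec$covariates[-idx]) {
    v <- covariates[[oce$covariate]]
    if (is.null(v)) {
      stop("covariate '", oce$covariate, "' required", call. = FALSE)
    }
    other <- other + oce$slope * (v - oce$reference)
  }
  (target + f * (spec$emax - ce$slope * ce$reference + other)) / denom
}

#' Simulate a typical biomarker trajectory
#'
#' Computes the model-typical absolute biomarker level
#' `baseline - effect_at(t)` over a visit schedule, optionally with a 95%
#' parameter-uncertainty band obtained from independent normal parameter
#' draws (standard deviations from the model's relative standard errors, or a
#' supplied parameter sample such as a bootstrap matrix).
#'
#' @inheritParams individual_emax
#' @param baseline baseline biomarker level (outcome units).
#' @param times_weeks visit schedule in weeks (converted to months
#'   internally).
#' @param uncertainty `NULL` for the typical curve only, or a list with
#'   `param_draws` (>= 100), `seed`, and optionally `draws`, a matrix of
#'   parameter samples with columns named `emax`, `et50`/`k` and
#'   `slope_<covariate>` which is used instead of RSE-based draws.
#' @return a `sim_profile`: data frame with `time_weeks`, `t_months`,
#'   `typical`, and `lower95`/`upper95` when uncertainty was requested;
#'   attributes carry the baseline and covariate configuration.
#' @examples
#' simulate_profile(shpt_pth_model(), baseline = 600,
#'                  times_weeks = c(3, 6, 12, 24))
#' @export
simulate_profile <- function(spec, baseline, covariates = NULL,
                             times_weeks = c(3, 6, 12, 24),
                             uncertainty = NULL) {
  stopifnot(inherits(spec, "mbma_model"), length(times_weeks) >= 1L,
            all(times_weeks >= 0))
  t_months <- weeks_to_months(times_weeks)
  typical <- baseline - effect_at(spec, t_months, covariates, baseline)
  out <- data.frame(time_weeks = times_weeks, t_months = t_months,
                    typical = typical)
  if (!is.null(uncertainty)) {
    draws <- uncertainty$draws
    if (is.null(draws)) {
      nd <- uncertainty$param_draws
      if (is.null(nd) || nd < 100) {
        stop("uncertainty bands need param_draws >= 100", call. = FALSE)
      }
      if (is.null(spec$rse_pct)) {
        stop("spec carries no rse_pct; supply `draws` instead", call. = FALSE)
      }
      if (!is.null(uncertainty$seed)) set.seed(uncertainty$seed)
      draws <- .rse_param_draws(spec, nd)
    }
    lev <- apply(draws, 1L, function(par) {
      sp <- .apply_param_row(spec, par)
      baseline - effect_at(sp, t_months, covariates, baseline)
    })
    lev <- matrix(lev, nrow = length(t_months))
    out$lower95 <- apply(lev, 1L, stats::quantile, probs = 0.025, names = FALSE)
    out$upper95 <- apply(lev, 1L, stats::quantile, probs = 0.975, names = FALSE)
  }
  structure(out, baseline = baseline, covariate_config = covariates,
            outcome = spec$outcome,
            class = c("sim_profile", "data.frame"))
}

# Independent normal draws of the fixed effects using printed RSEs
# (zero correlation; the reported uncertainty carries no correlation
# structure). Positive parameters are truncated just above zero.
.rse_param_draws <- function(spec, n) {
  onset <- .onset_par(spec)
  nms <- c("emax", onset,
           vapply(spec$covariates, function(ce) paste0("slope_", ce$covariate),
                  character(1)))
  est <- c(spec$emax, .onset_val(spec),
           vapply(spec$covariates, `[[`, numeric(1), "slope"))
  names(est) <- nms
  rse <- spec$rse_pct[nms]
  if (anyNA(rse)) {
    stop("rse_pct missing for: ", paste(nms[is.na(rse)], collapse = ", "),
         call. = FALSE)
  }
  sds <- abs(est) * rse / 100
  draws <- vapply(seq_along(est),
                  function(j) stats::rnorm(n, est[j], sds[j]), numeric(n))
  colnames(draws) <- nms
  draws[, "emax"] <- pmax(draws[, "emax"], 1e-9)
  draws[, onset] <- pmax(draws[, onset], 1e-9)
  draws
}

# Rebuild a spec from one row of a parameter-draw matrix.
.apply_param_row <- function(spec, par) {
  spec$emax <- unname(par[["emax"]])
  onset <- .onset_par(spec)
  if (spec$form == "emax_et50") {
    spec$et50 <- unname(par[[onset]])
  } else {
    spec$k <- unname(par[[onset]])
  }
  spec$covariates <- lapply(spec$covariates, function(ce) {
    key <- paste0("slope_", ce$covariate)
    if (key %in% names(par)) ce$slope <- unname(par[[key]])
    ce
  })
  spec
}

#' @export
print.sim_profile <- function(x, ...) {
  cat("Typical ", attr(x, "outcome"), " trajectory (baseline ",
      format(attr(x, "baseline")), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
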