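# Serialization of model specifications, fit results and diagnostic tables.

#' Write / read a model specification as a YAML config
#'
#' Keys mirror the [model_spec()] field names, so configs are portable
#' across tools and hand-editable.
#'
#' @param spec an `mbma_model`.
#' @param path file path (`.yml`/`.yaml`).
#' @return `path` (write) or an `mbma_model` (read).
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mbma_model"))
  x <- unclass(spec)
  x$covariates <- lapply(x$covariates, unclass)
  x$rse_pct <- if (!is.null(x$rse_pct)) as.list(x$rse_pct)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(
    outcome = x$outcome, form = x$form, emax = x$emax,
    et50 = x$et50, k = x$k,
    covariates = lapply(x$covariates, function(ce) {
      covariate_effect(ce$covariate, ce$slope, ce$reference, ce$parameter)
    }),
    iiv = x$iiv %||% list(),
    residual_sd = x$residual_sd,
    residual_weighting = x$residual_weighting,
    rse_pct = if (!is.null(x$rse_pct)) unlist(x$rse_pct)
  )
}

#' Serialize a fit result as JSON
#'
#' Writes estimates, standard errors, relative standard errors, the
#' objective value, convergence state, problem sizes and empirical Bayes
#' study effects.
#'
#' @param fit an [mbma()] fit.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mbma"))
  out <- list(
    outcome = fit$spec$outcome, form = fit$spec$form,
    estimates = as.list(fit$coefficients), se = as.list(fit$se),
    rse_pct = as.list(fit$rse_pct), ofv = fit$ofv,
    convergence = fit$convergence, n_studies = fit$n_studies,
    n_arms = fit$n_arms, n_obs = fit$n_obs,
    excluded_arms = fit$excluded_arms,
    eta = if (!is.null(fit$eta)) as.data.frame(fit$eta)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a plot-ready VPC table
#'
#' One CSV with the percentile curves and the observed overlay: columns
#' `time_weeks`, `p2.5`, `p50`, `p97.5` (band rows) followed by the
#' observed points (`observed`, `n`).
#'
#' @param v an [vpc()] result.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_vpc_csv <- function(v, path) {
  stopifnot(inherits(v, "mbma_vpc"))
  band <- v$percentiles
  names(band) <- c("time_weeks", "p2.5", "p50", "p97.5")
  obs <- v$observed
  tab <- merge(obs[, c("time_weeks", "observed", "n")], band,
               by = "time_weeks", all.x = TRUE)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
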