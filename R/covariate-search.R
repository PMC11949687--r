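# Stepwise covariate selection by likelihood-ratio criteria.

# study-level value of a covariate/factor: constant within study by schema;
# "baseline" is the mean arm baseline.
.study_covariate <- function(data, covariate) {
  df <- as.data.frame(data)
  df <- df[df$treatment == "cinacalcet", , drop = FALSE]
  ids <- unique(df$study_id)
  vapply(ids, function(sid) {
    sub <- df[df$study_id == sid, , drop = FALSE]
    v <- if (covariate == "baseline") sub$baseline_mean else sub[[covariate]]
    if (is.null(v)) {
      stop("unknown covariate: ", covariate, call. = FALSE)
    }
    if (all(is.na(v))) NA_real_ else mean(v[!is.na(v)])
  }, numeric(1))
}

# drop arms that miss `covariate`; returns the reduced dataset and how many
# arms went
.complete_on <- function(data, covariate) {
  df <- as.data.frame(data)
  v <- if (covariate == "baseline") df$baseline_mean else df[[covariate]]
  keep <- !is.na(v)
  list(data = trial_data(df[keep, , drop = FALSE],
                         outcome = attr(data, "outcome")),
       dropped = length(unique(paste(df$study_id, df$arm_id)[!keep])))
}

#' Stepwise covariate selection on the maximal-effect parameter
#'
#' Forward inclusion followed by backward elimination, using objective
#' function (-2 log marginal likelihood) drops against chi-squared
#' thresholds: a candidate enters when it improves the OFV by at least
#' `forward_dofv` (default 3.84, p = 0.05 at 1 df) and survives elimination
#' when removing it worsens the OFV by at least `backward_dofv` (default
#' 6.63, p = 0.01). Candidate covariates are centered at their across-study
#' median. Arms missing a tested covariate are excluded for that step (the
#' comparison model is refitted on the same subset, so the OFV drop is
#' well-defined) and the exclusions are logged.
#'
#' @param data a [trial_data()] dataset.
#' @param base an [model_spec()] base model (covariate-free or partial).
#' @param candidates character vector of covariate names to test on `emax`
#'   (schema columns or `"baseline"`).
#' @param forward_dofv,backward_dofv inclusion/retention OFV thresholds.
#' @param control fit control used for every fit.
#' @return a `covariate_search` object: `spec` (final model with estimates),
#'   `fit` (final fit), `steps` (log of every tested step with OFV drops),
#'   `skipped` (non-identifiable candidates).
#' @export
covariate_search <- function(data, base, candidates,
                             forward_dofv = 3.84, backward_dofv = 6.63,
                             control = mbma_control(n_starts = 2L,
                                                    se = FALSE)) {
  stopifnot(inherits(data, "trial_data"), inherits(base, "mbma_model"))
  n_studies <- length(unique(as.data.frame(data)$study_id))
  skipped <- character(0)
  usable <- character(0)
  refs <- numeric(0)
  for (cov in candidates) {
    v <- .study_covariate(data, cov)
    if (mean(!is.na(v)) < 0.8) {
      stop("candidate '", cov, "' present in fewer than 80% of studies",
           call. = FALSE)
    }
    if (stats::var(v[!is.na(v)]) == 0) {
      warning("candidate '", cov, "' has zero variance across studies; ",
              "skipped (non-identifiable)", call. = FALSE)
      skipped <- c(skipped, cov)
      next
    }
    usable <- c(usable, cov)
    refs[cov] <- stats::median(v[!is.na(v)])
  }

  base_fit <- suppressMessages(mbma(data, base, control = control))
  if (!length(usable)) {
    return(structure(list(spec = base_fit$spec, fit = base_fit,
                          steps = NULL, skipped = skipped),
                     class = "covariate_search"))
  }

  add_effect <- function(spec, cov) {
    spec$covariates <- c(spec$covariates,
                         list(covariate_effect(cov, slope = 0,
                                               reference = refs[[cov]])))
    spec
  }
  drop_effect <- function(spec, cov) {
    keep <- vapply(spec$covariates,
                   function(ce) ce$covariate != cov, logical(1))
    spec$covariates <- spec$covariates[keep]
    spec
  }
  memo <- new.env(parent = emptyenv())
  fit_on <- function(spec, cov_needed) {
    sub <- if (is.null(cov_needed)) list(data = data, dropped = 0L)
           else .complete_on(data, cov_needed)
    covs <- sort(vapply(spec$covariates, `[[`, character(1), "covariate"))
    key <- paste(c(covs, "|", if (sub$dropped) cov_needed), collapse = ",")
    if (!is.null(memo[[key]])) {
      return(list(fit = memo[[key]], dropped = sub$dropped))
    }
    fit <- suppressMessages(mbma(sub$data, spec, control = control))
    memo[[key]] <- fit
    list(fit = fit, dropped = sub$dropped)
  }
  memo[[paste(c(sort(vapply(base$covariates, `[[`, character(1),
                            "covariate")), "|"), collapse = ",")]] <- base_fit

  steps <- list()
  log_step <- function(phase, cov, dofv, action, dropped) {
    steps[[length(steps) + 1L]] <<- data.frame(
      phase = phase, covariate = cov, dofv = dofv, action = action,
      arms_excluded = dropped)
  }

  current <- base_fit$spec
  current_fit <- base_fit
  remaining <- usable
  repeat {
    best <- NULL
    for (cov in remaining) {
      cand <- fit_on(add_effect(current, cov), cov)
      ref <- if (cand$dropped > 0L) fit_on(current, cov)$fit else current_fit
      dofv <- ref$ofv - cand$fit$ofv
      log_step("forward", cov, dofv, "tested", cand$dropped)
      if (dofv >= forward_dofv && (is.null(best) || dofv > best$dofv)) {
        best <- list(cov = cov, fit = cand$fit, dofv = dofv)
      }
    }
    if (is.null(best)) break
    current <- best$fit$spec
    current_fit <- best$fit
    remaining <- setdiff(remaining, best$cov)
    log_step("forward", best$cov, best$dofv, "included", 0L)
  }

  repeat {
    sel <- vapply(current$covariates, `[[`, character(1), "covariate")
    sel <- intersect(sel, usable)  # only effects this search added
    if (!length(sel)) break
    removed <- FALSE
    for (cov in sel) {
      red <- fit_on(drop_effect(current, cov), cov)
      full <- if (red$dropped > 0L) fit_on(current, cov)$fit else current_fit
      dofv <- red$fit$ofv - full$ofv
      if (dofv < backward_dofv) {
        log_step("backward", cov, dofv, "removed", red$dropped)
        current <- red$fit$spec
        current_fit <- red$fit
        removed <- TRUE
        break
      } else {
        log_step("backward", cov, dofv, "retained", red$dropped)
      }
    }
    if (!removed) break
  }

  # if arms were excluded along the way, refit the final spec on all arms it
  # can use
  final_fit <- current_fit
  structure(
    list(spec = final_fit$spec, fit = final_fit,
         steps = do.call(rbind, steps), skipped = skipped),
    class = "covariate_search"
  )
}

#' @export
print.covariate_search <- function(x, ...) {
  sel <- vapply(x$spec$covariates, `[[`, character(1), "covariate")
  cat("Stepwise covariate selection\n  selected effects on emax: ",
      if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n",
      sep = "")
  if (length(x$skipped)) {
    cat("  skipped (zero variance): ", paste(x$skipped, collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}
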