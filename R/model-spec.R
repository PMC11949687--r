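# Model specification objects.
#
# A `mbma_model` bundles the structural time-course form, its fixed effects,
# linear centered covariate effects on Emax, the inter-study random-effect
# parameterization and the residual model. The same object serves as a truth
# for simulation, as initial values for estimation, and as the carrier of
# estimates afterwards.

#' Define a covariate effect on a model parameter
#'
#' Covariate effects are linear and centered: the individualized maximal
#' decrease is `emax + slope * (value - reference)`. The special covariate
#' name `"baseline"` resolves to an arm's own baseline biomarker level.
#'
#' @param covariate covariate name (a column of the trial schema, or
#'   `"baseline"`).
#' @param slope effect per covariate unit, in outcome units.
#' @param reference centering value, in covariate units.
#' @param parameter target parameter; only `"emax"` is supported, matching the
#'   covariate structure identified for cinacalcet.
#' @return a `covariate_effect` object.
#' @export
covariate_effect <- function(covariate, slope, reference, parameter = "emax") {
  stopifnot(is.character(covariate), length(covariate) == 1L,
            is.finite(slope), is.finite(reference))
  parameter <- match.arg(parameter, "emax")
  structure(
    list(parameter = parameter, covariate = covariate,
         slope = slope, reference = reference),
    class = "covariate_effect"
  )
}

#' Specify a pharmacodynamic time-course model
#'
#' Two structural forms describe the typical decrease of a biomarker from
#' baseline under treatment:
#' \describe{
#'   \item{`"emax_et50"`}{hyperbolic onset, `decrease(t) = Emax * t / (ET50 + t)`
#'     — used for PTH;}
#'   \item{`"exp_onset"`}{first-order asymptotic onset,
#'     `decrease(t) = Emax * (1 - exp(-K t))` — used for serum calcium and
#'     phosphorus.}
#' }
#' Time `t` is in months (4 weeks). `emax` is a positive maximal decrease in
#' outcome units; the sign convention (biomarker falls) is applied at the
#' trajectory level.
#'
#' @param outcome `"PTH"`, `"CA"` or `"P"`.
#' @param form structural form, see Details.
#' @param emax maximal decrease (outcome units) at the covariate reference.
#' @param et50 months to half-maximal effect (`emax_et50` form only).
#' @param k onset rate, 1/months (`exp_onset` form only).
#' @param covariates list of [covariate_effect()] terms.
#' @param iiv inter-study variability: named list mapping a parameter
#'   (`"emax"`, `"et50"`, `"k"`) to `list(sd =, scale =)` where `scale` is
#'   `"proportional"` (log-normal, sd as a fraction, e.g. 0.193 for 19.3%) or
#'   `"additive"`.
#' @param residual_sd residual standard deviation on the weighted arm-mean
#'   scale (see `residual_weighting`).
#' @param residual_weighting `"inverse_sqrt_n"` (arm-mean variance
#'   `residual_sd^2 / n`, the meta-analytic standard) or `"none"`.
#' @param rse_pct optional named vector of relative standard errors (percent)
#'   used for parameter-uncertainty bands when no fit is available; names
#'   among `emax`, `et50`, `k`, and `slope_<covariate>`.
#' @return an `mbma_model` object.
#' @seealso [shpt_pth_model()], [shpt_ca_model()], [shpt_p_model()] for the
#'   reported cinacalcet models.
#' @export
model_spec <- function(outcome, form = c("emax_et50", "exp_onset"),
                       emax, et50 = NULL, k = NULL,
                       covariates = list(), iiv = list(),
                       residual_sd, residual_weighting = c("inverse_sqrt_n", "none"),
                       rse_pct = NULL) {
  outcome <- match.arg(outcome, .outcomes)
  form <- match.arg(form)
  residual_weighting <- match.arg(residual_weighting)
  stopifnot(is.numeric(emax), emax > 0, is.numeric(residual_sd),
            residual_sd > 0)
  if (form == "emax_et50") {
    if (is.null(et50) || !is.null(k)) {
      stop("form 'emax_et50' requires `et50` and no `k`", call. = FALSE)
    }
    stopifnot(et50 > 0)
  } else {
    if (is.null(k) || !is.null(et50)) {
      stop("form 'exp_onset' requires `k` and no `et50`", call. = FALSE)
    }
    stopifnot(k > 0)
  }
  if (length(covariates) && !all(vapply(covariates, inherits, logical(1),
                                        "covariate_effect"))) {
    stop("`covariates` must be a list of covariate_effect objects",
         call. = FALSE)
  }
  onset_par <- if (form == "emax_et50") "et50" else "k"
  for (nm in names(iiv)) {
    if (!nm %in% c("emax", onset_par)) {
      stop("iiv on unknown parameter: ", nm, call. = FALSE)
    }
    term <- iiv[[nm]]
    stopifnot(is.numeric(term$sd), term$sd >= 0)
    term$scale <- match.arg(term$scale, c("proportional", "additive"))
    iiv[[nm]] <- term
  }
  structure(
    list(outcome = outcome, form = form, emax = emax, et50 = et50, k = k,
         covariates = covariates, iiv = iiv, residual_sd = residual_sd,
         residual_weighting = residual_weighting, rse_pct = rse_pct),
    class = "mbma_model"
  )
}

#' @export
print.mbma_model <- function(x, ...) {
  cat("Time-course model for ", x$outcome, " (", x$form, ")\n", sep = "")
  cat("  emax = ", format(x$emax), " (maximal decrease, outcome units)\n",
      sep = "")
  if (x$form == "emax_et50") {
    cat("  et50 = ", format(x$et50), " months\n", sep = "")
  } else {
    cat("  k    = ", format(x$k), " / month\n", sep = "")
  }
  for (ce in x$covariates) {
    cat("  covariate on ", ce$parameter, ": ", ce$covariate, " slope ",
        format(ce$slope), " (reference ", format(ce$reference), ")\n",
        sep = "")
  }
  for (nm in names(x$iiv)) {
    cat("  inter-study sd(", nm, ") = ", format(x$iiv[[nm]]$sd), " [",
        x$iiv[[nm]]$scale, "]\n", sep = "")
  }
  cat("  residual sd = ", format(x$residual_sd), " [", x$residual_weighting,
      "]\n", sep = "")
  invisible(x)
}

#' Reported final models for cinacalcet in secondary hyperparathyroidism
#'
#' Ready-made `mbma_model` objects carrying the published final-model
#' estimates for the three biomarkers: a hyperbolic PTH model (Emax 308 pg/mL
#' at the reference baseline of 636 pg/mL, baseline-on-Emax slope 0.503, ET50
#' 0.46 months), an asymptotic serum-calcium model (Emax 0.811 mg/dL at the
#' reference vitamin-D use of 66%, slope -0.00588 per percentage point, onset
#' rate 4.64/month) and an asymptotic serum-phosphorus model (Emax 0.524
#' mg/dL, onset rate 2.4/month, no covariates). Inter-study variabilities,
#' residual errors and relative standard errors are included, so the objects
#' can drive simulation with parameter-uncertainty bands, serve as simulation
#' truths, or initialize estimation.
#'
#' @return an `mbma_model`.
#' @examples
#' spec <- shpt_pth_model()
#' effect_at(spec, t_months = 3, baseline = 600) # typical 12-week decrease
#' @export
shpt_pth_model <- function() {
  model_spec(
    outcome = "PTH", form = "emax_et50", emax = 308, et50 = 0.46,
    covariates = list(covariate_effect("baseline", slope = 0.503,
                                       reference = 636)),
    iiv = list(emax = list(sd = 0.193, scale = "proportional"),
               et50 = list(sd = 0.677, scale = "proportional")),
    residual_sd = 1.463,
    rse_pct = c(emax = 5.9, et50 = 18.0, slope_baseline = 8.4)
  )
}

#' @rdname shpt_pth_model
#' @export
shpt_ca_model <- function() {
  model_spec(
    outcome = "CA", form = "exp_onset", emax = 0.811, k = 4.64,
    covariates = list(covariate_effect("vd_pct", slope = -0.00588,
                                       reference = 66)),
    iiv = list(emax = list(sd = 0.121, scale = "proportional")),
    residual_sd = 1.881,
    rse_pct = c(emax = 4.0, k = 13.9, slope_vd_pct = 20.7)
  )
}

#' @rdname shpt_pth_model
#' @export
shpt_p_model <- function() {
  model_spec(
    outcome = "P", form = "exp_onset", emax = 0.524, k = 2.4,
    iiv = list(emax = list(sd = 0.454, scale = "proportional"),
               k = list(sd = 0.763, scale = "additive")),
    residual_sd = 1.597,
    rse_pct = c(emax = 14.1, k = 22.4)
  )
}

# Onset parameter name for a spec ("et50" or "k") and its value.
.onset_par <- function(spec) if (spec$form == "emax_et50") "et50" else "k"
.onset_val <- function(spec) if (spec$form == "emax_et50") spec$et50 else spec$k
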