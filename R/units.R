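#' Convert trial follow-up times from weeks to model months
#'
#' All time-course parameters in this package (ET50, onset rate K) are on a
#' months scale, while trials report visit schedules in weeks. One model month
#' is defined as exactly 4 weeks, so the conversion is `t_weeks / 4`. This
#' convention, rather than the calendar-month average of 4.345 weeks, is what
#' makes a hyperbolic model with ET50 = 0.46 months reach 61.9/76.4/86.7/92.9%
#' of its maximal effect at 3/6/12/24 weeks.
#'
#' @param t_weeks numeric vector of non-negative times in weeks.
#' @return numeric vector of times in months (weeks / 4).
#' @examples
#' weeks_to_months(c(3, 6, 12, 24))
#' @export
weeks_to_months <- function(t_weeks) {
  if (!is.numeric(t_weeks) || anyNA(t_weeks)) {
    stop("`t_weeks` must be numeric without missing values", call. = FALSE)
  }
  if (any(t_weeks < 0)) {
    stop("times in weeks must be non-negative", call. = FALSE)
  }
  t_weeks / 4
}

# molar masses (g/mol) behind the standard clinical-chemistry factors:
# Ca 40.08 -> 1 mmol/L = 4.008 mg/dL; P 30.97 -> 1 mmol/L = 3.097 mg/dL
.unit_factor <- c(CA = 4.008, P = 3.097)

#' Convert serum calcium or phosphorus between mmol/L and mg/dL
#'
#' Source trials report serum calcium and phosphorus in either SI (mmol/L) or
#' conventional (mg/dL) units; the package's canonical internal unit is mg/dL.
#' Conversion uses the molar masses of calcium (40.08 g/mol) and phosphorus
#' (30.97 g/mol): 1 mmol/L equals 4.008 mg/dL for calcium and 3.097 mg/dL for
#' phosphorus.
#'
#' @param value numeric vector of concentrations.
#' @param analyte `"CA"` or `"P"`.
#' @param from,to `"mmol_L"` or `"mg_dL"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_units(2.40, "CA", "mmol_L", "mg_dL") # 9.619 mg/dL
#' @export
convert_units <- function(value, analyte = c("CA", "P"),
                          from = c("mmol_L", "mg_dL"),
                          to = c("mg_dL", "mmol_L")) {
  analyte <- match.arg(analyte)
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) {
    return(value)
  }
  k <- .unit_factor[[analyte]]
  if (from == "mmol_L") value * k else value / k
}
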