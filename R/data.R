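# Arm-level dataset schema.
#
# One row per (study arm, visit). `observed_mean` is stored as an absolute
# biomarker level internally; rows flagged `is_change_from_baseline` are
# converted at ingest (absolute = baseline + signed change) and converted back
# on write, so file round-trips are exact.

.schema_cols <- c(
  "study_id", "arm_id", "treatment", "n", "dose_low_mg", "dose_high_mg",
  "outcome", "time_weeks", "observed_mean", "baseline_mean",
  "is_change_from_baseline", "vd_pct", "pb_pct", "dialysis_months",
  "white_pct", "female_pct", "age_years", "blinded", "region"
)

.covariate_cols <- c(
  "vd_pct", "pb_pct", "dialysis_months", "white_pct", "female_pct",
  "age_years", "blinded", "region"
)

.outcomes <- c("PTH", "CA", "P")

#' Construct an arm-level trial dataset
#'
#' Validates a data frame of arm-level longitudinal summaries (one row per arm
#' and visit) and returns it as a `trial_data` object, the input container for
#' all fitting and diagnostic functions. `observed_mean` must hold absolute
#' biomarker levels (PTH in pg/mL, calcium/phosphorus in mg/dL); use
#' [read_trial_data()] to ingest files that report change from baseline.
#'
#' @param df data frame with the columns listed in [read_trial_data()].
#' @param outcome expected outcome code (`"PTH"`, `"CA"`, `"P"`); checked
#'   against the `outcome` column.
#' @param provenance optional free-text note carried along as an attribute.
#' @return a `trial_data` object (a validated data frame).
#' @export
trial_data <- function(df, outcome = NULL, provenance = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.schema_cols, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[.schema_cols]
  out <- unique(df$outcome)
  if (length(out) != 1L) {
    stop("mixed outcomes in one dataset: ", paste(out, collapse = ", "),
         call. = FALSE)
  }
  if (!out %in% .outcomes) {
    stop("unknown outcome: ", out, call. = FALSE)
  }
  if (!is.null(outcome) && out != outcome) {
    stop("dataset outcome is ", out, ", expected ", outcome, call. = FALSE)
  }
  .validate_trial_rows(df)
  df <- df[order(df$study_id, df$arm_id, df$time_weeks), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    outcome = out,
    provenance = provenance,
    class = c("trial_data", "data.frame")
  )
}

.validate_trial_rows <- function(df) {
  if (!all(df$treatment %in% c("cinacalcet", "control"))) {
    stop("treatment must be 'cinacalcet' or 'control'", call. = FALSE)
  }
  if (anyNA(df$n) || any(df$n < 1) || any(df$n != round(df$n))) {
    stop("n must be a positive integer for every row", call. = FALSE)
  }
  if (anyNA(df$time_weeks) || any(df$time_weeks < 0)) {
    stop("time_weeks must be non-negative", call. = FALSE)
  }
  if (anyNA(df$observed_mean) || anyNA(df$baseline_mean)) {
    stop("observed_mean and baseline_mean are mandatory", call. = FALSE)
  }
  if (df$outcome[1L] == "PTH" && any(df$baseline_mean <= 0)) {
    stop("PTH baseline_mean must be positive", call. = FALSE)
  }
  key <- paste(df$study_id, df$arm_id, sep = "\r")
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    t <- sort(rows$time_weeks)
    if (any(diff(t) <= 0)) {
      stop("times not strictly increasing for arm (", rows$study_id[1L], ", ",
           rows$arm_id[1L], "): duplicated visit times; duplicated ",
           "(study_id, arm_id) blocks also trigger this check", call. = FALSE)
    }
    for (col in c("treatment", "n", "baseline_mean", .covariate_cols)) {
      v <- rows[[col]]
      if (length(unique(v[!is.na(v)])) > 1L) {
        stop("column ", col, " varies within arm (", rows$study_id[1L], ", ",
             rows$arm_id[1L], ")", call. = FALSE)
      }
    }
  }
  pct_cols <- c("vd_pct", "pb_pct", "white_pct", "female_pct")
  for (col in pct_cols) {
    v <- df[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      stop(col, " must lie in [0, 100]", call. = FALSE)
    }
  }
  if (any(df$dialysis_months < 0, na.rm = TRUE)) {
    stop("dialysis_months must be non-negative", call. = FALSE)
  }
  if (any(df$age_years <= 0, na.rm = TRUE)) {
    stop("age_years must be positive", call. = FALSE)
  }
  if (!all(df$blinded %in% c(0, 1, NA))) {
    stop("blinded must be 0, 1 or missing", call. = FALSE)
  }
  if (!all(df$region %in% c("asia", "western") | is.na(df$region))) {
    stop("region must be 'asia', 'western' or missing", call. = FALSE)
  }
  invisible(df)
}

#' Read an arm-level trial dataset from CSV
#'
#' Reads the package's standard CSV layout: UTF-8, `.` decimal separator,
#' empty cells for missing values, one row per (arm, visit), columns exactly
#' `study_id, arm_id, treatment, n, dose_low_mg, dose_high_mg, outcome,
#' time_weeks, observed_mean, baseline_mean, is_change_from_baseline, vd_pct,
#' pb_pct, dialysis_months, white_pct, female_pct, age_years, blinded,
#' region`. Rows with `is_change_from_baseline = TRUE` report the signed
#' change from baseline and are converted to absolute levels on ingest.
#'
#' @param path CSV file path.
#' @param outcome expected outcome code; a file with a different or mixed
#'   outcome is rejected.
#' @return a validated [trial_data] object.
#' @seealso [write_trial_data()] for the inverse operation.
#' @export
read_trial_data <- function(path, outcome = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  header <- utils::read.csv(path, nrows = 1L, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.schema_cols, names(header))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  classes <- c(study_id = "character", arm_id = "character",
               treatment = "character", n = "integer",
               dose_low_mg = "numeric", dose_high_mg = "numeric",
               outcome = "character", time_weeks = "numeric",
               observed_mean = "numeric", baseline_mean = "numeric",
               is_change_from_baseline = "logical", vd_pct = "numeric",
               pb_pct = "numeric", dialysis_months = "numeric",
               white_pct = "numeric", female_pct = "numeric",
               age_years = "numeric", blinded = "numeric",
               region = "character")
  cls <- classes[names(header)] # NA (= automatic) for any extra column
  names(cls) <- names(header)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8", colClasses = cls)
  chg <- which(df$is_change_from_baseline)
  if (length(chg)) {
    df$observed_mean[chg] <- df$baseline_mean[chg] + df$observed_mean[chg]
  }
  trial_data(df, outcome = outcome, provenance = path)
}

#' Write an arm-level trial dataset to CSV
#'
#' Inverse of [read_trial_data()]: rows originally reported as change from
#' baseline are written back as signed changes, so `read_trial_data()` of the
#' written file reproduces the dataset field for field.
#'
#' @param data a [trial_data] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  df <- as.data.frame(data)[.schema_cols]
  chg <- which(df$is_change_from_baseline)
  if (length(chg)) {
    df$observed_mean[chg] <- df$observed_mean[chg] - df$baseline_mean[chg]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @export
print.trial_data <- function(x, ...) {
  key <- paste(x$study_id, x$arm_id, sep = "/")
  cat("Arm-level trial dataset (", attr(x, "outcome"), ")\n", sep = "")
  cat("  studies: ", length(unique(x$study_id)),
      "   arms: ", length(unique(key)),
      "   observations: ", nrow(x), "\n", sep = "")
  cat("  subjects (sum of arm n): ",
      sum(x$n[!duplicated(key)]), "\n", sep = "")
  cat("  follow-up: ", min(x$time_weeks), "-", max(x$time_weeks),
      " weeks\n", sep = "")
  invisible(x)
}

# Split a dataset into per-arm records for model evaluation. Only cinacalcet
# arms carry drug-effect information; control arms are dropped with a message
# when present. Returns a list of arms, each with times in months and the
# observed decrease from baseline (positive = biomarker fell).
.mbma_arms <- function(data, quiet = FALSE) {
  stopifnot(inherits(data, "trial_data"))
  df <- as.data.frame(data)
  drop <- df$treatment != "cinacalcet"
  if (any(drop) && !quiet) {
    message("dropping ", sum(drop), " control-arm row(s): only cinacalcet ",
            "arms enter the drug-effect model")
  }
  df <- df[!drop, , drop = FALSE]
  key <- paste(df$study_id, df$arm_id, sep = "\r")
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    rows <- df[idx, , drop = FALSE]
    rows <- rows[order(rows$time_weeks), , drop = FALSE]
    cov <- as.list(rows[1L, .covariate_cols])
    cov$region <- NULL
    cov <- vapply(cov, function(v) if (is.na(v)) NA_real_ else as.numeric(v),
                  numeric(1))
    cov[["baseline"]] <- rows$baseline_mean[1L]
    list(
      study_id = rows$study_id[1L],
      arm_id = rows$arm_id[1L],
      t_months = weeks_to_months(rows$time_weeks),
      time_weeks = rows$time_weeks,
      decrease = rows$baseline_mean[1L] - rows$observed_mean,
      n = rows$n[1L],
      baseline = rows$baseline_mean[1L],
      covariates = cov
    )
  })
}

# Arms grouped by study (the exchangeable random-effect unit).
.mbma_studies <- function(data, quiet = FALSE) {
  arms <- .mbma_arms(data, quiet = quiet)
  split(arms, vapply(arms, `[[`, character(1), "study_id"))
}
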