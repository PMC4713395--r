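#' Age bands of the SAPS II score
#'
#' Maps age to the score's six bands `<40`, `40-59`, `60-69`, `70-74`,
#' `75-79`, `>=80` (left-closed: 40 maps to `40-59`, 80 to `>=80`), or to
#' the binary `<80` / `>=80` split.
#'
#' @param age Age in years (numeric vector, `>= 16`).
#' @return `age_band()`: an ordered factor with the six band labels.
#'   `age_binary()`: an ordered factor with levels `<80`, `>=80`.
#' @examples
#' age_band(c(39, 40, 79, 80))
#' age_binary(c(79, 80))
#' @export
age_band <- function(age) {
  if (any(is.na(age)) || any(age < 16))
    stop("age must be >= 16 and non-missing", call. = FALSE)
  cut(age, breaks = c(-Inf, 40, 60, 70, 75, 80, Inf), right = FALSE,
      labels = .age_band_labels, ordered_result = TRUE)
}

#' @rdname age_band
#' @export
age_binary <- function(age) {
  if (any(is.na(age)) || any(age < 16))
    stop("age must be >= 16 and non-missing", call. = FALSE)
  factor(ifelse(age >= 80, ">=80", "<80"), levels = c("<80", ">=80"),
         ordered = TRUE)
}

#' Apply the cohort inclusion rules
#'
#' A scored stay is included when it is a unique medical-ICU stay with a
#' known SAPS II and an age-adjusted SAPS II strictly greater than 15 (the
#' threshold separating intensive-care from intermediate-care stays).
#' Excluded stays are tallied by reason in a fixed precedence order, so that
#' a stay failing several criteria is counted exactly once:
#' non-medical ICU, then multiple ICU stays within the hospital stay, then
#' unknown SAPS II, then low severity (age-adjusted SAPS II `<= 15`).
#'
#' @param cohort Scored cohort data frame: one row per hospital stay with at
#'   least `icu_type` (`medical`/`other`), `n_icu_stays_in_hospital_stay`,
#'   `saps2_unknown` (logical) and `age_adjusted` (integer, `NA` allowed
#'   when `saps2_unknown`). The output of [score_cohort()] qualifies.
#' @return List of class `"cohort_filter"` with elements `included` (the
#'   retained rows, original order) and `flowchart`, a named list of counts:
#'   `n_input`, `n_excluded_non_medical_icu`, `n_excluded_multiple_icu`,
#'   `n_excluded_unknown_saps2`, `n_excluded_low_severity`, `n_included`.
#'   The counts always sum to `n_input`.
#' @export
apply_inclusion <- function(cohort) {
  needed <- c("icu_type", "n_icu_stays_in_hospital_stay", "saps2_unknown",
              "age_adjusted")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "),
         "; score the cohort first (see score_cohort)", call. = FALSE)

  non_medical <- cohort$icu_type != "medical"
  multiple <- !non_medical & cohort$n_icu_stays_in_hospital_stay > 1
  unknown <- !non_medical & !multiple & cohort$saps2_unknown
  low <- !non_medical & !multiple & !unknown & cohort$age_adjusted <= 15
  included <- !(non_medical | multiple | unknown | low)

  out <- list(
    included = cohort[included, , drop = FALSE],
    flowchart = list(
      n_input = nrow(cohort),
      n_excluded_non_medical_icu = sum(non_medical),
      n_excluded_multiple_icu = sum(multiple),
      n_excluded_unknown_saps2 = sum(unknown),
      n_excluded_low_severity = sum(low),
      n_included = sum(included)))
  class(out) <- "cohort_filter"
  out
}

#' @export
print.cohort_filter <- function(x, ...) {
  fc <- x$flowchart
  cat("Cohort inclusion flowchart\n")
  cat(sprintf("  stays in input:              %d\n", fc$n_input))
  cat(sprintf("  - non-medical ICU:           %d\n",
              fc$n_excluded_non_medical_icu))
  cat(sprintf("  - multiple ICU stays:        %d\n",
              fc$n_excluded_multiple_icu))
  cat(sprintf("  - unknown SAPS II:           %d\n",
              fc$n_excluded_unknown_saps2))
  cat(sprintf("  - age-adjusted SAPS II <=15: %d\n",
              fc$n_excluded_low_severity))
  cat(sprintf("  stays included:              %d\n", fc$n_included))
  invisible(x)
}

#' Score a raw cohort
#'
#' Appends SAPS II scoring columns (`total`, `age_points`, `age_adjusted`,
#' `predicted_mortality`) and the `saps2_unknown` flag to a cohort table.
#' Stays whose physiology is unrecorded (all physiology columns `NA`) are
#' flagged `saps2_unknown` and receive `NA` scores; no imputation is done,
#' matching the downstream exclusion of unknown-SAPS II stays.
#'
#' @param cohort Cohort data frame in the standard schema (see
#'   [generate_cohort()] / [read_cohort()]).
#' @return The cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort) {
  phys <- cohort[, .physiology_fields, drop = FALSE]
  unknown <- is.na(phys$gcs)
  cohort$saps2_unknown <- unknown
  cohort$total <- NA_integer_
  cohort$age_points <- saps2_age_points(cohort$age)
  cohort$age_adjusted <- NA_integer_
  cohort$predicted_mortality <- NA_real_
  if (any(!unknown)) {
    ventilated <- (cohort$invasive_mv | cohort$niv)[!unknown]
    scored <- score_saps2(cohort$age[!unknown], phys[!unknown, , drop = FALSE],
                          ventilated = ventilated)
    cohort$total[!unknown] <- scored$total
    cohort$age_adjusted[!unknown] <- scored$age_adjusted
    cohort$predicted_mortality[!unknown] <- scored$predicted_mortality
  }
  cohort
}

#' Classify a cohort's organ supports
#'
#' Appends the per-organ support levels and the treatment-intensity group
#' (see [classify_supports()]) to a cohort table.
#'
#' @inheritParams score_cohort
#' @return The cohort with `hemodynamic`, `respiratory`, `renal`,
#'   `intensity_points` and `group` columns appended.
#' @export
classify_cohort <- function(cohort) {
  cbind(cohort, classify_supports(cohort))
}
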