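#' SAPS II age points
#'
#' Points contributed by age to the SAPS II total, on the score's six age
#' bands `<40`, `40-59`, `60-69`, `70-74`, `75-79`, `>=80` (left-closed:
#' 40 falls in `40-59`, 80 in `>=80`).
#'
#' @param age Age in years at ICU admission (numeric vector, all `>= 16`).
#' @return Integer vector of age points (0, 7, 12, 15, 16 or 18).
#' @examples
#' saps2_age_points(c(39, 40, 79, 80))
#' @export
saps2_age_points <- function(age) {
  if (any(is.na(age)) || any(age < 16))
    stop("age must be >= 16 and non-missing", call. = FALSE)
  .band_points(age, .saps2_age)
}

.physiology_fields <- c("heart_rate", "systolic_bp", "temperature",
                        "pao2_fio2", "urine_output", "serum_urea", "wbc",
                        "potassium", "sodium", "bicarbonate", "bilirubin",
                        "gcs", "chronic_disease", "admission_type")

.check_physiology <- function(physiology) {
  missing_cols <- setdiff(.physiology_fields, names(physiology))
  if (length(missing_cols))
    stop("physiology is missing fields: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  gcs <- physiology$gcs
  if (any(is.na(gcs)) || any(gcs < 3 | gcs > 15))
    stop("gcs must lie in [3, 15]", call. = FALSE)
  if (!all(physiology$chronic_disease %in% names(.saps2_chronic)))
    stop("chronic_disease must be one of: ",
         paste(names(.saps2_chronic), collapse = ", "), call. = FALSE)
  if (!all(physiology$admission_type %in% names(.saps2_admission)))
    stop("admission_type must be one of: ",
         paste(names(.saps2_admission), collapse = ", "), call. = FALSE)
  quantitative <- c("heart_rate", "systolic_bp", "temperature",
                    "urine_output", "serum_urea", "wbc", "potassium",
                    "sodium", "bicarbonate", "bilirubin")
  for (f in quantitative)
    if (any(is.na(physiology[[f]])))
      stop("physiology field '", f, "' has missing values; ",
           "records with unknown SAPS II must be flagged, not scored",
           call. = FALSE)
  invisible(TRUE)
}

#' Compute SAPS II scores for one or more stays
#'
#' Computes the component-wise SAPS II breakdown, the total score, the
#' age-adjusted score (total minus age points) and the predicted hospital
#' mortality for each row of a physiology table. Inputs are the scoreable
#' values (worst value of the first 24 h of the ICU stay); selecting the
#' worst value is the caller's responsibility.
#'
#' The PaO2/FiO2 ratio is scored only for ventilated patients (invasive
#' ventilation or CPAP): `pao2_fio2` must be non-missing exactly when
#' `ventilated` is `TRUE`.
#'
#' @param age Age in years (vector, `>= 16`), one per row of `physiology`.
#' @param physiology Data frame with columns `heart_rate` (bpm),
#'   `systolic_bp` (mmHg), `temperature` (deg C), `pao2_fio2` (mmHg, `NA`
#'   when not ventilated), `urine_output` (L/24 h), `serum_urea` (mmol/L),
#'   `wbc` (10^9/L), `potassium` (mmol/L), `sodium` (mmol/L), `bicarbonate`
#'   (mmol/L), `bilirubin` (umol/L), `gcs` (integer 3-15), `chronic_disease`
#'   (`none`, `metastatic_cancer`, `hematologic_malignancy`, `aids`),
#'   `admission_type` (`scheduled_surgical`, `medical`,
#'   `unscheduled_surgical`).
#' @param ventilated Logical vector: was the patient ventilated (invasive MV
#'   or CPAP/NIV) during the first 24 h? Defaults to `pao2_fio2` being
#'   present.
#' @return Data frame with one row per stay: the integer points of each
#'   component (columns named after the physiology fields, plus
#'   `age_points`), `total`, `age_adjusted` and `predicted_mortality`.
#' @seealso [saps2_predicted_mortality()], [saps2_age_points()]
#' @examples
#' phi <- data.frame(heart_rate = 80, systolic_bp = 120, temperature = 37,
#'                   pao2_fio2 = NA_real_, urine_output = 1.5,
#'                   serum_urea = 5, wbc = 8, potassium = 4, sodium = 138,
#'                   bicarbonate = 24, bilirubin = 10, gcs = 15L,
#'                   chronic_disease = "none",
#'                   admission_type = "scheduled_surgical")
#' score_saps2(30, phi)  # total 0
#' @export
score_saps2 <- function(age, physiology,
                        ventilated = !is.na(physiology$pao2_fio2)) {
  physiology <- as.data.frame(physiology)
  n <- nrow(physiology)
  if (length(age) != n)
    stop("length(age) must equal nrow(physiology)", call. = FALSE)
  .check_physiology(physiology)
  if (any(!ventilated & !is.na(physiology$pao2_fio2)))
    stop("pao2_fio2 supplied for a non-ventilated patient", call. = FALSE)
  if (any(ventilated & is.na(physiology$pao2_fio2)))
    stop("pao2_fio2 missing for a ventilated patient", call. = FALSE)

  pts <- data.frame(row.names = seq_len(n))
  for (f in setdiff(names(.saps2_bands), "pao2_fio2"))
    pts[[f]] <- .band_points(physiology[[f]], .saps2_bands[[f]])
  pf <- integer(n)
  pf[ventilated] <- .band_points(physiology$pao2_fio2[ventilated],
                                 .saps2_bands$pao2_fio2)
  pts$pao2_fio2 <- pf
  pts$chronic_disease <- unname(.saps2_chronic[physiology$chronic_disease])
  pts$admission_type <- unname(.saps2_admission[physiology$admission_type])
  pts$age_points <- saps2_age_points(age)

  pts <- pts[, c(.physiology_fields, "age_points")]
  pts$total <- as.integer(rowSums(pts))
  pts$age_adjusted <- pts$total - pts$age_points
  pts$predicted_mortality <- saps2_predicted_mortality(pts$total)
  pts
}

#' Predicted hospital mortality from a SAPS II total
#'
#' Applies the score's published logistic conversion
#' `logit = -7.7631 + 0.0737 S + 0.9971 log(S + 1)`,
#' `p = exp(logit) / (1 + exp(logit))`.
#'
#' @param total SAPS II total score (non-negative numeric vector).
#' @return Probability of hospital death, strictly increasing in `total`,
#'   in (0, 1).
#' @examples
#' saps2_predicted_mortality(c(0, 36, 77))
#' @export
saps2_predicted_mortality <- function(total) {
  if (any(is.na(total)) || any(total < 0))
    stop("SAPS II total must be non-negative", call. = FALSE)
  logit <- .saps2_logit[["intercept"]] +
    .saps2_logit[["score"]] * total +
    .saps2_logit[["log_score"]] * log(total + 1)
  stats::plogis(logit)
}

#' Age-adjusted SAPS II
#'
#' The SAPS II total minus its age-related points, used as an
#' age-independent severity index (and as the `> 15` inclusion threshold
#' separating intensive-care from intermediate-care stays).
#'
#' @param total SAPS II total score.
#' @param age Age in years (`>= 16`).
#' @return Integer vector, `total - saps2_age_points(age)`.
#' @export
saps2_age_adjusted <- function(total, age) {
  ap <- saps2_age_points(age)
  if (any(total < ap))
    stop("inconsistent input: total below the age points for this age",
         call. = FALSE)
  as.integer(total - ap)
}
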