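# SAPS II weight tables, transcribed from the original score definition
# (Le Gall, Lemeshow & Saulnier 1993, JAMA 270:2957-2963). These constants
# are frozen: the test suite pins every band and the logit coefficients, so
# any silent edit fails loudly. All cut points are left-closed / right-open
# except the final band.

# Each physiological component: breaks define bands [b_i, b_{i+1}) on the
# scoreable (worst-in-first-24h) value supplied by the caller.
.saps2_bands <- list(
  heart_rate   = list(breaks = c(-Inf, 40, 70, 120, 160, Inf),
                      points = c(11L, 2L, 0L, 4L, 7L)),
  systolic_bp  = list(breaks = c(-Inf, 70, 100, 200, Inf),
                      points = c(13L, 5L, 0L, 2L)),
  temperature  = list(breaks = c(-Inf, 39, Inf),
                      points = c(0L, 3L)),
  # PaO2/FiO2 (mmHg): scored only when the patient is ventilated or on CPAP
  pao2_fio2    = list(breaks = c(-Inf, 100, 200, Inf),
                      points = c(11L, 9L, 6L)),
  urine_output = list(breaks = c(-Inf, 0.5, 1.0, Inf),
                      points = c(11L, 4L, 0L)),
  serum_urea   = list(breaks = c(-Inf, 10, 30, Inf),
                      points = c(0L, 6L, 10L)),
  wbc          = list(breaks = c(-Inf, 1, 20, Inf),
                      points = c(12L, 0L, 3L)),
  potassium    = list(breaks = c(-Inf, 3, 5, Inf),
                      points = c(3L, 0L, 3L)),
  sodium       = list(breaks = c(-Inf, 125, 145, Inf),
                      points = c(5L, 0L, 1L)),
  bicarbonate  = list(breaks = c(-Inf, 15, 20, Inf),
                      points = c(6L, 3L, 0L)),
  # bilirubin in umol/L; original cut points 4 and 6 mg/dL (x 17.1)
  bilirubin    = list(breaks = c(-Inf, 68.4, 102.6, Inf),
                      points = c(0L, 4L, 9L)),
  gcs          = list(breaks = c(-Inf, 6, 9, 11, 14, Inf),
                      points = c(26L, 13L, 7L, 5L, 0L))
)

.saps2_chronic <- c(none = 0L, metastatic_cancer = 9L,
                    hematologic_malignancy = 10L, aids = 17L)

.saps2_admission <- c(scheduled_surgical = 0L, medical = 6L,
                      unscheduled_surgical = 8L)

# Age bands <40, 40-59, 60-69, 70-74, 75-79, >=80 (left-closed)
.saps2_age <- list(breaks = c(-Inf, 40, 60, 70, 75, 80, Inf),
                   points = c(0L, 7L, 12L, 15L, 16L, 18L))

# Hospital-mortality conversion: logit = b0 + b1*S + b2*log(S + 1)
.saps2_logit <- c(intercept = -7.7631, score = 0.0737, log_score = 0.9971)

# Maximum attainable SAPS II total (all components at worst band)
.saps2_max_total <- 163L

.band_points <- function(x, band) {
  band$points[findInterval(x, band$breaks, left.open = FALSE)]
}
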