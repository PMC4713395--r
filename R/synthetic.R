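#' Simulation configuration for the synthetic administrative cohort
#'
#' Builds the ground-truth parameter set of the synthetic cohort generator.
#' The synthetic cohort emulates the structure of a medical-ICU
#' administrative database: one row per hospital stay, stay-level procedure
#' summaries (maximum catecholamine dose, worst ventilator settings, renal
#' replacement flag), an age distribution with mean near 58 years and a
#' substantial `>= 80` tail, severity correlated with age and with support
#' intensity, and hospital death drawn as a per-stratum multiplier times the
#' SAPS II-predicted mortality.
#'
#' The mortality model is multiplicative: within each (age band x intensity
#' group) stratum, `P(death) = min(1, m * p_SAPS2)`. In expectation the
#' stratum's standardized mortality ratio equals the (possibly clamped)
#' multiplier, which gives a closed-form target for recovery tests.
#'
#' @param n_stays Number of hospital stays to generate.
#' @param seed Integer seed; generation is a pure function of the
#'   configuration, so identical configurations give bit-identical cohorts.
#' @param age_mixture Truncated-normal mixture for age: list with `weights`
#'   (summing to 1), `means`, `sds` (years) and `bounds` (truncation range).
#' @param severity_age_loading Correlation loading of the latent severity on
#'   standardised age, in `[0, 1)`. Severity is a standard-normal latent per
#'   stay; physiology fields are monotone deformations of it plus noise and
#'   support allocation is logistic in it.
#' @param mortality_multipliers 6 x 4 numeric matrix of non-negative
#'   multipliers, rows = SAPS II age bands, columns = intensity groups 0-3
#'   (see [multiplier_matrix()]), applied to the SAPS II-predicted death
#'   probability.
#' @param support_model Logistic intercepts/slopes (on the latent severity)
#'   for catecholamine use, invasive ventilation, NIV and renal replacement,
#'   plus the catecholamine agent mix. Defaults generate doses, FiO2 and
#'   PEEP on both sides of the 8 ug/kg/min, 0.6 and 6 cm H2O classification
#'   thresholds so boundary behaviour is always exercised.
#' @param frac_multiple_icu_stays Fraction of stays with more than one ICU
#'   stay in the hospital stay (excluded downstream).
#' @param frac_unknown_saps2 Fraction of stays with unrecorded physiology
#'   (flagged unknown SAPS II, excluded downstream).
#' @param frac_other_icu Fraction of stays in a non-medical ICU. The default
#'   0 reflects a database restricted to medical ICUs.
#' @param frac_female Fraction of female patients.
#' @return Object of class `"sim_config"`.
#' @seealso [generate_cohort()], [multiplier_matrix()]
#' @export
simulation_config <- function(n_stays = 25000L,
                              seed = 20060101L,
                              age_mixture = list(
                                weights = c(0.40, 0.48, 0.12),
                                means = c(44, 64, 85),
                                sds = c(14, 10, 4),
                                bounds = c(16, 100)),
                              severity_age_loading = 0.15,
                              mortality_multipliers = multiplier_matrix(1),
                              support_model = default_support_model(),
                              frac_multiple_icu_stays = 0.176,
                              frac_unknown_saps2 = 0.05,
                              frac_other_icu = 0,
                              frac_female = 0.405) {
  cfg <- list(n_stays = as.integer(n_stays), seed = as.integer(seed),
              age_mixture = age_mixture,
              severity_age_loading = severity_age_loading,
              mortality_multipliers = mortality_multipliers,
              support_model = support_model,
              frac_multiple_icu_stays = frac_multiple_icu_stays,
              frac_unknown_saps2 = frac_unknown_saps2,
              frac_other_icu = frac_other_icu,
              frac_female = frac_female)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Stratum multiplier matrix
#'
#' Convenience constructor for the (age band x intensity group) mortality
#' multiplier matrix. A scalar fills the whole matrix; a length-4 vector is
#' recycled across age bands (one multiplier per intensity group); a full
#' 6 x 4 matrix is validated and returned.
#'
#' @param m Scalar, length-4 vector (per group), or 6 x 4 matrix.
#' @return 6 x 4 matrix with age-band row names and group column names.
#' @export
multiplier_matrix <- function(m = 1) {
  groups <- as.character(0:3)
  if (is.matrix(m)) {
    if (!all(dim(m) == c(6L, 4L)))
      stop("multiplier matrix must be 6 age bands x 4 groups", call. = FALSE)
    out <- m
  } else if (length(m) == 1L) {
    out <- matrix(m, 6, 4)
  } else if (length(m) == 4L) {
    out <- matrix(m, 6, 4, byrow = TRUE)
  } else {
    stop("m must be a scalar, a length-4 vector or a 6x4 matrix",
         call. = FALSE)
  }
  dimnames(out) <- list(.age_band_labels, groups)
  out
}

#' @rdname simulation_config
#' @export
default_support_model <- function() {
  list(
    catecholamine = list(intercept = -1.6, slope = 2.6,
                         agents = c(dobutamine = 0.15, dopamine = 0.20,
                                    epinephrine = 0.10,
                                    norepinephrine = 0.55),
                         # log-normal dose centred on the 8 ug/kg/min
                         # threshold: both sides always exercised
                         dose_meanlog = log(8), dose_sdlog = 0.5),
    invasive_mv = list(intercept = -1.0, slope = 2.4,
                       fio2_shift = -1.1, fio2_noise_sd = 0.8,
                       peep_mean = 4.0, peep_slope = 1.3, peep_sd = 2.0),
    niv = list(intercept = -2.0, slope = 0.3),
    rrt = list(intercept = -2.3, slope = 1.8))
}

#' Validate a simulation configuration
#'
#' Checks every invariant of the configuration (weights summing to 1,
#' probabilities in `[0, 1]`, non-negative multipliers, ...) and fails with
#' an error naming the offending field.
#'
#' @param cfg A `sim_config` object (possibly hand-edited).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  problem <- function(field, msg)
    stop("invalid simulation config: field '", field, "' ", msg,
         call. = FALSE)
  if (is.na(cfg$n_stays) || cfg$n_stays < 0)
    problem("n_stays", "must be a non-negative integer")
  if (is.na(cfg$seed)) problem("seed", "must be an integer")
  am <- cfg$age_mixture
  if (abs(sum(am$weights) - 1) > 1e-8)
    problem("age_mixture", "weights must sum to 1")
  if (length(am$means) != length(am$weights) ||
      length(am$sds) != length(am$weights))
    problem("age_mixture", "weights/means/sds lengths differ")
  if (any(am$sds <= 0)) problem("age_mixture", "sds must be positive")
  if (am$bounds[1] < 16) problem("age_mixture", "lower bound must be >= 16")
  if (cfg$severity_age_loading < 0 || cfg$severity_age_loading >= 1)
    problem("severity_age_loading", "must lie in [0, 1)")
  mm <- cfg$mortality_multipliers
  if (!is.matrix(mm) || !all(dim(mm) == c(6, 4)) || any(mm < 0) ||
      any(is.na(mm)))
    problem("mortality_multipliers", "must be a non-negative 6x4 matrix")
  for (f in c("frac_multiple_icu_stays", "frac_unknown_saps2",
              "frac_other_icu", "frac_female")) {
    v <- cfg[[f]]
    if (is.na(v) || v < 0 || v > 1) problem(f, "must lie in [0, 1]")
  }
  ag <- cfg$support_model$catecholamine$agents
  if (abs(sum(ag) - 1) > 1e-8)
    problem("support_model", "catecholamine agent mix must sum to 1")
  invisible(cfg)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic administrative ICU cohort
#'
#' Draws `n_stays` hospital-stay records from the generative model described
#' in [simulation_config()]. Output is deterministic given the
#' configuration (including its seed). The stratum used for the mortality
#' multiplier lookup is derived with the same [age_band()] and
#' [classify_supports()] rules used by the analysis, so the generator's
#' ground truth and the analysis pipeline always agree on stratum
#' membership.
#'
#' @param config A [simulation_config()] object.
#' @return Data frame with one row per stay in the standard cohort schema:
#'   identifiers and demographics (`stay_id`, `age`, `sex`,
#'   `n_icu_stays_in_hospital_stay`, `icu_type`), the 14 physiology columns
#'   (all `NA` for unknown-SAPS II stays), the support columns, and
#'   `hospital_death`.
#' @examples
#' cohort <- generate_cohort(simulation_config(n_stays = 100))
#' table(intensity_group(cohort))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_stays
  schema_cols <- .cohort_schema
  if (n == 0L) {
    empty <- lapply(schema_cols, function(cl) vector(cl, 0L))
    return(as.data.frame(empty, stringsAsFactors = FALSE))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # demographics
  am <- config$age_mixture
  comp <- sample.int(length(am$weights), n, replace = TRUE, prob = am$weights)
  age <- round(.rtruncnorm(n, am$means[comp], am$sds[comp],
                           am$bounds[1], am$bounds[2]))
  age <- as.integer(.clip(age, 16, am$bounds[2]))
  sex <- ifelse(stats::runif(n) < config$frac_female, "female", "male")

  # latent severity: standard normal with a mild age loading
  lam <- config$severity_age_loading
  z <- lam * (age - 58) / 18 + sqrt(1 - lam^2) * stats::rnorm(n)

  # physiology: monotone deformations of the latent plus field noise
  dev <- function(sd) z + stats::rnorm(n, 0, sd)
  s_hr <- dev(0.9); s_bp <- dev(0.8); s_t <- dev(1.0); s_u <- dev(0.8)
  s_ur <- dev(0.7); s_w <- dev(1.0); s_k <- dev(1.1); s_na <- dev(1.1)
  s_hc <- dev(0.8); s_bi <- dev(1.0); s_g <- dev(0.8); s_pf <- dev(0.8)
  phys <- data.frame(
    heart_rate = as.integer(round(.clip(90 + 26 * s_hr, 30, 220))),
    systolic_bp = as.integer(round(.clip(118 - 27 * s_bp, 40, 260))),
    temperature = round(.clip(37.2 + 1.0 * s_t, 32, 42), 1),
    pao2_fio2 = NA_real_,
    urine_output = round(.clip(exp(0.30 - 1.10 * s_u), 0.01, 8), 2),
    serum_urea = round(.clip(exp(2.0 + 0.70 * s_ur), 0.5, 90), 1),
    wbc = round(.clip(exp(2.3 + 0.50 * s_w), 0.1, 80), 1),
    potassium = round(.clip(4.1 + 0.65 * s_k, 1.5, 9), 1),
    sodium = as.integer(round(.clip(138 - 5.5 * s_na, 108, 175))),
    bicarbonate = as.integer(round(.clip(22.5 - 4.8 * s_hc, 4, 45))),
    bilirubin = round(.clip(exp(2.7 + 1.0 * s_bi), 1, 600), 1),
    gcs = as.integer(.clip(15 - round(pmax(0, 3.9 * (s_g - 0.1))), 3, 15)),
    chronic_disease = sample(names(.saps2_chronic), n, replace = TRUE,
                             prob = c(0.86, 0.06, 0.05, 0.03)),
    admission_type = sample(names(.saps2_admission), n, replace = TRUE,
                            prob = c(0.03, 0.92, 0.05)),
    stringsAsFactors = FALSE)

  # organ supports, logistic in the latent severity
  sm <- config$support_model
  cat_on <- stats::runif(n) < stats::plogis(sm$catecholamine$intercept +
                                              sm$catecholamine$slope * z)
  agent <- rep("none", n)
  agent[cat_on] <- sample(names(sm$catecholamine$agents), sum(cat_on),
                          replace = TRUE, prob = sm$catecholamine$agents)
  dose <- rep(NA_real_, n)
  dd <- agent %in% c("dobutamine", "dopamine")
  dose[dd] <- round(stats::rlnorm(sum(dd), sm$catecholamine$dose_meanlog,
                                  sm$catecholamine$dose_sdlog), 1)
  inv <- stats::runif(n) < stats::plogis(sm$invasive_mv$intercept +
                                           sm$invasive_mv$slope * z)
  fio2 <- rep(NA_real_, n)
  fio2[inv] <- round(.clip(0.21 + 0.79 *
    stats::plogis(z[inv] + sm$invasive_mv$fio2_shift +
                    stats::rnorm(sum(inv), 0,
                                 sm$invasive_mv$fio2_noise_sd)),
    0.21, 1), 2)
  peep <- rep(NA_real_, n)
  peep[inv] <- pmax(0, round(sm$invasive_mv$peep_mean +
                               sm$invasive_mv$peep_slope * z[inv] +
                               stats::rnorm(sum(inv), 0,
                                            sm$invasive_mv$peep_sd)))
  niv <- stats::runif(n) < stats::plogis(sm$niv$intercept + sm$niv$slope * z)
  rrt <- stats::runif(n) < stats::plogis(sm$rrt$intercept + sm$rrt$slope * z)

  ventilated <- inv | niv
  pf <- rep(NA_real_, n)
  pf[ventilated] <- round(.clip(280 - 78 * s_pf[ventilated], 40, 500))
  phys$pao2_fio2 <- pf

  cohort <- data.frame(
    stay_id = sprintf("S%07d", seq_len(n)),
    age = age, sex = sex,
    n_icu_stays_in_hospital_stay = 1L +
      ifelse(stats::runif(n) < config$frac_multiple_icu_stays,
             1L + stats::rpois(n, 0.4), 0L),
    icu_type = ifelse(stats::runif(n) < config$frac_other_icu,
                      "other", "medical"),
    phys,
    catecholamine = agent, catecholamine_max_dose = dose,
    niv = niv, invasive_mv = inv, mv_max_fio2 = fio2, mv_max_peep = peep,
    rrt = rrt,
    stringsAsFactors = FALSE)

  # mortality: stratum multiplier times the SAPS II-predicted probability,
  # evaluated with the same banding/classification rules as the analysis
  scored <- score_saps2(age, phys, ventilated = ventilated)
  group <- intensity_group(cohort)
  band <- age_band(age)
  m <- config$mortality_multipliers[cbind(as.integer(band), group + 1L)]
  p_death <- pmin(1, m * scored$predicted_mortality)
  cohort$hospital_death <- stats::runif(n) < p_death

  # mask physiology for the unknown-SAPS II fraction (after mortality is
  # drawn, so masking does not alter the death process)
  mask <- stats::runif(n) < config$frac_unknown_saps2
  if (any(mask)) {
    for (f in .physiology_fields)
      cohort[[f]][mask] <- NA
  }
  cohort
}

.cohort_schema <- c(
  stay_id = "character", age = "integer", sex = "character",
  n_icu_stays_in_hospital_stay = "integer", icu_type = "character",
  heart_rate = "integer", systolic_bp = "integer", temperature = "numeric",
  pao2_fio2 = "numeric", urine_output = "numeric", serum_urea = "numeric",
  wbc = "numeric", potassium = "numeric", sodium = "integer",
  bicarbonate = "integer", bilirubin = "numeric", gcs = "integer",
  chronic_disease = "character", admission_type = "character",
  catecholamine = "character", catecholamine_max_dose = "numeric",
  niv = "logical", invasive_mv = "logical", mv_max_fio2 = "numeric",
  mv_max_peep = "numeric", rrt = "logical", hospital_death = "logical")

#' Read and write cohort CSV files
#'
#' The cohort CSV dialect is fixed: header row with exactly the standard
#' schema columns, UTF-8, `.` decimal separator, empty cell for missing.
#' `read_cohort(write_cohort(x))` is the identity, field for field.
#' `read_cohort()` validates row-level invariants (GCS in 3-15, age >= 16,
#' dose/ventilator-setting nullability) and reports offending row numbers.
#'
#' @param cohort Cohort data frame in the standard schema.
#' @param path File path.
#' @return `read_cohort()`: the cohort data frame. `write_cohort()`: `path`,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(names(.cohort_schema), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(cohort[, names(.cohort_schema)], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE,
                            fileEncoding = "UTF-8")
  unknown <- setdiff(names(header), names(.cohort_schema))
  if (length(unknown))
    stop("unknown cohort columns: ", paste(unknown, collapse = ", "),
         "; accepted schema: ", paste(names(.cohort_schema), collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(names(.cohort_schema), names(header))
  if (length(missing_cols))
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- utils::read.csv(path, colClasses = unname(.cohort_schema[names(header)]),
                       check.names = FALSE, fileEncoding = "UTF-8",
                       na.strings = "")
  x <- x[, names(.cohort_schema)]
  .validate_cohort_rows(x)
  x
}

.validate_cohort_rows <- function(x) {
  bad_row <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      stop("cohort parse error at row ", idx[1], ": ", msg, call. = FALSE)
  }
  bad_row(is.na(x$age) | x$age < 16, "age must be >= 16")
  bad_row(is.na(x$n_icu_stays_in_hospital_stay) |
            x$n_icu_stays_in_hospital_stay < 1,
          "n_icu_stays_in_hospital_stay must be >= 1")
  bad_row(!x$icu_type %in% c("medical", "other"),
          "icu_type must be 'medical' or 'other'")
  bad_row(!is.na(x$gcs) & (x$gcs < 3 | x$gcs > 15),
          "gcs must lie in [3, 15]")
  known <- !is.na(x$gcs)
  phys_na <- is.na(x[, setdiff(.physiology_fields,
                               c("pao2_fio2", "gcs"))])
  bad_row(known & rowSums(phys_na) > 0,
          "physiology must be fully recorded or fully missing")
  bad_row(!known & rowSums(!phys_na) > 0,
          "physiology must be fully recorded or fully missing")
  dd <- x$catecholamine %in% c("dobutamine", "dopamine")
  bad_row(dd & is.na(x$catecholamine_max_dose),
          "catecholamine_max_dose required for dobutamine/dopamine")
  bad_row(!dd & !is.na(x$catecholamine_max_dose),
          "catecholamine_max_dose must be empty unless dobutamine/dopamine")
  bad_row(x$invasive_mv & (is.na(x$mv_max_fio2) | is.na(x$mv_max_peep)),
          "mv_max_fio2/mv_max_peep required under invasive ventilation")
  bad_row(!x$invasive_mv & (!is.na(x$mv_max_fio2) | !is.na(x$mv_max_peep)),
          "mv_max_fio2/mv_max_peep must be empty without invasive ventilation")
  bad_row(!is.na(x$mv_max_fio2) & (x$mv_max_fio2 < 0.21 | x$mv_max_fio2 > 1),
          "mv_max_fio2 must lie in [0.21, 1]")
  invisible(x)
}
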