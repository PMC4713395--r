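#' Round half away from zero
#'
#' Display rounding used for all reported percentages (base R's `round()`
#' rounds half to even, which does not match how the tables are printed).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Standardized mortality ratio with exact Poisson confidence interval
#'
#' SMR = observed deaths / expected deaths, where expected deaths is the sum
#' of per-patient SAPS II-predicted death probabilities. The 95% interval is
#' the exact Poisson (Garwood) interval on the observed count, divided by
#' the expected count (treated as fixed); lower limit 0 when no deaths are
#' observed.
#'
#' @param observed Observed death count (non-negative).
#' @param expected Expected death count (strictly positive).
#' @param conf_level Confidence level, default 0.95.
#' @return Named list: `smr`, `ci_low`, `ci_high`, `observed`, `expected`.
#' @examples
#' compute_smr(20, 10)
#' @export
compute_smr <- function(observed, expected, conf_level = 0.95) {
  if (is.na(expected) || expected <= 0)
    stop("SMR undefined: expected deaths must be > 0", call. = FALSE)
  if (is.na(observed) || observed < 0)
    stop("observed deaths must be >= 0", call. = FALSE)
  alpha <- 1 - conf_level
  lower <- if (observed == 0) 0 else
    stats::qchisq(alpha / 2, 2 * observed) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * (observed + 1)) / 2
  list(smr = observed / expected, ci_low = lower / expected,
       ci_high = upper / expected,
       observed = observed, expected = expected)
}

.as_test_result <- function(test_name, statistic, df, p_value) {
  out <- list(test_name = test_name, statistic = unname(statistic),
              df = unname(df), p_value = unname(p_value))
  class(out) <- "icu_test"
  out
}

#' @export
print.icu_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.3g\n", x$test_name,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic with `(r-1)(c-1)` degrees of freedom and asymptotic
#' p-value, without continuity correction (all tables in this analysis are
#' large-sample).
#'
#' @param tab Contingency table (matrix of counts).
#' @return An `icu_test` result with `test_name = "chi_square"`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin", call. = FALSE)
  # the p-value is asymptotic by design; silence the small-expected-count
  # advisory so sparse strata in small cohorts do not spam callers
  res <- withCallingHandlers(
    stats::chisq.test(tab, correct = FALSE),
    warning = function(w) {
      if (grepl("approximation may be incorrect", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  .as_test_result("chi_square", res$statistic, res$parameter, res$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard H statistic with tie correction and asymptotic chi-square
#' p-value.
#'
#' @param samples List of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return An `icu_test` result with `test_name = "kruskal_wallis"`.
#' @export
kruskal_wallis_test <- function(samples) {
  .check_samples(samples)
  res <- stats::kruskal.test(samples)
  stat <- res$statistic
  p <- res$p.value
  if (is.nan(stat)) { # all observations tied: no evidence of difference
    stat <- 0; p <- 1
  }
  .as_test_result("kruskal_wallis", stat, res$parameter, p)
}

#' One-way analysis of variance across groups
#'
#' Classical equal-variance one-way ANOVA F test.
#'
#' @param samples List of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return An `icu_test` result with `test_name = "anova"`; `df` holds the
#'   numerator and denominator degrees of freedom.
#' @export
anova_test <- function(samples) {
  .check_samples(samples)
  values <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  res <- stats::oneway.test(values ~ g, var.equal = TRUE)
  stat <- res$statistic
  if (is.nan(stat)) stat <- 0  # identical groups: zero between-group SS
  .as_test_result("anova", stat,
                  c(res$parameter[["num df"]], res$parameter[["denom df"]]),
                  if (is.nan(res$p.value)) 1 else res$p.value)
}

.check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(lengths(samples) < 1))
    stop("every group needs at least one observation", call. = FALSE)
  invisible(samples)
}

#' Mortality and SMR by intensity group and age band
#'
#' One row per (age band + "All ages") x intensity group stratum, with the
#' stay count, observed deaths, mortality percentage (1 decimal, half away
#' from zero), expected deaths (sum of SAPS II-predicted probabilities),
#' and the SMR with its exact Poisson 95% interval. SMR columns are `NA`
#' where predicted mortality is unavailable (e.g. printed-table fixtures)
#' or expected deaths are zero.
#'
#' @param cohort Filtered, scored, classified cohort: needs `age`,
#'   `hospital_death`, `group` and (for SMR) `predicted_mortality`.
#' @return Data frame of stratum summaries.
#' @export
mortality_by_group_and_age <- function(cohort) {
  if (nrow(cohort) == 0)
    return(data.frame(age_band = character(), group = integer(),
                      n = integer(), observed_deaths = integer(),
                      mortality_pct = numeric(), expected_deaths = numeric(),
                      smr = numeric(), smr_low = numeric(),
                      smr_high = numeric()))
  band <- as.character(age_band(cohort$age))
  has_pred <- "predicted_mortality" %in% names(cohort) &&
    !all(is.na(cohort$predicted_mortality))
  rows <- list()
  for (g in sort(unique(cohort$group))) {
    for (b in .band_levels_all) {
      sel <- cohort$group == g & (b == "All ages" | band == b)
      n <- sum(sel)
      if (n == 0 && b != "All ages") next
      obs <- sum(cohort$hospital_death[sel])
      exp_d <- if (has_pred) sum(cohort$predicted_mortality[sel]) else NA_real_
      smr <- smr_lo <- smr_hi <- NA_real_
      if (has_pred && !is.na(exp_d) && exp_d > 0) {
        s <- compute_smr(obs, exp_d)
        smr <- s$smr; smr_lo <- s$ci_low; smr_hi <- s$ci_high
      }
      rows[[length(rows) + 1L]] <- data.frame(
        age_band = b, group = g, n = n, observed_deaths = obs,
        mortality_pct = if (n > 0) round_half_away(100 * obs / n, 1)
                        else NA_real_,
        expected_deaths = exp_d, smr = smr, smr_low = smr_lo,
        smr_high = smr_hi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Treatment-intensity distribution across an age partition
#'
#' Cross-tabulates intensity group against age bands, with column
#' percentages (1 decimal, half away from zero). Column sums equal the
#' age-band sizes.
#'
#' @param cohort Classified cohort: needs `age` and `group`.
#' @param partition `"saps2_bands"` for the six SAPS II age bands or
#'   `"binary80"` for the `<80` / `>=80` split.
#' @return List with `counts` (groups x bands matrix), `col_pct` (same
#'   shape, column percentages) and `test` (chi-square on the counts, `NA`
#'   if any margin is empty).
#' @export
intensity_distribution <- function(cohort,
                                   partition = c("saps2_bands", "binary80")) {
  partition <- match.arg(partition)
  bands <- if (partition == "saps2_bands") age_band(cohort$age)
           else age_binary(cohort$age)
  counts <- table(group = factor(cohort$group, levels = 0:3), band = bands)
  counts <- unclass(counts)
  col_n <- colSums(counts)
  col_pct <- sweep(counts, 2, pmax(col_n, 1), "/") * 100
  col_pct <- round_half_away(col_pct, 1)
  test <- if (all(col_n > 0) && all(rowSums(counts) > 0))
    chi_square_test(counts) else NULL
  list(counts = counts, col_pct = col_pct, test = test)
}

#' Stratified treatment-intensity / SMR analysis of an ICU cohort
#'
#' The package's main entry point: runs the full stratified analysis on a
#' scored, classified, filtered cohort and returns one object holding every
#' summary the analysis produces:
#'
#' * overall cohort description (n, deaths, mean age, fraction `>= 80`,
#'   mean age-adjusted SAPS II);
#' * severity and crude mortality by age band, with ANOVA / chi-square
#'   tests;
#' * the intensity-by-age contingency tables on the six SAPS II age bands
#'   and on the binary `<80`/`>=80` split, with chi-square and
#'   Kruskal-Wallis tests;
#' * hospital mortality by intensity group and age band;
#' * SMR (with exact Poisson 95% intervals) by intensity group and age
#'   band — the stratified estimates at the heart of the analysis.
#'
#' @param cohort Cohort data frame that has passed [apply_inclusion()] and
#'   carries scoring ([score_cohort()]) and classification
#'   ([classify_cohort()]) columns. Fixture cohorts without predicted
#'   mortality are accepted; SMR panels are then `NA`.
#' @return Object of class `"intensity_analysis"`. Use `print()`,
#'   `summary()`, `coef()` (the group x age-band SMR matrix) and `plot()`
#'   (mortality and SMR against age per group); [write_report()] serialises
#'   all tables to CSV/JSON.
#' @examples
#' cohort <- generate_cohort(simulation_config(n_stays = 2000))
#' cohort <- classify_cohort(score_cohort(cohort))
#' fit <- intensity_analysis(apply_inclusion(cohort)$included)
#' fit
#' @export
intensity_analysis <- function(cohort) {
  needed <- c("age", "hospital_death", "group")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "),
         "; run score_cohort()/classify_cohort() first", call. = FALSE)
  n <- nrow(cohort)
  band <- age_band(cohort$age)
  has_aa <- "age_adjusted" %in% names(cohort) &&
    !all(is.na(cohort$age_adjusted))

  overall <- list(
    n = n,
    deaths = sum(cohort$hospital_death),
    mortality_pct = round_half_away(100 * mean(cohort$hospital_death), 1),
    mean_age = mean(cohort$age), sd_age = stats::sd(cohort$age),
    n_ge80 = sum(cohort$age >= 80),
    pct_ge80 = round_half_away(100 * mean(cohort$age >= 80), 1),
    mean_age_adjusted = if (has_aa) mean(cohort$age_adjusted) else NA_real_,
    sd_age_adjusted = if (has_aa) stats::sd(cohort$age_adjusted) else NA_real_)

  by_band <- data.frame(
    age_band = levels(band),
    n = as.integer(table(band)),
    deaths = as.integer(tapply(cohort$hospital_death, band, sum,
                               default = 0)),
    row.names = NULL)
  by_band$mortality_pct <- round_half_away(
    100 * by_band$deaths / pmax(by_band$n, 1), 1)
  if (has_aa) {
    by_band$mean_age_adjusted <- as.numeric(
      tapply(cohort$age_adjusted, band, mean, default = NA))
    by_band$sd_age_adjusted <- as.numeric(
      tapply(cohort$age_adjusted, band, stats::sd, default = NA))
  }

  severity_anova <- if (has_aa && nlevels(droplevels(band)) >= 2)
    anova_test(split(cohort$age_adjusted, droplevels(band))) else NULL
  mortality_by_band_test <- {
    tab <- table(band, cohort$hospital_death)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) >= 2 && all(colSums(tab) > 0))
      chi_square_test(unclass(tab)) else NULL
  }

  dist_bands <- intensity_distribution(cohort, "saps2_bands")
  dist_bands$kruskal <- if (nlevels(droplevels(band)) >= 2)
    kruskal_wallis_test(split(cohort$group, droplevels(band))) else NULL
  dist_binary <- intensity_distribution(cohort, "binary80")

  strata <- mortality_by_group_and_age(cohort)

  by_group <- strata[strata$age_band == "All ages", , drop = FALSE]
  rownames(by_group) <- NULL

  fit <- list(overall = overall, by_band = by_band,
              severity_anova = severity_anova,
              mortality_by_band_test = mortality_by_band_test,
              intensity_by_band = dist_bands,
              intensity_binary = dist_binary,
              strata = strata, by_group = by_group)
  class(fit) <- "intensity_analysis"
  fit
}

#' @export
print.intensity_analysis <- function(x, ...) {
  o <- x$overall
  cat("Stratified treatment-intensity / SMR analysis\n")
  cat(sprintf("  %d stays, %d deaths (%.1f%%); mean age %.1f (SD %.1f), %.1f%% aged >=80\n",
              o$n, o$deaths, o$mortality_pct, o$mean_age, o$sd_age,
              o$pct_ge80))
  if (!is.na(o$mean_age_adjusted))
    cat(sprintf("  mean age-adjusted SAPS II %.1f (SD %.1f)\n",
                o$mean_age_adjusted, o$sd_age_adjusted))
  cat("\nHospital mortality (%) by intensity group, all ages:\n")
  bg <- x$by_group
  for (i in seq_len(nrow(bg)))
    cat(sprintf("  group %d: %5d stays, %5d deaths (%.1f%%)%s\n",
                bg$group[i], bg$n[i], bg$observed_deaths[i],
                bg$mortality_pct[i],
                if (is.na(bg$smr[i])) "" else
                  sprintf(", SMR %.2f [%.2f, %.2f]", bg$smr[i],
                          bg$smr_low[i], bg$smr_high[i])))
  invisible(x)
}

#' @export
summary.intensity_analysis <- function(object, ...) {
  print(object)
  cat("\nTreatment intensity by SAPS II age band (column %):\n")
  print(object$intensity_by_band$col_pct)
  if (!is.null(object$intensity_by_band$kruskal))
    print(object$intensity_by_band$kruskal)
  cat("\nMortality by age band:\n")
  print(object$by_band, row.names = FALSE)
  if (!is.null(object$severity_anova)) {
    cat("\nAge-adjusted SAPS II across bands: ")
    print(object$severity_anova)
  }
  invisible(object)
}

#' @export
coef.intensity_analysis <- function(object, ...) {
  s <- object$strata
  bands <- .band_levels_all
  groups <- sort(unique(s$group))
  out <- matrix(NA_real_, length(groups), length(bands),
                dimnames = list(group = as.character(groups), age = bands))
  for (i in seq_len(nrow(s)))
    out[as.character(s$group[i]), s$age_band[i]] <- s$smr[i]
  out
}

#' @export
plot.intensity_analysis <- function(x, which = c("mortality", "smr"), ...) {
  which <- match.arg(which)
  s <- x$strata[x$strata$age_band != "All ages", , drop = FALSE]
  groups <- sort(unique(s$group))
  bands <- .age_band_labels
  y <- if (which == "mortality") s$mortality_pct else s$smr
  if (all(is.na(y))) stop("nothing to plot: values are all NA",
                          call. = FALSE)
  ylab <- if (which == "mortality") "Hospital mortality (%)" else
    "Standardized mortality ratio"
  plot(NA, xlim = c(1, length(bands)), ylim = range(y, na.rm = TRUE),
       xaxt = "n", xlab = "Age band", ylab = ylab, ...)
  graphics::axis(1, at = seq_along(bands), labels = bands)
  for (g in groups) {
    sel <- s$group == g
    idx <- match(s$age_band[sel], bands)
    graphics::lines(idx, y[sel], type = "b", pch = 15 + g, lty = g + 1,
                    col = g + 1)
  }
  graphics::legend("topleft", legend = paste("group", groups),
                   pch = 15 + groups, lty = groups + 1, col = groups + 1,
                   bty = "n")
  if (which == "smr") graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Write all analysis tables to disk
#'
#' Serialises an [intensity_analysis()] object to a directory:
#' `table2.csv` (intensity by SAPS II age band), `table3.csv` (intensity by
#' `<80`/`>=80`), `table4.csv` (mortality by group and age band),
#' `smr_by_age_group.csv` (SMR strata) and `report.json` (everything,
#' including overall description and test results).
#'
#' @param fit An `intensity_analysis` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "intensity_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dist_to_df <- function(d) {
    df <- data.frame(group = rownames(d$counts))
    for (b in colnames(d$counts)) {
      df[[paste0("n_", b)]] <- d$counts[, b]
      df[[paste0("pct_", b)]] <- d$col_pct[, b]
    }
    df
  }
  utils::write.csv(dist_to_df(fit$intensity_by_band),
                   file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(dist_to_df(fit$intensity_binary),
                   file.path(dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(fit$strata[fit$strata$age_band %in% .band_levels_all, ],
                   file.path(dir, "table4.csv"), row.names = FALSE)
  smr <- fit$strata[fit$strata$age_band != "All ages", ]
  utils::write.csv(smr, file.path(dir, "smr_by_age_group.csv"),
                   row.names = FALSE)
  test_json <- function(t) if (is.null(t)) NULL else
    t[c("test_name", "statistic", "df", "p_value")]
  report <- list(
    overall = fit$overall,
    by_band = fit$by_band,
    severity_anova = test_json(fit$severity_anova),
    mortality_by_band_test = test_json(fit$mortality_by_band_test),
    intensity_by_band = list(counts = fit$intensity_by_band$counts,
                             col_pct = fit$intensity_by_band$col_pct,
                             chi_square = test_json(fit$intensity_by_band$test),
                             kruskal = test_json(fit$intensity_by_band$kruskal)),
    intensity_binary = list(counts = fit$intensity_binary$counts,
                            col_pct = fit$intensity_binary$col_pct,
                            chi_square = test_json(fit$intensity_binary$test)),
    strata = fit$strata)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(dir)
}
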