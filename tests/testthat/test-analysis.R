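test_that("percentage rounding is half away from zero", {
  expect_identical(round_half_away(c(10.05, 10.14, 10.15, -10.15), 1),
                   c(10.1, 10.1, 10.2, -10.2))
  expect_identical(round_half_away(30.95, 1), 31.0)
})

test_that("SMR is observed/expected with an exact Poisson interval", {
  expect_identical(compute_smr(10, 10)$smr, 1)
  expect_identical(compute_smr(20, 10)$smr, 2)
  s <- compute_smr(10, 10)
  # Garwood interval on O = 10: chi-square quantiles / (2 E)
  expect_equal(s$ci_low, qchisq(0.025, 20) / 2 / 10)
  expect_equal(s$ci_high, qchisq(0.975, 22) / 2 / 10)
  expect_identical(compute_smr(0, 5)$ci_low, 0)
  expect_error(compute_smr(10, 0), "expected")
})

test_that("chi-square equals the brute-force Pearson oracle, df included", {
  flat <- matrix(10, 2, 2)
  res <- chi_square_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_identical(res$df, 1L)

  # binary-age group-3 death table from the published counts
  tab <- matrix(c(4197, 8701 - 4197, 931, 1407 - 931), 2, 2, byrow = TRUE)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, oracle_pearson(tab), tolerance = 1e-12)
  # scale property: doubling all cells doubles the statistic
  expect_equal(chi_square_test(2 * tab)$statistic, 2 * res$statistic,
               tolerance = 1e-12)

  set.seed(15)
  for (r in 2:5) {
    tab <- matrix(rpois(r * 3, 30) + 1, r, 3)
    expect_equal(chi_square_test(tab)$statistic, oracle_pearson(tab),
                 tolerance = 1e-10)
    expect_identical(chi_square_test(tab)$df, (r - 1L) * 2L)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("Kruskal-Wallis H matches the rank-formula hand computation", {
  # two groups {1,2,3} vs {4,5,6}: ranks 1..6, no ties
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 = 12/42 * (3*(2-3.5)^2*2)
  h <- kruskal_wallis_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(h$statistic, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))
  expect_identical(h$df, 1L)
  # identical groups: H = 0 under the tie-corrected statistic
  expect_equal(kruskal_wallis_test(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_error(kruskal_wallis_test(list(1:3)), "two groups")
})

test_that("one-way ANOVA returns F and both degrees of freedom", {
  a <- anova_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  ref <- summary(aov(y ~ g, data.frame(y = 1:9,
                                       g = factor(rep(1:3, each = 3)))))[[1]]
  expect_equal(a$statistic, ref[["F value"]][1])
  expect_identical(a$df, c(2, 6))
  # identical groups: F defined as 0
  expect_equal(anova_test(list(c(5, 5), c(5, 5)))$statistic, 0)
  expect_error(anova_test(list(numeric(0), 1:3)), "observation")
})

test_that("stratified mortality table conserves counts and rounds as printed", {
  cohort <- make_analysis_cohort(n = 4000, seed = 77)
  tab <- mortality_by_group_and_age(cohort)
  all_ages <- tab[tab$age_band == "All ages", ]
  expect_identical(sum(all_ages$n), nrow(cohort))
  expect_identical(sum(all_ages$observed_deaths),
                   sum(cohort$hospital_death))
  # per-group band rows sum back to the all-ages row
  for (g in unique(tab$group)) {
    rows <- tab[tab$group == g & tab$age_band != "All ages", ]
    expect_identical(sum(rows$n), all_ages$n[all_ages$group == g])
    expect_identical(sum(rows$observed_deaths),
                     all_ages$observed_deaths[all_ages$group == g])
    expect_equal(sum(rows$expected_deaths),
                 all_ages$expected_deaths[all_ages$group == g])
  }
  expect_equal(tab$mortality_pct,
               round_half_away(100 * tab$observed_deaths / tab$n, 1))
  # SMR consistency with compute_smr
  i <- which(tab$expected_deaths > 0)[1]
  s <- compute_smr(tab$observed_deaths[i], tab$expected_deaths[i])
  expect_equal(tab$smr[i], s$smr)
  expect_equal(tab$smr_low[i], s$ci_low)

  # degenerate inputs
  expect_identical(nrow(mortality_by_group_and_age(cohort[0, ])), 0L)
  no_deaths <- cohort[1:10, ]
  no_deaths$hospital_death <- FALSE
  expect_true(all(mortality_by_group_and_age(no_deaths)$mortality_pct == 0))
})

test_that("intensity distribution columns sum to the age-band sizes", {
  cohort <- make_analysis_cohort(n = 3000, seed = 12)
  d <- intensity_distribution(cohort, "saps2_bands")
  expect_identical(as.integer(colSums(d$counts)),
                   as.vector(unname(table(age_band(cohort$age)))))
  expect_identical(sum(d$counts), nrow(cohort))
  # column percentages sum to ~100
  expect_true(all(abs(colSums(d$col_pct) - 100) < 0.3))
  # permutation invariance
  perm <- sample.int(nrow(cohort))
  d2 <- intensity_distribution(cohort[perm, ], "saps2_bands")
  expect_identical(d$counts, d2$counts)
  # single-record cohort: exactly one nonzero cell
  d1 <- intensity_distribution(cohort[7, ], "binary80")
  expect_identical(sum(d1$counts), 1L)
  expect_identical(sum(d1$counts > 0), 1L)
})

test_that("full analysis runs end-to-end on a synthetic cohort", {
  cohort <- make_analysis_cohort(n = 5000, seed = 9)
  fit <- intensity_analysis(cohort)
  expect_s3_class(fit, "intensity_analysis")
  expect_identical(fit$overall$n, nrow(cohort))
  expect_identical(fit$overall$deaths, sum(cohort$hospital_death))
  expect_identical(sum(fit$by_band$n), nrow(cohort))
  expect_identical(sum(fit$intensity_by_band$counts), nrow(cohort))
  # coef() exposes the SMR matrix
  cm <- coef(fit)
  expect_identical(dim(cm), c(length(unique(cohort$group)), 7L))
  all_ages <- fit$by_group
  expect_equal(unname(cm[, "All ages"]), all_ages$smr)
  # overall SMR near 1 under unit multipliers
  expect_lt(abs(sum(all_ages$observed_deaths) /
                  sum(all_ages$expected_deaths) - 1), 0.1)
  expect_output(print(fit), "Stratified treatment-intensity")
  expect_output(summary(fit), "age band")

  path <- withr::local_tempdir()
  write_report(fit, path)
  expect_true(all(file.exists(file.path(path,
    c("table2.csv", "table3.csv", "table4.csv", "smr_by_age_group.csv",
      "report.json")))))
  t4 <- read.csv(file.path(path, "table4.csv"))
  expect_identical(sum(t4$n[t4$age_band == "All ages"]), nrow(cohort))
  # plot method draws without error
  pdf(NULL)
  expect_silent(plot(fit, "smr"))
  dev.off()
})

test_that("SMR recovers a known stratum multiplier from a large cohort", {
  cohort <- make_analysis_cohort(n = 20000, seed = 31,
                                 multipliers = multiplier_matrix(1.5))
  fit <- intensity_analysis(cohort)
  # truth accounting for probability clamping at 1
  m <- 1.5
  p <- cohort$predicted_mortality
  truth <- sum(pmin(1, m * p)) / sum(p)
  overall <- compute_smr(sum(cohort$hospital_death), sum(p))
  expect_gt(truth, overall$ci_low)
  expect_lt(truth, overall$ci_high)
})
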