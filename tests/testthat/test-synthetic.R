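test_that("generation is a pure, deterministic function of the config", {
  cfg <- simulation_config(n_stays = 500, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(simulation_config(n_stays = 500, seed = 100))
  expect_false(identical(a, c2))
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_cohort(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("n_stays = 0 yields an empty cohort with the full schema", {
  empty <- generate_cohort(simulation_config(n_stays = 0))
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(icusmr:::.cohort_schema))
})

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(n_stays = -1), "n_stays")
  expect_error(simulation_config(frac_unknown_saps2 = 1.2),
               "frac_unknown_saps2")
  expect_error(simulation_config(mortality_multipliers = multiplier_matrix(1) - 2),
               "mortality_multipliers")
  bad_mix <- list(weights = c(0.5, 0.2), means = c(50, 70), sds = c(10, 5),
                  bounds = c(16, 100))
  expect_error(simulation_config(age_mixture = bad_mix), "age_mixture")
  expect_error(multiplier_matrix(c(1, 2)), "scalar")
})

test_that("generated records satisfy the schema invariants", {
  co <- generate_cohort(simulation_config(n_stays = 4000, seed = 3))
  expect_identical(nrow(co), 4000L)
  expect_true(all(co$age >= 16))
  expect_true(all(co$n_icu_stays_in_hospital_stay >= 1))
  unknown <- is.na(co$gcs)
  # physiology null iff flagged unknown: all-or-none missingness
  phys <- co[, setdiff(icusmr:::.physiology_fields, "pao2_fio2")]
  expect_true(all(rowSums(is.na(phys[unknown, ])) == ncol(phys)))
  expect_true(all(rowSums(is.na(phys[!unknown, ])) == 0))
  dd <- co$catecholamine %in% c("dobutamine", "dopamine")
  expect_identical(dd, !is.na(co$catecholamine_max_dose))
  expect_identical(co$invasive_mv, !is.na(co$mv_max_fio2))
  expect_identical(co$invasive_mv, !is.na(co$mv_max_peep))
  expect_true(all(co$mv_max_fio2[co$invasive_mv] >= 0.21 &
                    co$mv_max_fio2[co$invasive_mv] <= 1))
  expect_true(all(co$gcs[!unknown] >= 3 & co$gcs[!unknown] <= 15))
  # both sides of each classification threshold occur
  expect_true(any(co$catecholamine_max_dose <= 8, na.rm = TRUE))
  expect_true(any(co$catecholamine_max_dose > 8, na.rm = TRUE))
  expect_true(any(co$mv_max_fio2 < 0.6, na.rm = TRUE))
  expect_true(any(co$mv_max_fio2 >= 0.6, na.rm = TRUE))
  expect_true(any(co$mv_max_peep < 6, na.rm = TRUE))
  expect_true(any(co$mv_max_peep >= 6, na.rm = TRUE))
})

test_that("default config reproduces the target marginal shape", {
  co <- generate_cohort(simulation_config(n_stays = 20000, seed = 1))
  expect_gt(mean(co$age), 55); expect_lt(mean(co$age), 62)
  p80 <- mean(co$age >= 80)
  expect_gt(p80, 0.10); expect_lt(p80, 0.17)
  frac_mult <- mean(co$n_icu_stays_in_hospital_stay > 1)
  expect_gt(frac_mult, 0.15); expect_lt(frac_mult, 0.21)
})

test_that("with unit multipliers observed deaths match predicted mortality", {
  co <- generate_cohort(simulation_config(n_stays = 50000, seed = 8))
  sc <- score_cohort(co)
  known <- !sc$saps2_unknown
  p <- sc$predicted_mortality[known]
  obs <- sum(sc$hospital_death[known])
  se <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(obs - sum(p)), 3 * se)
})

test_that("cohort CSV round-trips field-for-field", {
  co <- generate_cohort(simulation_config(n_stays = 100, seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co, ignore_attr = TRUE)

  # header-only file: empty cohort, no error
  empty <- generate_cohort(simulation_config(n_stays = 0))
  write_cohort(empty, path)
  expect_identical(nrow(read_cohort(path)), 0L)
})

test_that("malformed cohort files are rejected with row context", {
  co <- generate_cohort(simulation_config(n_stays = 20, seed = 4,
                                          frac_unknown_saps2 = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  co$gcs[3] <- 17L
  write_cohort(co, path)
  expect_error(read_cohort(path), "row 3.*gcs|gcs.*row 3")

  co$gcs[3] <- 12L
  write_cohort(co, path)
  lines <- readLines(path)
  lines[1] <- sub("gcs", "glasgow", lines[1])
  writeLines(lines, path)
  expect_error(read_cohort(path), "unknown cohort columns")
})
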