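# Independent reference implementations used as oracles. Deliberately
# written in a different style (scalar if-else chains transcribed from the
# published definitions) so they share no code with the package.

# -- SAPS II, one record at a time ------------------------------------------
oracle_saps2_total <- function(age, p, ventilated) {
  pts <- 0
  hr <- p$heart_rate
  pts <- pts + if (hr < 40) 11 else if (hr < 70) 2 else if (hr < 120) 0
    else if (hr < 160) 4 else 7
  bp <- p$systolic_bp
  pts <- pts + if (bp < 70) 13 else if (bp < 100) 5 else if (bp < 200) 0
    else 2
  pts <- pts + if (p$temperature >= 39) 3 else 0
  if (ventilated) {
    pf <- p$pao2_fio2
    pts <- pts + if (pf < 100) 11 else if (pf < 200) 9 else 6
  }
  uo <- p$urine_output
  pts <- pts + if (uo < 0.5) 11 else if (uo < 1) 4 else 0
  ur <- p$serum_urea
  pts <- pts + if (ur < 10) 0 else if (ur < 30) 6 else 10
  w <- p$wbc
  pts <- pts + if (w < 1) 12 else if (w < 20) 0 else 3
  k <- p$potassium
  pts <- pts + if (k < 3) 3 else if (k < 5) 0 else 3
  na <- p$sodium
  pts <- pts + if (na < 125) 5 else if (na < 145) 0 else 1
  hco3 <- p$bicarbonate
  pts <- pts + if (hco3 < 15) 6 else if (hco3 < 20) 3 else 0
  bili <- p$bilirubin
  pts <- pts + if (bili < 68.4) 0 else if (bili < 102.6) 4 else 9
  g <- p$gcs
  pts <- pts + if (g < 6) 26 else if (g < 9) 13 else if (g < 11) 7
    else if (g < 14) 5 else 0
  pts <- pts + switch(p$chronic_disease, none = 0, metastatic_cancer = 9,
                      hematologic_malignancy = 10, aids = 17)
  pts <- pts + switch(p$admission_type, scheduled_surgical = 0, medical = 6,
                      unscheduled_surgical = 8)
  pts <- pts + if (age < 40) 0 else if (age < 60) 7 else if (age < 70) 12
    else if (age < 75) 15 else if (age < 80) 16 else 18
  pts
}

# physiology with every component in its zero-point band
zero_band_physiology <- function(n = 1) {
  data.frame(heart_rate = rep(80L, n), systolic_bp = 120L, temperature = 37,
             pao2_fio2 = NA_real_, urine_output = 1.5, serum_urea = 5,
             wbc = 8, potassium = 4, sodium = 138, bicarbonate = 24,
             bilirubin = 10, gcs = 15L, chronic_disease = "none",
             admission_type = "scheduled_surgical",
             stringsAsFactors = FALSE)
}

# random scoreable physiologies spanning every band (including boundaries)
random_physiology <- function(n) {
  vent <- runif(n) < 0.5
  data.frame(
    heart_rate = sample(c(20:220, 40L, 70L, 120L, 160L), n, replace = TRUE),
    systolic_bp = sample(c(40:250, 70L, 100L, 200L), n, replace = TRUE),
    temperature = round(runif(n, 33, 42), 1),
    pao2_fio2 = ifelse(vent, sample(c(40:450, 100L, 200L), n,
                                    replace = TRUE), NA_real_),
    urine_output = sample(c(seq(0, 4, by = 0.05), 0.5, 1), n,
                          replace = TRUE),
    serum_urea = sample(c(seq(1, 60, by = 0.5), 10, 30), n, replace = TRUE),
    wbc = sample(c(seq(0.2, 40, by = 0.2), 1, 20), n, replace = TRUE),
    potassium = sample(c(seq(1.5, 8, by = 0.1), 3, 5), n, replace = TRUE),
    sodium = sample(c(110:170, 125L, 145L), n, replace = TRUE),
    bicarbonate = sample(c(4:40, 15L, 20L), n, replace = TRUE),
    bilirubin = sample(c(seq(1, 300, by = 0.5), 68.4, 102.6), n,
                       replace = TRUE),
    gcs = sample(3:15, n, replace = TRUE),
    chronic_disease = sample(c("none", "metastatic_cancer",
                               "hematologic_malignancy", "aids"), n,
                             replace = TRUE),
    admission_type = sample(c("scheduled_surgical", "medical",
                              "unscheduled_surgical"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# -- intensity classifier ----------------------------------------------------
# oracle: classify one stay from first principles, then map the
# (hemodynamic, respiratory, renal) level triple through an explicit
# 18-entry rule table
oracle_levels <- function(s) {
  hemo <- "none"
  if (s$catecholamine %in% c("dobutamine", "dopamine"))
    hemo <- if (s$catecholamine_max_dose > 8) "high" else "low"
  if (s$catecholamine %in% c("epinephrine", "norepinephrine")) hemo <- "high"
  resp <- "none"
  if (isTRUE(s$niv)) resp <- "low"
  if (isTRUE(s$invasive_mv))
    resp <- if (s$mv_max_fio2 >= 0.6 || s$mv_max_peep >= 6) "high" else "low"
  renal <- if (isTRUE(s$rrt)) "high" else "none"
  c(hemo = hemo, resp = resp, renal = renal)
}

# exhaustive rule table over {none,low,high} x {none,low,high} x {none,high}
oracle_group_table <- local({
  tab <- expand.grid(hemo = c("none", "low", "high"),
                     resp = c("none", "low", "high"),
                     renal = c("none", "high"), stringsAsFactors = FALSE)
  val <- c(none = 0, low = 1, high = 2)
  tab$group <- pmin(val[tab$hemo] + val[tab$resp] + val[tab$renal], 3)
  tab
})

oracle_group <- function(levels3) {
  t <- oracle_group_table
  t$group[t$hemo == levels3[["hemo"]] & t$resp == levels3[["resp"]] &
            t$renal == levels3[["renal"]]]
}

# random support events, all invariants holding, thresholds well covered
random_supports <- function(n) {
  agent <- sample(c("none", "dobutamine", "dopamine", "epinephrine",
                    "norepinephrine"), n, replace = TRUE)
  dd <- agent %in% c("dobutamine", "dopamine")
  dose <- rep(NA_real_, n)
  dose[dd] <- sample(c(seq(0.5, 20, by = 0.5), 8, 8, 7.9, 8.1),
                     sum(dd), replace = TRUE)
  inv <- runif(n) < 0.5
  fio2 <- rep(NA_real_, n)
  fio2[inv] <- sample(c(seq(0.21, 1, by = 0.01), 0.6, 0.59, 0.61),
                      sum(inv), replace = TRUE)
  peep <- rep(NA_real_, n)
  peep[inv] <- sample(c(0:14, 6L, 5L, 7L), sum(inv), replace = TRUE)
  data.frame(catecholamine = agent, catecholamine_max_dose = dose,
             niv = runif(n) < 0.3, invasive_mv = inv, mv_max_fio2 = fio2,
             mv_max_peep = peep, rrt = runif(n) < 0.25,
             stringsAsFactors = FALSE)
}

# support events representing a given level triple (for lattice tests)
supports_for_levels <- function(hemo, resp, renal) {
  s <- data.frame(catecholamine = "none",
                  catecholamine_max_dose = NA_real_, niv = FALSE,
                  invasive_mv = FALSE, mv_max_fio2 = NA_real_,
                  mv_max_peep = NA_real_, rrt = FALSE,
                  stringsAsFactors = FALSE)
  if (hemo == "low") {
    s$catecholamine <- "dobutamine"; s$catecholamine_max_dose <- 5
  } else if (hemo == "high") {
    s$catecholamine <- "norepinephrine"
  }
  if (resp == "low") {
    s$invasive_mv <- TRUE; s$mv_max_fio2 <- 0.4; s$mv_max_peep <- 4
  } else if (resp == "high") {
    s$invasive_mv <- TRUE; s$mv_max_fio2 <- 0.8; s$mv_max_peep <- 8
  }
  s$rrt <- renal == "high"
  s
}

# -- Pearson chi-square, brute force ----------------------------------------
oracle_pearson <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  stat
}

# small scored+classified synthetic cohort ready for analysis
make_analysis_cohort <- function(n = 2000, seed = 42,
                                 multipliers = multiplier_matrix(1)) {
  cfg <- simulation_config(n_stays = n, seed = seed,
                           mortality_multipliers = multipliers)
  cl <- classify_cohort(score_cohort(generate_cohort(cfg)))
  apply_inclusion(cl)$included
}
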