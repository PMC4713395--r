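no_support <- function() supports_for_levels("none", "none", "none")

test_that("single-stay worked examples classify as published", {
  cases <- list(
    list(s = no_support(), group = 0L),
    # NIV alone: one low-intense support
    list(s = within(no_support(), niv <- TRUE), group = 1L),
    # invasive MV FiO2 0.7 / PEEP 5: one high-intense support
    list(s = supports_for_levels("none", "none", "none") |>
           transform(invasive_mv = TRUE, mv_max_fio2 = 0.7, mv_max_peep = 5),
         group = 2L),
    # dobutamine 5 + invasive MV 0.5/5: two low-intense supports
    list(s = transform(no_support(), catecholamine = "dobutamine",
                       catecholamine_max_dose = 5, invasive_mv = TRUE,
                       mv_max_fio2 = 0.5, mv_max_peep = 5), group = 2L),
    # norepinephrine + RRT: two high-intense supports
    list(s = transform(no_support(), catecholamine = "norepinephrine",
                       rrt = TRUE), group = 3L))
  for (cs in cases)
    expect_identical(classify_supports(cs$s)$group, cs$group)
})

test_that("threshold boundaries follow the operational definitions", {
  # dose exactly 8 ug/kg/min is low-intense; above 8 is high-intense
  d8 <- transform(no_support(), catecholamine = "dopamine",
                  catecholamine_max_dose = 8)
  expect_identical(classify_supports(d8)$hemodynamic, "low")
  d8.1 <- transform(d8, catecholamine_max_dose = 8.1)
  expect_identical(classify_supports(d8.1)$hemodynamic, "high")
  # epinephrine / norepinephrine high at any dose
  for (a in c("epinephrine", "norepinephrine"))
    expect_identical(
      classify_supports(transform(no_support(),
                                  catecholamine = a))$hemodynamic, "high")
  # FiO2 exactly 0.6 or PEEP exactly 6 make invasive MV high-intense
  mv <- function(f, p) transform(no_support(), invasive_mv = TRUE,
                                 mv_max_fio2 = f, mv_max_peep = p)
  expect_identical(classify_supports(mv(0.60, 0))$respiratory, "high")
  expect_identical(classify_supports(mv(0.59, 6))$respiratory, "high")
  expect_identical(classify_supports(mv(0.59, 5))$respiratory, "low")
})

test_that("classification equals the rule-table oracle on the full lattice", {
  for (i in seq_len(nrow(oracle_group_table))) {
    lv <- oracle_group_table[i, ]
    s <- supports_for_levels(lv$hemo, lv$resp, lv$renal)
    got <- classify_supports(s)
    expect_identical(got$hemodynamic, lv$hemo)
    expect_identical(got$respiratory, lv$resp)
    expect_identical(got$renal, lv$renal)
    expect_identical(got$group, as.integer(lv$group))
    expect_identical(got$group,
                     as.integer(min(got$intensity_points, 3L)))
  }
})

test_that("classification agrees with the oracle on randomized supports", {
  set.seed(202)
  s <- random_supports(10000)
  got <- classify_supports(s)
  for (i in seq_len(nrow(s))) {
    lv <- oracle_levels(s[i, ])
    expect_identical(got$group[i], as.integer(oracle_group(lv)))
  }
  expect_true(all(got$group %in% 0:3))
  expect_identical(got$group == 3L, got$intensity_points >= 3L)
  expect_identical(got$group == 0L,
                   got$hemodynamic == "none" & got$respiratory == "none" &
                     got$renal == "none")
})

test_that("upgrading any organ never decreases the group (monotonicity)", {
  rank3 <- c(none = 0, low = 1, high = 2)
  t <- oracle_group_table
  grp <- function(h, r, rn)
    classify_supports(supports_for_levels(h, r, rn))$group
  for (i in seq_len(nrow(t))) {
    g0 <- grp(t$hemo[i], t$resp[i], t$renal[i])
    for (j in seq_len(nrow(t))) {
      dominates <- rank3[t$hemo[j]] >= rank3[t$hemo[i]] &&
        rank3[t$resp[j]] >= rank3[t$resp[i]] &&
        rank3[t$renal[j]] >= rank3[t$renal[i]]
      if (dominates)
        expect_gte(grp(t$hemo[j], t$resp[j], t$renal[j]), g0)
    }
  }
})

test_that("intensity_group is vectorised and order-preserving", {
  set.seed(11)
  s <- random_supports(200)
  g <- intensity_group(s)
  expect_identical(g, classify_supports(s)$group)
  perm <- sample.int(200)
  expect_identical(intensity_group(s[perm, ]), g[perm])
})

test_that("invalid support events are rejected", {
  expect_error(classify_supports(
    transform(no_support(), catecholamine = "dobutamine")), "dose")
  expect_error(classify_supports(
    transform(no_support(), invasive_mv = TRUE)), "mv_max")
  expect_error(classify_supports(
    transform(no_support(), mv_max_fio2 = 0.5)), "invasive")
})
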