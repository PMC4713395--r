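---
title: "Treatment intensity, age and risk-adjusted ICU mortality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment intensity, age and risk-adjusted ICU mortality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icusmr)
```

## The scientific question

Older ICU patients die more often than younger ones, but severity scores
rise only modestly with age. One candidate explanation is that the *amount*
of organ support delivered, and its efficiency, differ across ages. `icusmr`
implements an analysis of that question on administrative hospital-stay
data: it scores severity (SAPS II), classifies each stay into a four-group
treatment-intensity indicator built from the three most common organ
supports, applies cohort inclusion rules, and compares observed with
severity-predicted mortality (the standardized mortality ratio, SMR) within
age x intensity strata.

## Severity: SAPS II and its age-adjusted variant

SAPS II sums integer points over 15 variables: 12 physiological measurements
(worst value of the first 24 h), chronic disease, admission type, and age.
The point table and the logistic conversion to a predicted probability of
hospital death,

$$\operatorname{logit}(p) = -7.7631 + 0.0737\,S + 0.9971\,\ln(S+1),$$

are frozen constants in this package, taken from the score's original 1993
definition, and pinned by checksum-style tests so any silent edit fails.
The *age-adjusted* SAPS II subtracts the age-related points (0 / 7 / 12 /
15 / 16 / 18 for the bands `<40`, `40-59`, `60-69`, `70-74`, `75-79`,
`>=80`) and serves as an age-independent severity index; the inclusion
threshold "age-adjusted SAPS II > 15" is the usual administrative boundary
between intensive and intermediate care. All age bands are left-closed
(40 belongs to `40-59`, 80 to `>=80`). The scoring functions take the
already-selected scoreable values; choosing worst-in-24h values is the data
producer's job. Missing physiology is never imputed: such stays are flagged
`saps2_unknown` and excluded by the filter.

The PaO2/FiO2 component is defined only under ventilation (invasive or
CPAP); `score_saps2()` therefore requires the ratio exactly when the
`ventilated` flag is set and rejects inconsistent records rather than
guessing.

## The treatment-intensity indicator

Each of the three organ supports is graded none / low-intense /
high-intense from stay-level procedure summaries:

| organ | low-intense | high-intense |
|---|---|---|
| hemodynamic | dobutamine or dopamine <= 8 ug/kg/min | > 8 ug/kg/min, or any epinephrine / norepinephrine |
| respiratory | NIV, or invasive MV with FiO2 < 0.6 and PEEP < 6 cm H2O | invasive MV with FiO2 >= 0.6 or PEEP >= 6 cm H2O |
| renal | — | any renal replacement therapy |

Counting low = 1 point and high = 2, the intensity group is
`min(points, 3)`: 0 = no support, 1 = one low-intense support, 2 = two lows
or one high, 3 = anything more intense. This "points >= 3" formalisation of
group 3 is the unique monotone extension of the three enumerated groups.
Design choices worth stating:

* each organ takes the **maximum** level over the stay (the database stores
  stay-level summaries; there is no timeline), so NIV plus invasive MV is
  graded by the invasive settings;
* the dose boundary is **<= 8 low / > 8 high**: the indicator's defining
  table uses "<= 8" even though accompanying prose says "less than 8"; the
  table is the operational definition;
* epinephrine and norepinephrine are high-intense at any dose — no dose
  threshold exists for them;
* CPAP counts as respiratory support only when coded as NIV.

## Inclusion rules and flowchart accounting

A stay enters the analysis cohort iff it is a *medical*-ICU stay, unique
within its hospital stay, with known SAPS II and age-adjusted SAPS II
strictly above 15. A stay failing several rules is counted under exactly one
exclusion reason, in the fixed precedence order non-medical ICU, multiple
ICU stays, unknown SAPS II, low severity; the order is a package convention
(no published order exists) chosen so flowchart counts are reproducible.
The order does not affect which stays are included, only the per-reason
tallies.

## Stratified analysis and the SMR

For every (age band x intensity group) stratum, and for each margin, the
package reports the stay count, observed deaths, mortality percentage,
expected deaths $E=\sum_i p_i$ (sum of SAPS II-predicted probabilities) and
$\mathrm{SMR} = O/E$. Two numerical conventions:

* **Expected deaths use the full SAPS II probability**, not the
  age-adjusted score: the age-adjusted index is only the inclusion
  threshold and severity covariate, while the SMR question is "more or
  fewer deaths than the score predicts".
* **Confidence intervals** are exact Poisson (Garwood) intervals on $O$
  with $E$ fixed: $[\chi^2_{2O,\alpha/2}/2,\ \chi^2_{2(O+1),1-\alpha/2}/2]/E$,
  with lower limit 0 at $O=0$. The reference analysis reports no interval
  method; a defensible one is needed to draw SMR-versus-age curves
  honestly.
* **Display rounding** is half away from zero to one decimal
  (`round_half_away()`), matching how the published tables print; all
  internal computation is unrounded.

Group comparisons use the classical machinery: Pearson chi-square without
continuity correction (large-sample tables), Kruskal-Wallis with tie
correction for the ordinal intensity distribution across age bands, and
equal-variance one-way ANOVA for quantitative variables. Degenerate inputs
(all observations tied) return a zero statistic with p = 1 rather than NaN.

## The synthetic cohort generator

The study's administrative database is not public. `generate_cohort()`
therefore emulates its *structure*, with every parameter explicit in
`simulation_config()` and the whole draw a pure function of the seed
(default 20060101):

* **Age** is a three-component truncated-normal mixture
  (weights 0.40/0.48/0.12, means 44/64/85, SDs 14/10/4, truncated to
  [16, 100]) giving mean ~58.4, SD ~17.5 and ~13.5% of patients aged >= 80,
  emulating the reference cohort's reported marginals (58.3 / 18.2 /
  13.6%).
* **Severity** is one standard-normal latent per stay with a 0.15 loading
  on standardised age — enough to reproduce the reported slight upward
  drift of age-adjusted severity with age. Physiology fields are monotone
  deformations of the latent plus field-specific noise; support allocation
  is logistic in it, which induces the severity-intensity correlation
  without committing to unobserved structure.
* **Doses and ventilator settings** straddle every classification boundary
  by construction (dose log-normal with median exactly 8 ug/kg/min; FiO2
  and PEEP spread across 0.6 and 6 cm H2O), so classifier boundary
  behaviour is always exercised by generated data.
* **Mortality** is Bernoulli with
  $P(\text{death}) = \min(1, m_{b,g}\, p_{\text{SAPS II}})$ where
  $m_{b,g}$ is the configured multiplier of the stay's (age band,
  intensity group) stratum, evaluated with the *same* banding and
  classification rules as the analysis. With all multipliers 1 the cohort
  is perfectly calibrated by construction; in general a stratum's SMR
  converges to $\sum_i \min(1, m p_i) / \sum_i p_i$, the multiplier
  deflated by clamping — recovery tests compare against this exact
  conditional expectation, not against the raw $m$.
* 17.6% of stays get multiple ICU stays (the published exclusion fraction
  6346/36002) and 5% get masked physiology (no published count exists; a
  plausible administrative missingness rate, chosen once). Non-medical ICU
  stays default to 0% since the source database covers medical ICUs only.

Support-allocation intercepts and slopes were calibrated once against the
published intensity distribution (31 / 14.6 / 13.6 / 42.9% across groups
0-3) and then frozen; the defaults land at roughly 29 / 16 / 16 / 39% after
filtering, and the included cohort's mean age-adjusted SAPS II (~37) runs a
few points below the reported 41. The generator reproduces stated marginals
and the multiplicative mortality structure — not the real joint
distribution of physiology, not ICD-10 case mix, not inter-hospital or
temporal structure. Passing recovery tests therefore validate the
*pipeline's estimators* under a known truth; they are not evidence about
any real cohort.

## What the fixture can and cannot check

`reference_fixture()` re-encodes the published per-stratum stay and death
counts of the reference cohort (23,578 stays). Expanded to one row per
stay, it lets the table builders reproduce every published percentage
exactly — a worked-example check of counting and rounding. It carries no
physiology, so predicted mortality and hence SMR are undefined on it; SMR
behaviour is validated on synthetic cohorts instead. One internal
inconsistency of the published tables is worth knowing: the binary-split
table prints 6624 group-0 stays under age < 80, while the per-band counts
sum to 6224 — and the percentages printed next to it (30.5%, and 8.2%
group-0 mortality under 80) match 6224. The package derives all binary-split
numbers from the per-band counts.

## Problem sizes and reproducibility

The test suite generates its cohorts at n = 2,000-50,000 stays and uses 100
replicate seeds for multiplier recovery — sizes at which stratum-level
Monte-Carlo error (about $\sqrt{O}/E$) is a few percent of the SMR, small
enough to separate the configured multipliers {0.5, 1, 1.5, 2}. All
randomness flows from explicit seeds; `generate_cohort()` restores the
caller's RNG state, so package functions never perturb a user's random
stream.

## Worked example

```{r example}
cfg <- simulation_config(n_stays = 10000)
cohort <- generate_cohort(cfg)
included <- apply_inclusion(classify_cohort(score_cohort(cohort)))$included
fit <- intensity_analysis(included)
fit
coef(fit)  # SMR by intensity group and age band
```

## Known limitations

* SAPS II is used as published (1993 logit); the score's known
  decalibration on modern cohorts is deliberately not corrected, matching
  the analysis it supports. Absolute SMRs on real data should be read
  accordingly.
* The intensity indicator ignores treatment duration, dose trajectories and
  the number of support episodes — none exist in stay-level administrative
  summaries.
* The generator's support-allocation parameters are convenience choices
  reproducing stated marginals, not estimates of any real allocation
  process.
* Hospital mortality is the only outcome; no readmission, functional or
  longer-term endpoints.
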