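#' Classify organ supports into the four-group treatment-intensity indicator
#'
#' Assigns each ICU stay a per-organ support level and the four-group
#' treatment-intensity classification used throughout the analysis:
#'
#' * Low-intense supports: dobutamine or dopamine at `<= 8` ug/kg/min;
#'   noninvasive ventilation; invasive mechanical ventilation with
#'   FiO2 `< 0.6` **and** PEEP `< 6` cm H2O.
#' * High-intense supports: dobutamine or dopamine at `> 8` ug/kg/min, or
#'   epinephrine or norepinephrine at any dose; invasive mechanical
#'   ventilation with FiO2 `>= 0.6` **or** PEEP `>= 6` cm H2O; any renal
#'   replacement therapy.
#'
#' Each organ (hemodynamic, respiratory, renal) takes the maximum level
#' attained by any qualifying support over the whole stay; renal support is
#' only ever high-intense. Counting a low-intense support as 1 point and a
#' high-intense support as 2, the intensity group is `min(points, 3)`:
#' group 0 = no support, 1 = one low-intense support, 2 = two low-intense
#' supports or one high-intense support, 3 = more intense support.
#'
#' @param supports Data frame with one row per stay and columns
#'   `catecholamine` (`none`, `dobutamine`, `dopamine`, `epinephrine`,
#'   `norepinephrine`), `catecholamine_max_dose` (ug/kg/min; required for
#'   dobutamine/dopamine, `NA` otherwise), `niv` (logical), `invasive_mv`
#'   (logical), `mv_max_fio2` (fraction 0.21-1.0, `NA` unless invasive MV),
#'   `mv_max_peep` (cm H2O, `NA` unless invasive MV), `rrt` (logical).
#' @return Data frame with columns `hemodynamic`, `respiratory` (each
#'   `none`/`low`/`high`), `renal` (`none`/`high`), `intensity_points`
#'   (integer) and `group` (integer 0-3), one row per input row.
#' @examples
#' classify_supports(data.frame(
#'   catecholamine = "norepinephrine", catecholamine_max_dose = NA_real_,
#'   niv = FALSE, invasive_mv = TRUE, mv_max_fio2 = 0.7, mv_max_peep = 8,
#'   rrt = TRUE))  # two high-intense supports: group 3
#' @export
classify_supports <- function(supports) {
  supports <- as.data.frame(supports)
  .check_supports(supports)
  n <- nrow(supports)

  agent <- supports$catecholamine
  dose <- supports$catecholamine_max_dose
  hemo <- rep("none", n)
  dd <- agent %in% c("dobutamine", "dopamine")
  hemo[dd & dose <= 8] <- "low"
  hemo[dd & dose > 8] <- "high"
  hemo[agent %in% c("epinephrine", "norepinephrine")] <- "high"

  resp <- rep("none", n)
  resp[supports$niv] <- "low"
  inv <- supports$invasive_mv
  inv_high <- inv & (supports$mv_max_fio2 >= 0.6 | supports$mv_max_peep >= 6)
  resp[inv & !inv_high] <- "low"
  resp[inv_high] <- "high"

  renal <- ifelse(supports$rrt, "high", "none")

  level_pts <- c(none = 0L, low = 1L, high = 2L)
  points <- level_pts[hemo] + level_pts[resp] + level_pts[renal]
  data.frame(hemodynamic = hemo, respiratory = resp, renal = renal,
             intensity_points = as.integer(points),
             group = as.integer(pmin(points, 3L)),
             row.names = NULL)
}

.check_supports <- function(supports) {
  required <- c("catecholamine", "catecholamine_max_dose", "niv",
                "invasive_mv", "mv_max_fio2", "mv_max_peep", "rrt")
  missing_cols <- setdiff(required, names(supports))
  if (length(missing_cols))
    stop("supports is missing fields: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  agents <- c("none", "dobutamine", "dopamine", "epinephrine",
              "norepinephrine")
  if (!all(supports$catecholamine %in% agents))
    stop("catecholamine must be one of: ", paste(agents, collapse = ", "),
         call. = FALSE)
  dd <- supports$catecholamine %in% c("dobutamine", "dopamine")
  if (any(dd & is.na(supports$catecholamine_max_dose)))
    stop("catecholamine_max_dose required for dobutamine/dopamine",
         call. = FALSE)
  if (any(!dd & !is.na(supports$catecholamine_max_dose)))
    stop("catecholamine_max_dose only meaningful for dobutamine/dopamine",
         call. = FALSE)
  inv <- supports$invasive_mv
  if (any(inv & (is.na(supports$mv_max_fio2) | is.na(supports$mv_max_peep))))
    stop("mv_max_fio2 and mv_max_peep required under invasive ventilation",
         call. = FALSE)
  if (any(!inv & (!is.na(supports$mv_max_fio2) | !is.na(supports$mv_max_peep))))
    stop("mv_max_fio2/mv_max_peep given without invasive ventilation",
         call. = FALSE)
  fio2 <- supports$mv_max_fio2[inv]
  if (any(fio2 < 0.21 | fio2 > 1))
    stop("mv_max_fio2 must lie in [0.21, 1]", call. = FALSE)
  if (any(supports$mv_max_peep[inv] < 0))
    stop("mv_max_peep must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Treatment-intensity group for a cohort
#'
#' Vectorised, order-preserving shortcut for `classify_supports(...)$group`.
#'
#' @param records Data frame containing the support columns (see
#'   [classify_supports()]).
#' @return Integer vector of intensity groups (0-3), one per row.
#' @export
intensity_group <- function(records) {
  classify_supports(records)$group
}
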