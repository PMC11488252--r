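#' Milk-clotting activity in Soxhlet units per ml
#'
#' One Soxhlet unit (SU) is the amount of enzyme that clots 1 ml of a
#' standard skim-milk/CaCl2 solution in 40 min (2400 s) at 35 degC. With
#' the standard assay (0.5 ml enzyme added to 5 ml milk) the activity of
#' a sample that clots the milk in `T` seconds at dilution `D` is
#'
#'   SU/ml = (2400 * 5 * D) / (T * 0.5) = 24000 * D / T
#'
#' The commonly printed one-line form "2400 x 5 x D/T x 0.5" is grouped
#' here as reference_time x milk_volume x dilution over clotting_time x
#' enzyme_volume: only that grouping satisfies the unit definition
#' (0.5 ml holding 5 SU clots 5 ml in exactly 40 min, i.e. 10 SU/ml at
#' T = 2400 s, D = 1); the literal left-to-right reading does not.
#'
#' @param clotting_time_s observed clotting time in seconds (> 0).
#' @param dilution dilution factor of the test material (>= 1).
#' @param milk_volume_ml volume of reconstituted skim milk in the assay
#'   tube (ml), default 5.
#' @param enzyme_volume_ml volume of enzyme preparation added (ml),
#'   default 0.5.
#' @param reference_time_s clotting time defining one unit (s),
#'   default 2400 (40 min).
#' @return activity in SU per ml of enzyme preparation (vectorized over
#'   `clotting_time_s` and `dilution`).
#' @examples
#' soxhlet_units(2400)         # definitional case: 10 SU/ml
#' soxhlet_units(12)           # 2000 SU/ml
#' soxhlet_units(50, dilution = 2)
#' @export
soxhlet_units <- function(clotting_time_s, dilution = 1,
                          milk_volume_ml = 5, enzyme_volume_ml = 0.5,
                          reference_time_s = 2400) {
  check_positive(clotting_time_s, "clotting_time_s", scalar = FALSE)
  check_positive(milk_volume_ml, "milk_volume_ml")
  check_positive(enzyme_volume_ml, "enzyme_volume_ml")
  check_positive(reference_time_s, "reference_time_s")
  if (!is.numeric(dilution) || anyNA(dilution) || any(dilution < 1)) {
    stop("`dilution` must be numeric and >= 1", call. = FALSE)
  }
  (reference_time_s * milk_volume_ml * dilution) /
    (clotting_time_s * enzyme_volume_ml)
}

#' Ratio of milk-clotting to general protease activity
#'
#' A high MCA/PA ratio is the figure of merit for cheese-making
#' coagulants: clotting without excessive proteolysis of the curd.
#'
#' @param mca milk-clotting activity (SU/ml, >= 0).
#' @param pa protease activity (tyrosine-release units per ml, > 0).
#' @return the dimensionless ratio `mca / pa` at full precision; round
#'   to the nearest integer for reporting.
#' @examples
#' round(mca_pa_ratio(3000, 0.272))  # 11029
#' @export
mca_pa_ratio <- function(mca, pa) {
  check_positive(mca, "mca", strict = FALSE, scalar = FALSE)
  check_positive(pa, "pa", scalar = FALSE)
  mca / pa
}

#' Cell leakage from immobilization beads
#'
#' Leakage of cells from alginate beads into the medium is quantified by
#' comparing the optical density of the immobilized-cell culture
#' filtrate with that of a free-cell culture:
#' `100 - 100 * od_immobilized / od_free`. A negative value (immobilized
#' filtrate denser than the free control, possible under measurement
#' noise) is returned as-is with an `out_of_range` flag rather than
#' being clamped or rejected.
#'
#' @param od_immobilized optical density of the immobilized-cell culture
#'   filtrate (>= 0).
#' @param od_free optical density of the free-cell culture filtrate
#'   (> 0).
#' @return a list with `percent` (leakage retained inside the beads, in
#'   percent of the free-cell OD) and logical `out_of_range`.
#' @examples
#' leakage_percent(0.25, 1.0)$percent  # 75
#' @export
leakage_percent <- function(od_immobilized, od_free) {
  check_positive(od_immobilized, "od_immobilized", strict = FALSE)
  check_positive(od_free, "od_free")
  pct <- 100 - 100 * od_immobilized / od_free
  list(percent = pct, out_of_range = pct < 0)
}

#' Normalize an activity profile to its optimum
#'
#' Expresses activity across a swept condition (temperature, pH, carbon
#' or nitrogen source, ...) as a percentage of the maximum, which
#' defines the optimum condition (100 % activity). Ties are broken by
#' the first occurrence of the maximum, matching the convention of
#' calling the lower temperature the optimum when two levels share the
#' peak activity.
#'
#' @param profile a data frame with columns `level` (condition label or
#'   numeric value) and `activity` (>= 0, at least one > 0). Additional
#'   columns (e.g. `form`, `spread`) are carried through.
#' @return a [tibble::tibble] with an added `relative_pct` column in
#'   \[0, 100\] (max exactly 100), with attributes `optimum_level` and
#'   `optimum_index`.
#' @examples
#' p <- data.frame(level = c(25, 30, 35, 40), activity = c(400, 1200, 2400, 2400))
#' normalize_profile(p)
#' @export
normalize_profile <- function(profile) {
  profile <- as_profile_df(profile)
  act <- profile$activity
  if (all(act == 0)) {
    stop("degenerate profile: all activities are zero", call. = FALSE)
  }
  i_max <- which.max(act)   # first occurrence on ties
  out <- tibble::as_tibble(profile)
  out$relative_pct <- 100 * act / act[i_max]
  attr(out, "optimum_level") <- profile$level[i_max]
  attr(out, "optimum_index") <- i_max
  out
}

# Shared validation for profile-shaped inputs.
as_profile_df <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("level", "activity") %in% names(profile))) {
    stop("`profile` must be a data frame with columns `level` and `activity`",
         call. = FALSE)
  }
  if (nrow(profile) == 0L) {
    stop("`profile` has no rows", call. = FALSE)
  }
  check_positive(profile$activity, "activity", strict = FALSE, scalar = FALSE)
  profile
}

#' Retention of enzyme production across reuse cycles
#'
#' Immobilized beads are recovered after each fermentation cycle and
#' reused; operational stability is the per-cycle production expressed
#' as a percentage of the first cycle.
#'
#' @param production numeric vector of per-cycle enzyme production
#'   (SU/ml), ordered by cycle; cycle 1 must be > 0.
#' @param cycle optional integer cycle indices (default `1:n`).
#' @return a [tibble::tibble] with columns `cycle`, `production`,
#'   `retention_pct` (cycle 1 = 100 by construction).
#' @examples
#' reuse_retention(c(3000, 3000, 2010))
#' @export
reuse_retention <- function(production, cycle = seq_along(production)) {
  if (length(production) == 0L) {
    stop("`production` is empty", call. = FALSE)
  }
  check_positive(production, "production", strict = FALSE, scalar = FALSE)
  if (production[1] <= 0) {
    stop("cycle-1 `production` must be > 0", call. = FALSE)
  }
  if (length(cycle) != length(production)) {
    stop("`cycle` and `production` lengths differ", call. = FALSE)
  }
  tibble::tibble(
    cycle = as.integer(cycle),
    production = production,
    retention_pct = 100 * production / production[1]
  )
}
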