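#' Arrhenius regression for activation or deactivation energy
#'
#' Fits `ln(response)` against `1/T` (K^-1) by ordinary least squares
#' and converts the slope to an energy: `E = -slope * R / 1000` kJ/mol,
#' with R = 8.314 J K^-1 mol^-1.
#'
#' The same sign convention is used for both modes. In activation mode
#' the response is an activity or production rising with temperature
#' below the optimum (slope negative on the 1/T axis, energy positive).
#' In deactivation mode the response is the deactivation rate constant
#' kd, which also rises with temperature, so the slope is again
#' negative and `Ed = -slope * R` is positive; a negative energy is
#' flagged (`well_posed = FALSE`), not rejected.
#'
#' @param temperature_K absolute temperatures in Kelvin (> 200),
#'   all distinct, length >= 2.
#' @param response positive responses: relative activity (%), production
#'   (SU/ml), or kd (min^-1), matching `temperature_K`.
#' @param mode `"activation"` (energy reported as Ea) or
#'   `"deactivation"` (Ed).
#' @return an object of class `arrhenius_fit`: list with `slope` (K, on
#'   the 1/T axis), `slope_per_1000` (the same slope on the 1000/T axis,
#'   = `slope / 1000`), `intercept`, `energy_kJ_mol`, `r_squared`,
#'   `n_points`, `mode`, `well_posed`.
#' @examples
#' T_K <- celsius_to_kelvin(c(25, 35, 45))
#' k <- 1e6 * exp(-50000 / (8.314 * T_K))
#' fit_arrhenius(T_K, k, mode = "activation")$energy_kJ_mol  # 50
#' @export
fit_arrhenius <- function(temperature_K, response,
                          mode = c("activation", "deactivation")) {
  mode <- match.arg(mode)
  if (!is.numeric(temperature_K) || !is.numeric(response) ||
      anyNA(temperature_K) || anyNA(response) ||
      any(!is.finite(temperature_K)) || any(!is.finite(response))) {
    stop("`temperature_K` and `response` must be finite and non-missing",
         call. = FALSE)
  }
  if (length(temperature_K) != length(response)) {
    stop("`temperature_K` and `response` lengths differ", call. = FALSE)
  }
  if (length(temperature_K) < 2L) {
    stop("insufficient data: need >= 2 Arrhenius points", call. = FALSE)
  }
  if (anyDuplicated(temperature_K)) {
    stop("insufficient data: temperatures must be distinct", call. = FALSE)
  }
  if (any(temperature_K <= 200)) {
    stop("`temperature_K` must be in Kelvin (> 200)", call. = FALSE)
  }
  if (any(response <= 0)) {
    stop("`response` must be > 0 (log is taken)", call. = FALSE)
  }

  x <- 1 / temperature_K
  y <- log(response)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- r_squared_of(fit, y)
  energy <- -slope * GAS_CONSTANT / 1000

  structure(list(
    slope = slope,
    slope_per_1000 = slope / 1000,
    intercept = intercept,
    energy_kJ_mol = energy,
    r_squared = r2,
    n_points = length(x),
    mode = mode,
    well_posed = energy > 0
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  label <- if (x$mode == "activation") "Ea" else "Ed"
  cat("Arrhenius fit (", x$mode, " mode, ", x$n_points, " points)\n", sep = "")
  cat(sprintf("  %s        = %.2f kJ/mol%s\n", label, x$energy_kJ_mol,
              if (x$well_posed) "" else "  [flag: negative energy]"))
  cat(sprintf("  slope     = %.6g K (1/T axis)\n", x$slope))
  cat(sprintf("  r-squared = %.4f\n", x$r_squared))
  invisible(x)
}

#' Ascending limb of an activity--temperature profile
#'
#' The activation-energy fit uses only the rising part of the
#' activity--temperature curve: above the optimum the apparent activity
#' is dominated by denaturation, not activation. This selects the
#' records at temperatures up to and including the optimum (first
#' occurrence of the maximum on ties) and converts them to Kelvin.
#'
#' @param profile a data frame with numeric `level` (degrees Celsius)
#'   and `activity` columns, as accepted by [normalize_profile()].
#' @return a [tibble::tibble] with columns `temperature_K` and
#'   `response`, ready for [fit_arrhenius()].
#' @examples
#' p <- data.frame(level = seq(25, 60, 5),
#'                 activity = c(400, 1200, 2400, 2400, 2000, 1750, 1200, 800))
#' select_ascending_limb(p)  # 25, 30, 35 degC
#' @export
select_ascending_limb <- function(profile) {
  profile <- as_profile_df(profile)
  if (!is.numeric(profile$level)) {
    stop("`profile$level` must be numeric temperatures in degC", call. = FALSE)
  }
  normed <- normalize_profile(profile)
  i_max <- attr(normed, "optimum_index")
  keep <- which(profile$level <= profile$level[i_max])
  if (length(keep) < 2L) {
    stop("insufficient data: ascending limb has fewer than 2 points",
         call. = FALSE)
  }
  tibble::tibble(
    temperature_K = celsius_to_kelvin(profile$level[keep]),
    response = profile$activity[keep]
  )
}
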