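#' Fit first-order thermal inactivation to a residual-activity series
#'
#' Irreversible thermal denaturation of the enzyme is modelled as
#' first-order loss: `A(t) = A0 * exp(-kd * t)`. The deactivation rate
#' constant `kd` is estimated by ordinary least squares of
#' `ln(residual fraction)` on time; `kd = -slope`. The time-0 point
#' (typically 100 %) enters the regression like any other point — the
#' intercept is estimated, not forced.
#'
#' Zero or negative residual activities cannot enter the log fit and
#' are dropped with a warning. A non-negative slope (activity not
#' decaying) is flagged via `decaying = FALSE` rather than rejected.
#'
#' @param time_min times in minutes, strictly increasing, >= 0.
#' @param residual_pct residual activity in percent of the unheated
#'   control (100 = no loss).
#' @return an object of class `decay_fit`: a list with `kd` (min^-1),
#'   `intercept` (ln fraction at t = 0), `r_squared`, `half_life_min`
#'   (`ln(2)/kd`), `d_value_min` (`ln(10)/kd`), `n_points`, `decaying`.
#'   For a non-decaying series `kd`, `half_life_min` and `d_value_min`
#'   are `NA`.
#' @examples
#' fit_first_order_decay(c(0, 15, 30, 45, 60),
#'                       100 * exp(-0.01 * c(0, 15, 30, 45, 60)))
#' @seealso [half_life()], [d_value()], [summarize_inactivation()]
#' @export
fit_first_order_decay <- function(time_min, residual_pct) {
  if (!is.numeric(time_min) || !is.numeric(residual_pct) ||
      anyNA(time_min) || anyNA(residual_pct) ||
      any(!is.finite(time_min)) || any(!is.finite(residual_pct))) {
    stop("`time_min` and `residual_pct` must be finite and non-missing",
         call. = FALSE)
  }
  if (length(time_min) != length(residual_pct)) {
    stop("`time_min` and `residual_pct` lengths differ", call. = FALSE)
  }
  if (any(time_min < 0)) stop("`time_min` must be >= 0", call. = FALSE)
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }

  usable <- residual_pct > 0
  if (any(!usable)) {
    warning(sprintf("%d point(s) with residual activity <= 0 excluded from log fit",
                    sum(!usable)), call. = FALSE)
  }
  t <- time_min[usable]
  y <- log(residual_pct[usable] / 100)
  n <- length(t)
  if (n < 2L) {
    stop("insufficient data: need >= 2 points with residual activity > 0",
         call. = FALSE)
  }

  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- r_squared_of(fit, y)
  decaying <- slope < 0
  kd <- if (decaying) -slope else NA_real_

  structure(list(
    kd = kd,
    intercept = intercept,
    r_squared = r2,
    half_life_min = if (decaying) half_life(kd) else NA_real_,
    d_value_min = if (decaying) d_value(kd) else NA_real_,
    n_points = n,
    decaying = decaying
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order inactivation fit (", x$n_points, " points)\n", sep = "")
  if (!x$decaying) {
    cat("  series is not decaying (slope >= 0); no kd reported\n")
  } else {
    cat(sprintf("  kd        = %.6g min^-1\n", x$kd))
    cat(sprintf("  t1/2      = %.4g min\n", x$half_life_min))
    cat(sprintf("  D-value   = %.4g min\n", x$d_value_min))
  }
  cat(sprintf("  r-squared = %.4f\n", x$r_squared))
  invisible(x)
}

#' Half-life of activity under first-order inactivation
#'
#' Time for residual activity to fall to 50 %: `t1/2 = ln(2) / kd`.
#'
#' @param kd first-order deactivation rate constant (min^-1, > 0).
#' @return half-life in minutes (vectorized).
#' @examples
#' half_life(log(2) / 182)  # 182 min
#' @export
half_life <- function(kd) {
  check_positive(kd, "kd", scalar = FALSE)
  log(2) / kd
}

#' Decimal-reduction time (D-value)
#'
#' Time for residual activity to fall to 10 % of its initial value:
#' `D = ln(10) / kd`. For any first-order process
#' `D = log2(10) * t1/2` (about 3.3219 half-lives).
#'
#' @inheritParams half_life
#' @return D-value in minutes (vectorized).
#' @examples
#' d_value(log(2) / 182)  # about 605 min
#' @export
d_value <- function(kd) {
  check_positive(kd, "kd", scalar = FALSE)
  log(10) / kd
}

#' Check a printed half-life / D-value pair for internal consistency
#'
#' Under first-order kinetics the two values are locked together:
#' `D = log2(10) * t1/2`. Published summary tables sometimes round an
#' unprinted kd before deriving each quantity, leaving pairs that
#' disagree by a few minutes. This checker recomputes the D-value
#' implied by each half-life and flags deviations beyond `tol_min`.
#'
#' @param half_life_min half-life values in minutes (> 0).
#' @param d_value_min the paired D-values in minutes (> 0).
#' @param tol_min flag deviations larger than this many minutes
#'   (default 2).
#' @return a [tibble::tibble] with columns `half_life_min`,
#'   `d_value_min`, `expected_d_min` (= `log2(10) * t1/2`),
#'   `deviation_min` and logical `consistent`.
#' @examples
#' check_kinetic_pair(c(238, 182), c(793, 605))
#' @export
check_kinetic_pair <- function(half_life_min, d_value_min, tol_min = 2) {
  check_positive(half_life_min, "half_life_min", scalar = FALSE)
  check_positive(d_value_min, "d_value_min", scalar = FALSE)
  check_positive(tol_min, "tol_min")
  if (length(half_life_min) != length(d_value_min)) {
    stop("`half_life_min` and `d_value_min` lengths differ", call. = FALSE)
  }
  expected <- log2(10) * half_life_min
  dev <- d_value_min - expected
  tibble::tibble(
    half_life_min = half_life_min,
    d_value_min = d_value_min,
    expected_d_min = expected,
    deviation_min = dev,
    consistent = abs(dev) <= tol_min
  )
}

#' Fit inactivation kinetics across temperatures and forms
#'
#' Runs [fit_first_order_decay()] on each (form, temperature) series of
#' a long-format stability table and collects kd with its derived
#' half-life and D-value.
#'
#' @param stability a data frame with columns `form` (`"free"` /
#'   `"immobilized"`), `temperature_C`, `time_min`, `residual_pct`.
#' @return a [tibble::tibble] with one row per (form, temperature):
#'   `form`, `temperature_C`, `kd`, `r_squared`, `half_life_min`,
#'   `d_value_min`, `n_points`, ordered by form then temperature. Empty
#'   input yields an empty table with a warning. A series whose fit
#'   fails raises an error naming the series.
#' @examples
#' sim <- simulate_thermal_series(kd = c(`50` = 0.002, `55` = 0.003),
#'                                times_min = c(0, 15, 30, 45, 60))
#' summarize_inactivation(sim)
#' @export
summarize_inactivation <- function(stability) {
  cols <- c("form", "temperature_C", "time_min", "residual_pct")
  if (!is.data.frame(stability) || !all(cols %in% names(stability))) {
    stop("`stability` must have columns form, temperature_C, time_min, residual_pct",
         call. = FALSE)
  }
  if (nrow(stability) == 0L) {
    warning("empty stability table; returning empty summary", call. = FALSE)
    return(tibble::tibble(
      form = character(), temperature_C = numeric(), kd = numeric(),
      r_squared = numeric(), half_life_min = numeric(),
      d_value_min = numeric(), n_points = integer()
    ))
  }
  keys <- unique(stability[order(stability$form, stability$temperature_C),
                           c("form", "temperature_C")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- stability$form == keys$form[i] &
      stability$temperature_C == keys$temperature_C[i]
    sub <- stability[sel, ]
    if (anyDuplicated(sub$time_min)) {
      # replicate observations: average residuals per time before fitting
      agg <- stats::aggregate(residual_pct ~ time_min, data = sub, FUN = mean)
      sub <- agg
    }
    sub <- sub[order(sub$time_min), ]
    fit <- tryCatch(
      fit_first_order_decay(sub$time_min, sub$residual_pct),
      error = function(e) {
        stop(sprintf("series form=%s temperature=%s degC: %s",
                     keys$form[i], keys$temperature_C[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
    tibble::tibble(
      form = keys$form[i], temperature_C = keys$temperature_C[i],
      kd = fit$kd, r_squared = fit$r_squared,
      half_life_min = fit$half_life_min, d_value_min = fit$d_value_min,
      n_points = fit$n_points
    )
  })
  do.call(rbind, rows)
}
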