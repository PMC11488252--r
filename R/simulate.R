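#' Simulate residual-activity time courses under first-order decay
#'
#' Generates the stability tables the fitting stages consume:
#' `residual(t) = 100 * exp(-kd * t)` at each temperature, with the
#' rate constant either given explicitly per temperature or derived
#' from an Arrhenius law `kd(T) = A * exp(-E / (R * T))`. Optional
#' measurement noise is applied per observation:
#'
#' * `"none"` — exact exponential decay;
#' * `"lognormal"` — multiplicative, `residual * exp(N(0, sd))`; the
#'   default error model for positive activity measurements, preserves
#'   positivity;
#' * `"gaussian"` — additive in percent units; values driven <= 0 are
#'   floored at a small positive epsilon and flagged via the
#'   `floored` column.
#'
#' Output is deterministic for a fixed (`seed`, configuration) pair;
#' the global RNG state is left untouched.
#'
#' @param kd named numeric vector of rate constants (min^-1); names are
#'   temperatures in degC. Mutually exclusive with `A`/`E_kJ_mol`.
#' @param A pre-exponential factor (min^-1) of an Arrhenius law.
#' @param E_kJ_mol energy (kJ/mol) of the Arrhenius law.
#' @param temperatures_C temperatures at which to evaluate the
#'   Arrhenius law (required with `A`/`E_kJ_mol`); default 25-60 degC
#'   in 5 degC steps, mirroring a typical preheating design.
#' @param times_min sampling times in minutes, strictly increasing,
#'   >= 0; default `c(0, 15, 30, 45, 60)`.
#' @param noise one of `"none"`, `"lognormal"`, `"gaussian"`.
#' @param noise_sd noise magnitude: ln-scale sd for lognormal, percent
#'   units for gaussian; >= 0.
#' @param n_replicates replicate series per temperature (>= 1).
#' @param form label carried into the output (`"free"` or
#'   `"immobilized"`).
#' @param seed integer seed; required whenever noise is generated.
#' @return a [tibble::tibble] with columns `form`, `temperature_C`,
#'   `replicate`, `time_min`, `residual_pct`, `floored`, and attribute
#'   `true_kd` (named by temperature).
#' @examples
#' simulate_thermal_series(kd = c(`50` = 0.01), times_min = c(0, 30, 60))
#' @export
simulate_thermal_series <- function(kd = NULL, A = NULL, E_kJ_mol = NULL,
                                    temperatures_C = seq(25, 60, by = 5),
                                    times_min = c(0, 15, 30, 45, 60),
                                    noise = c("none", "lognormal", "gaussian"),
                                    noise_sd = 0, n_replicates = 1L,
                                    form = "free", seed = NULL) {
  noise <- match.arg(noise)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (any(times_min < 0) || is.unsorted(times_min, strictly = TRUE)) {
    stop("`times_min` must be >= 0 and strictly increasing", call. = FALSE)
  }

  if (is.null(kd)) {
    if (is.null(A) || is.null(E_kJ_mol)) {
      stop("supply either `kd` or both `A` and `E_kJ_mol`", call. = FALSE)
    }
    check_positive(A, "A")
    check_positive(E_kJ_mol, "E_kJ_mol")
    kd <- arrhenius_kd(A, E_kJ_mol, temperatures_C)
  } else {
    if (!is.null(A) || !is.null(E_kJ_mol)) {
      stop("supply either `kd` or an Arrhenius law, not both", call. = FALSE)
    }
    check_positive(kd, "kd", scalar = FALSE)
    if (is.null(names(kd))) {
      stop("`kd` must be named by temperature in degC", call. = FALSE)
    }
  }
  temps <- as.numeric(names(kd))

  grid <- expand.grid(time_min = times_min,
                      replicate = seq_len(n_replicates),
                      temperature_C = temps,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$temperature_C, grid$replicate, grid$time_min), ]
  clean <- 100 * exp(-kd[as.character(grid$temperature_C)] * grid$time_min)

  noisy <- apply_noise(clean, noise, noise_sd, seed)
  floored <- rep(FALSE, length(noisy))
  if (noise == "gaussian") {
    bad <- noisy <= 0
    noisy[bad] <- 1e-6
    floored <- bad
  }

  out <- tibble::tibble(
    form = form,
    temperature_C = grid$temperature_C,
    replicate = as.integer(grid$replicate),
    time_min = grid$time_min,
    residual_pct = unname(noisy),
    floored = floored
  )
  attr(out, "true_kd") <- kd
  out
}

# kd(T) from an Arrhenius law; E in kJ/mol, T in degC.
arrhenius_kd <- function(A, E_kJ_mol, temperatures_C) {
  T_K <- celsius_to_kelvin(temperatures_C)
  kd <- A * exp(-E_kJ_mol * 1000 / (GAS_CONSTANT * T_K))
  names(kd) <- temperatures_C
  kd
}

# Draw noise without touching the caller's RNG state.
apply_noise <- function(clean, noise, noise_sd, seed) {
  if (noise == "none" || noise_sd == 0) return(clean)
  if (is.null(seed)) {
    stop("`seed` is required when generating noise", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    switch(noise,
      lognormal = clean * exp(stats::rnorm(length(clean), 0, noise_sd)),
      gaussian = clean + stats::rnorm(length(clean), 0, noise_sd)
    )
  })
}

#' Simulate a reuse-cycle production series
#'
#' Emulates the operational-stability pattern of an immobilized
#' biocatalyst: full production for a plateau of cycles, then geometric
#' decline at a fixed per-cycle fraction (e.g. progressive gelation or
#' fouling of the beads).
#'
#' @param initial cycle-1 production (SU/ml, > 0).
#' @param plateau_cycles number of cycles at full production (>= 0).
#' @param per_cycle_decline fractional loss per cycle after the plateau,
#'   in \[0, 1).
#' @param n_cycles total number of cycles (>= 1).
#' @param noise_sd ln-scale sd of multiplicative lognormal noise
#'   (0 = noiseless).
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return a [tibble::tibble] as returned by [reuse_retention()], with
#'   retention computed on the (possibly noisy) productions.
#' @examples
#' simulate_reuse_series(2400, plateau_cycles = 5,
#'                       per_cycle_decline = 0.077, n_cycles = 10)
#' @export
simulate_reuse_series <- function(initial, plateau_cycles,
                                  per_cycle_decline, n_cycles,
                                  noise_sd = 0, seed = NULL) {
  check_positive(initial, "initial")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (plateau_cycles < 0) stop("`plateau_cycles` must be >= 0", call. = FALSE)
  if (n_cycles < 1L) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (!is.numeric(per_cycle_decline) || per_cycle_decline < 0 ||
      per_cycle_decline >= 1) {
    stop("`per_cycle_decline` must be in [0, 1)", call. = FALSE)
  }
  cycle <- seq_len(n_cycles)
  decayed <- pmax(cycle - plateau_cycles, 0)
  production <- initial * (1 - per_cycle_decline)^decayed
  production <- apply_noise(production,
                            if (noise_sd > 0) "lognormal" else "none",
                            noise_sd, seed)
  reuse_retention(unname(production), cycle)
}

#' Simulate clotting-time assays from a known activity
#'
#' Inverts the Soxhlet-unit formula: a preparation of true activity
#' `SU` measured at dilution `D` clots in `T = 24000 * D / SU` seconds
#' (standard 5 ml milk / 0.5 ml enzyme assay). Optional multiplicative
#' lognormal noise models timing error; [soxhlet_units()] on the
#' noiseless output recovers the true activity exactly.
#'
#' @param true_su_per_ml true activity (SU/ml, > 0).
#' @param dilutions dilution factors (>= 1).
#' @param noise_sd ln-scale sd of multiplicative noise on the clotting
#'   time (0 = noiseless).
#' @param seed integer seed; required when `noise_sd > 0`.
#' @return a [tibble::tibble] with columns `dilution`,
#'   `clotting_time_s`, `su_per_ml` (activity recomputed from the
#'   simulated time).
#' @examples
#' simulate_clotting_times(2400, dilutions = 1)  # T = 10 s
#' @export
simulate_clotting_times <- function(true_su_per_ml, dilutions = 1,
                                    noise_sd = 0, seed = NULL) {
  check_positive(true_su_per_ml, "true_su_per_ml")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (any(dilutions < 1)) stop("`dilutions` must be >= 1", call. = FALSE)
  t_clean <- 24000 * dilutions / true_su_per_ml
  t_obs <- apply_noise(t_clean,
                       if (noise_sd > 0) "lognormal" else "none",
                       noise_sd, seed)
  tibble::tibble(
    dilution = dilutions,
    clotting_time_s = unname(t_obs),
    su_per_ml = soxhlet_units(unname(t_obs), dilutions)
  )
}
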