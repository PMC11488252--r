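# Independent least-squares oracle: solves the 2x2 normal equations
# directly, no lm(), no shared code with the fitting routines.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  sst <- sum((y - sy / n)^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - yhat)^2) / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Decay-fit oracle built on the normal equations.
decay_oracle <- function(time_min, residual_pct) {
  ols_oracle(time_min, log(residual_pct / 100))
}

# Arrhenius oracle: energy in kJ/mol from the normal-equation slope.
arrhenius_oracle <- function(temperature_K, response) {
  fit <- ols_oracle(1 / temperature_K, log(response))
  c(fit, list(energy_kJ_mol = -fit$slope * 8.314 / 1000))
}
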