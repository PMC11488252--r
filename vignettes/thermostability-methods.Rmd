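---
title: "Methods: clotting-assay statistics, inactivation kinetics and Arrhenius energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clotting-assay statistics, inactivation kinetics and Arrhenius energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoclot)
```

## Scope

`thermoclot` implements the computational chain used to characterize a
microbial milk-clotting enzyme produced by free versus
calcium-alginate-immobilized whole cells: the Soxhlet-unit clotting
statistic, relative-activity profiles with optimum selection, MCA/PA
ratios, leakage and reuse-retention metrics, first-order thermal
inactivation fitting, and Arrhenius estimation of activation and
deactivation energies. A synthetic-data layer generates every input the
pipeline consumes, so each stage is validated by parameter recovery
rather than by comparison to an external data deposit.

## The Soxhlet-unit statistic

One Soxhlet unit (SU) is the amount of enzyme that clots 1 ml of
standard skim-milk/CaCl~2~ solution in 40 min (2400 s) at 35 °C. In the
standard assay, 0.5 ml of (possibly diluted) enzyme preparation is
added to 5 ml of milk and the clotting time $T$ (s) is recorded. The
activity is

$$\mathrm{SU/ml} = \frac{2400 \times 5 \times D}{T \times 0.5} = \frac{24000\,D}{T},$$

where $D$ is the dilution factor. The formula is commonly typeset as
the one-liner "2400 × 5 × D/T × 0.5", which read literally
left-to-right gives $6000\,D/T$ and fails the unit definition: 0.5 ml
of a preparation holding 5 SU must clot the 5 ml of milk in exactly
40 min, i.e. read 10 SU/ml at $T = 2400$ s, $D = 1$. `soxhlet_units()`
therefore uses the grouping above, which satisfies that definitional
check; the identity $\mathrm{SU} \cdot T / D = 24000$ holds for all
valid inputs at default volumes.

Related assay-level statistics follow the field's conventions:
`mca_pa_ratio()` is the plain quotient of clotting to protease
activity (high values favour cheese making, since excess proteolysis
digests the curd); `leakage_percent()` is
$100 - 100\,\mathrm{OD_{imm}}/\mathrm{OD_{free}}$, with negative
values — possible under measurement noise when the immobilized
filtrate is denser than the free control — returned as-is with an
`out_of_range` flag rather than clamped or rejected;
`reuse_retention()` expresses per-cycle production as a percentage of
cycle 1. Ratios and SU values are conventionally reported to the
nearest integer; full precision is kept internally and rounding is left
to the caller.

## Relative-activity profiles and the optimum

`normalize_profile()` rescales activity across a swept condition
(temperature, pH, carbon/nitrogen source, metal ion) so the maximum is
exactly 100 %. Ties are broken by the *first* occurrence of the
maximum: for a temperature sweep read in increasing order this names
the lower of two equally active temperatures the optimum, the usual
reporting convention. Normalization preserves rank order and is
idempotent. The reported "±" spreads of replicate tables are stored
verbatim as text (their printed notation, e.g. `"086"`, is ambiguous)
and are never propagated through computations.

## First-order thermal inactivation

Irreversible thermal denaturation is modelled as first-order loss of
activity, $A(t) = A_0 e^{-k_d t}$. `fit_first_order_decay()` estimates
the deactivation rate constant $k_d$ (min⁻¹) by unweighted ordinary
least squares of $\ln(A(t)/100)$ on time, with $k_d = -\text{slope}$.
Numerical choices:

* **Natural logarithm.** A base-10 fit would give the same half-life
  after a slope conversion; the natural log lets the slope feed
  $t_{1/2} = \ln 2 / k_d$ and $D = \ln 10 / k_d$ directly.
* **The time-0 point is a data point.** Residual activity at $t = 0$
  (typically 100 %) enters the regression like any other observation;
  the intercept is estimated, not constrained, so a noisy control does
  not bias the slope.
* **Non-positive residuals** cannot enter the log and are excluded
  with a warning (not an error); at least two usable points are
  required.
* **Non-decaying series** (slope ≥ 0) are flagged via
  `decaying = FALSE` with `kd = NA` instead of reporting a negative
  rate.
* **Unweighted OLS, r² as the sole diagnostic** — matching standard
  practice for these log-linear inactivation plots; r² is computed
  directly from residuals rather than via `summary.lm()`, which warns
  on the numerically perfect fits that noiseless synthetic data
  produce by design.

The derived pair is locked to the rate constant:
$D/t_{1/2} = \ln 10 / \ln 2 = \log_2 10 \approx 3.3219$ for every fit.
Published summary tables sometimes round an unprinted $k_d$ before
deriving each quantity, leaving pairs a few minutes apart;
`check_kinetic_pair()` recomputes the D-value implied by each
half-life and flags deviations beyond a tolerance (default 2 min). On
the bundled thermostability summary it flags two such pairs (free
form at 50 °C: printed 793 min vs. implied 790.6; immobilized at
60 °C: printed 547 vs. implied 544.8).

`summarize_inactivation()` applies the fit per (form, temperature)
series of a long-format stability table; replicate observations at the
same time are averaged before fitting.

## Arrhenius energies

`fit_arrhenius()` regresses $\ln(\text{response})$ on $1/T$ (K⁻¹,
$T = {}^\circ\mathrm{C} + 273.15$) and converts the slope with the gas
constant $R = 8.314$ J K⁻¹ mol⁻¹:

$$E = -\text{slope} \times R / 1000 \quad \text{kJ/mol}.$$

One sign convention serves both modes. In *activation* mode the
response (activity or production below the optimum) rises with
temperature, the slope on the $1/T$ axis is negative, and $E_a > 0$.
In *deactivation* mode the response is $k_d$, which also rises with
temperature, so $-\text{slope} \times R$ is again positive. The two
conventions sometimes quoted ("slope = $-E_a/R$" versus "slope =
$E_d/R$") cannot both yield positive energies for physical data; the
unified convention reports the positive magnitude and flags a negative
energy (`well_posed = FALSE`) instead of silently passing it. The
$1000/T$ plotting axis rescales the slope by exactly 1000
(`slope_per_1000`) and leaves the energy unchanged.

Which temperatures enter an activation-energy fit is genuinely open for
activity–temperature profiles: above the optimum, apparent activity is
dominated by denaturation, not activation. `select_ascending_limb()`
therefore takes the rising limb up to and including the (first-max)
optimum as the default point set; callers can pass any explicit subset
to `fit_arrhenius()` instead. Energies are conventionally reported to
two decimals.

On the bundled thermostability summary, the $k_d$ values implied by the
printed free-form half-lives (238, 182, 133 min at 50/55/60 °C) give
$E_d = 52.06$ kJ/mol and the immobilized triple (216, 192, 164 min)
gives 24.63 kJ/mol. These are the package's own regressions on the
printed half-lives; the underlying per-timepoint activity series behind
published energy figures is typically not printed, so such fits are
anchored to the normal-equation oracle in the test suite rather than to
any externally quoted energy.

## Synthetic data and what passing tests show

The generators emulate the study design, not the biology:

* `simulate_thermal_series()` draws
  $\text{residual}(t) = 100\,e^{-k_d t}$ at each temperature, with
  $k_d$ either given per temperature or derived from an Arrhenius law
  $k_d(T) = A e^{-E/RT}$. Defaults mirror a typical preheating design:
  temperatures 25–60 °C in 5 °C steps, times 0, 15, 30, 45, 60 min.
* Noise is multiplicative lognormal by default
  ($\text{residual} \times e^{N(0,\sigma)}$): activity measurements
  are positive and replicate spreads look proportional rather than
  additive. Additive Gaussian noise is offered for robustness testing;
  values it drives below zero are floored at a small epsilon and
  flagged in the `floored` column.
* `simulate_reuse_series()` holds production constant through a
  plateau and then declines geometrically — the qualitative shape of
  bead reuse (full production for several cycles, then progressive
  loss). With a 5-cycle plateau and 7.7 % loss per cycle, retention at
  cycle 10 is $100 \times 0.923^5 \approx 67$ %.
* `simulate_clotting_times()` inverts the SU formula,
  $T = 24000\,D/\mathrm{SU}$, with optional multiplicative timing
  noise.

All generators take an explicit integer seed, produce byte-identical
output for identical (configuration, seed) pairs, and leave the
caller's RNG stream untouched. None of them model cell growth, bead
mass transfer, leakage dynamics, or the clotting reaction itself, so
recovery tests demonstrate correctness of the estimators under the
stated error model — not that real stability data satisfy first-order
kinetics.

### Recovery-study design

The noisy-recovery benchmark uses $k_d = 0.01$ min⁻¹ sampled at six
equally spaced times over 0–150 min with $\sigma = 0.05$ and 200
replicates. The window covers about two half-lives, the standard
design guidance for estimating an exponential rate: the OLS slope
standard error is $\sigma / \sqrt{S_{tt}}$, so a window short relative
to the half-life (e.g. 60 min against half-lives of 130–240 min)
leaves the median relative error above 10 % for *any* unbiased
estimator, while the two-half-life design brings it near 2.6 %. The
problem sizes throughout the examples and checks (3–8 temperatures,
5–6 timepoints, 200–500 replicates) match those of a realistic bench
study of this kind.

## Bundled reference tables

`fixture_table()` ships small transcribed reference tables from a
characterization of a honey-isolate *Bacillus amyloliquefaciens*
milk-clotting enzyme (screening zones, production optima, pH
stability, the thermostability summary, a reuse series). They are
guarded by checksum tests and used as realistic regression anchors.
Two known internal quirks are preserved rather than repaired: the
rounding-inconsistent (238, 793) and (164, 547) half-life/D pairs
described above, and a duplicated `NaNO3` level in the printed
nitrogen-source list. One further documented oddity: the pH-stability
table's free-form value at pH 8 / 60 min reads 73 % *retained*, while
the accompanying narrative describes a 73 % *loss*; the fixture
transcribes the table.

## Known limitations

* Only the single-exponential model is fitted: no z-value, Weibull, or
  biphasic inactivation, and no decay constants for pH-stability
  series (reported as raw percentages).
* No transition-state thermodynamics (ΔH‡, ΔG‡, ΔS‡) beyond
  $E_a$/$E_d$; no confidence intervals on energies (unweighted OLS
  only, r² as the sole diagnostic).
* The "±" spreads are carried as annotations; no error propagation.
* Activation-energy fits on activity profiles depend on the chosen
  limb; published energy values are generally not reproducible without
  the underlying per-timepoint series, which is why validation here
  rests on parameter recovery and on the regression oracle.
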