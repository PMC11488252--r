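#' Bundled reference tables for a free vs. immobilized milk-clotting study
#'
#' Small reference data sets from a characterization of a honey-isolate
#' *Bacillus amyloliquefaciens* milk-clotting enzyme, produced by free
#' and calcium-alginate-immobilized cells. They exercise every analysis
#' stage on realistic inputs and anchor regression tests. Available ids:
#'
#' * `"screening"` — isolate screening: strain number, clear-zone
#'   diameter (mm) and activity (SU/ml) for the clotting-positive
#'   isolates.
#' * `"parameters"` — production optima: activity (SU/ml) by incubation
#'   time, temperature, carbon source and nitrogen source, for both
#'   forms.
#' * `"ph_stability"` — residual production (%) after holding the cells
#'   at pH 5--9 for 15--60 min.
#' * `"thermo_summary"` — half-life and decimal-reduction time (min) of
#'   the enzyme at 50/55/60 degC for both forms. Note the free-form
#'   pair at 50 degC (238, 793) is not exactly first-order consistent
#'   (793 vs. the implied 790.6 min), a rounding artifact that
#'   [check_kinetic_pair()] is designed to catch.
#' * `"reuse"` — a 10-cycle reuse series with full production through
#'   cycle 5 then geometric decline to 67 % at cycle 10.
#'
#' The `spread` column preserves the reported "+/-" values verbatim as
#' text: their printed notation (e.g. `"086"`) is ambiguous and they
#' are stored, not propagated through any computation.
#'
#' @param id one of `"screening"`, `"parameters"`, `"ph_stability"`,
#'   `"thermo_summary"`, `"reuse"`.
#' @return a [tibble::tibble]; columns depend on `id`.
#' @examples
#' fixture_table("thermo_summary")
#' @export
fixture_table <- function(id = c("screening", "parameters", "ph_stability",
                                 "thermo_summary", "reuse")) {
  id <- match.arg(id)
  switch(id,
    screening = fixture_screening(),
    parameters = fixture_parameters(),
    ph_stability = fixture_ph_stability(),
    thermo_summary = fixture_thermo_summary(),
    reuse = fixture_reuse()
  )
}

fixture_screening <- function() {
  tibble::tibble(
    strain = c(2L, 4L, 5L, 6L, 7L, 11L, 12L, 14L, 15L, 16L, 17L, 18L, 19L, 20L),
    clear_zone_mm = c(25, 14, 13, 12, 13, 20, 12, 32, 11, 17, 12, 15, 13, 18),
    activity = c(2000, 600, 400, 343, 218, 1200, 240, 2400, 110, 750, 480,
                 800, 600, 1200),
    spread = c("086", "066", "055", "076", "006", "086", "086", "006",
               "077", "055", "049", "090", "048", "044")
  )
}

fixture_parameters <- function() {
  block <- function(variable, levels, form, activity, spread) {
    tibble::tibble(variable = variable, level = as.character(levels),
                   form = form, activity = activity, spread = spread)
  }
  inc <- c(6, 12, 24, 36, 48, 50, 62)
  tmp <- seq(25, 60, by = 5)
  carb <- c("lactose", "glucose", "fructose", "mannose", "maltose",
            "sucrose", "starch", "cellulose")
  nitr <- c("peptone", "casein", "gelatin", "NaNO3", "urea",
            "soybean", "KNO3", "NaNO3")
  rbind(
    block("incubation_time_h", inc, "free",
          c(400, 1200, 2400, 2400, 1750, 1000, 300),
          c("026", "022", "043", "023", "055", "065", "045")),
    block("incubation_time_h", inc, "immobilized",
          c(300, 1000, 2400, 2000, 1750, 1200, 800),
          c("007", "065", "046", "096", "034", "081", "082")),
    block("temperature_C", tmp, "free",
          c(400, 1200, 2400, 2400, 2000, 1750, 1200, 800),
          rep("086", 8)),
    block("temperature_C", tmp, "immobilized",
          c(300, 1500, 2400, 1714, 1500, 1000, 800, 400),
          c("086", "010", "20", "090", "20", "099", "076", "086")),
    block("carbon_source", carb, "free",
          c(2400, 2400, 2000, 2181, 2000, 2000, 1714, 1500),
          c("190", "310", "086", "097", "099", "200", "180", "190")),
    block("carbon_source", carb, "immobilized",
          c(2400, 2400, 1714, 1500, 2181, 2000, 1500, 1333),
          c("20", "099", "190", "200", "240", "220", "190", "086")),
    block("nitrogen_source", nitr, "free",
          c(3000, 2400, 2181, 800, 1741, 3000, 1500, 2000),
          c("099", "088", "099", "190", "160", "320", "086", "086")),
    block("nitrogen_source", nitr, "immobilized",
          c(2500, 2400, 1500, 800, 1714, 3000, 1500, 2000),
          c("220", "080", "155", "086", "077", "090", "186", "069"))
  )
}

fixture_ph_stability <- function() {
  grid <- expand.grid(time_min = c(15, 30, 45, 60),
                      ph = 5:9,
                      form = c("free", "immobilized"),
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$form, grid$ph, grid$time_min), ]
  vals_free <- c(100, 100, 100, 100,   # pH 5
                 100, 100, 100, 100,   # pH 6
                 100, 100, 100, 100,   # pH 7
                 100, 95, 86, 73,      # pH 8
                 100, 86, 70, 65)      # pH 9
  vals_imm <- c(100, 100, 100, 100,
                100, 100, 100, 100,
                100, 100, 100, 100,
                100, 100, 100, 95,
                100, 100, 90, 86)
  spread_free <- c("006", "003", "055", "009",
                   "000", "006", "003", "000",
                   "086", "066", "086", "086",
                   "088", "056", "066", "007",
                   "004", "006", "080", "056")
  spread_imm <- c("007", "086", "001", "000",
                  "001", "001", "002", "001",
                  "086", "086", "086", "086",
                  "086", "086", "086", "086",
                  "022", "001", "006", "005")
  tibble::tibble(
    form = grid$form,
    ph = grid$ph,
    time_min = grid$time_min,
    residual_pct = c(vals_free, vals_imm),
    spread = c(spread_free, spread_imm)
  )
}

fixture_thermo_summary <- function() {
  tibble::tibble(
    form = rep(c("free", "immobilized"), each = 3),
    temperature_C = rep(c(50, 55, 60), 2),
    half_life_min = c(238, 182, 133, 216, 192, 164),
    d_value_min = c(793, 605, 442, 718, 638, 547)
  )
}

fixture_reuse <- function() {
  # flat through cycle 5, then 7.7 % geometric loss per cycle:
  # retention at cycle 10 = 100 * 0.923^5 = 67.0 %
  cycle <- 1:10
  production <- 2400 * (1 - 0.077)^pmax(cycle - 5, 0)
  tibble::tibble(cycle = cycle, production = production)
}
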