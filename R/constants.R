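#' Exposure-scenario parameters
#'
#' Constants of the external- and ingestion-dose models with UNSCEAR-style
#' defaults: outdoor occupancy fraction, absorbed-dose to effective-dose
#' conversion, exposure hours per year, mean lifetime, ICRP stochastic risk
#' factor, and ingestion rates for drinking water and cereal grain
#' (guinea corn).
#'
#' @param occupancy Fraction of time spent outdoors, in (0, 1]. Default 0.2.
#' @param dose_conversion Effective-dose per absorbed-dose coefficient, Sv/Gy.
#'   Default 0.7.
#' @param hours_per_year Exposure hours in a year. Default 8760.
#' @param lifetime_y Mean lifetime DL used for lifetime risk, years. Default 70.
#' @param risk_factor Fatal-cancer risk per sievert (ICRP stochastic risk
#'   factor for the public). Default 0.05.
#' @param water_intake_l_d Drinking-water intake, litres per day. Default 2.
#' @param grain_intake_kg_y Per-capita cereal (guinea corn) consumption,
#'   kg per year. Default 24.8.
#'
#' @return A named list of class `exposure_params`.
#' @examples
#' exposure_params()
#' exposure_params(water_intake_l_d = 1) # alternative intake scenario
#' @export
exposure_params <- function(occupancy = 0.2,
                            dose_conversion = 0.7,
                            hours_per_year = 8760,
                            lifetime_y = 70,
                            risk_factor = 0.05,
                            water_intake_l_d = 2,
                            grain_intake_kg_y = 24.8) {
  check_number(occupancy, "occupancy", positive = TRUE)
  if (occupancy > 1) abort("`occupancy` is a fraction of time and must be <= 1.")
  check_number(dose_conversion, "dose_conversion", positive = TRUE)
  check_number(hours_per_year, "hours_per_year", positive = TRUE)
  check_number(lifetime_y, "lifetime_y", positive = TRUE)
  check_number(risk_factor, "risk_factor", positive = TRUE)
  check_number(water_intake_l_d, "water_intake_l_d", positive = TRUE)
  check_number(grain_intake_kg_y, "grain_intake_kg_y", positive = TRUE)
  structure(
    list(
      occupancy = occupancy,
      dose_conversion = dose_conversion,
      hours_per_year = hours_per_year,
      lifetime_y = lifetime_y,
      risk_factor = risk_factor,
      water_intake_l_d = water_intake_l_d,
      grain_intake_kg_y = grain_intake_kg_y
    ),
    class = "exposure_params"
  )
}

#' Absorbed dose-rate coefficients in air
#'
#' nGy/h of outdoor air-kerma rate at 1 m per Bq/kg of each nuclide
#' uniformly distributed in soil (UNSCEAR values).
#'
#' @param K40,U238,Th232 Coefficients in nGy/h per Bq/kg.
#' @return Named numeric vector over the three nuclides.
#' @examples
#' dose_rate_coefficients()
#' @export
dose_rate_coefficients <- function(K40 = 0.0417, U238 = 0.462, Th232 = 0.623) {
  out <- c(K40 = K40, U238 = U238, Th232 = Th232)
  check_number(out, "dose rate coefficients", positive = TRUE)
  out
}

#' Representative level index divisors
#'
#' Bq/kg divisors of the RLI screening index; an index of 1 corresponds to
#' an annual effective dose of about 1 mSv.
#'
#' @param K40,U238,Th232 Divisors in Bq/kg (defaults 1500, 150, 100).
#' @return Named numeric vector over the three nuclides.
#' @export
rli_divisors <- function(K40 = 1500, U238 = 150, Th232 = 100) {
  out <- c(K40 = K40, U238 = U238, Th232 = Th232)
  check_number(out, "RLI divisors", positive = TRUE)
  out
}

#' Ingestion dose coefficients
#'
#' Committed effective dose per unit intake (Sv/Bq) for adults; the Th-232
#' value applies to the thorium decay chain measured through its progeny.
#'
#' @param K40,U238,Th232 Dose coefficients in Sv/Bq.
#' @return Named numeric vector over the three nuclides.
#' @export
dose_coefficients <- function(K40 = 6.2e-9, U238 = 4.5e-8, Th232 = 2.3e-7) {
  out <- c(K40 = K40, U238 = U238, Th232 = Th232)
  check_number(out, "ingestion dose coefficients", positive = TRUE)
  out
}

#' Reference levels for report context
#'
#' World-average activity concentrations and dose benchmarks against which
#' survey results are usually compared: global mean soil activities, the
#' world-average outdoor absorbed dose rate, the outdoor annual effective
#' dose, and recommended ELCR limits for outdoor-external, indoor-external
#' and internal (ingestion) exposure.
#'
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @export
reference_limits <- function() {
  tibble(
    quantity = c(
      "soil_K40_global_mean", "soil_U238_global_mean", "soil_Th232_global_mean",
      "dose_rate_global_mean", "aed_outdoor_limit",
      "elcr_outdoor_limit", "elcr_indoor_limit", "elcr_internal_limit",
      "aed_ingestion_limit"
    ),
    value = c(420, 32, 45, 59, 0.07, 0.29e-3, 1.16e-3, 3.75e-3, 1),
    unit = c(
      "Bq/kg", "Bq/kg", "Bq/kg", "nGy/h", "mSv/y",
      "probability", "probability", "probability", "mSv/y"
    )
  )
}

#' IAEA cereal-grain transfer-factor references
#'
#' Mean soil-to-plant transfer factors for cereal grains from the IAEA
#' handbook of parameter values, used to contextualise measured TFs.
#'
#' @return Named numeric vector over the three nuclides.
#' @export
iaea_cereal_tf <- function() {
  c(K40 = 0.74, U238 = 0.0062, Th232 = 0.0021)
}

#' @export
print.exposure_params <- function(x, ...) {
  cat("Exposure parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}
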