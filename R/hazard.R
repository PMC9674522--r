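#' Outdoor absorbed dose rate in air
#'
#' Air-kerma rate 1 m above ground from the soil activity concentrations,
#' \eqn{D = 0.0417\,C_K + 0.462\,C_U + 0.623\,C_{Th}} nGy/h with the default
#' UNSCEAR coefficients.
#'
#' @param data Data frame of soil samples with columns `K40`, `U238`,
#'   `Th232` (Bq/kg) and, if present, a `medium` column that must be
#'   entirely `"soil"`.
#' @param constants Coefficients from [dose_rate_coefficients()].
#' @return The input as a tibble with a `dose_rate_nGy_h` column added.
#' @examples
#' tibble::tibble(K40 = 509.74, U238 = 12.82, Th232 = 16.63) |>
#'   absorbed_dose_rate()
#' @export
absorbed_dose_rate <- function(data, constants = dose_rate_coefficients()) {
  data <- as_tibble(data)
  check_activity_columns(data, "absorbed_dose_rate")
  if ("medium" %in% names(data)) check_medium(data, "soil", "absorbed_dose_rate")
  dplyr::mutate(
    data,
    dose_rate_nGy_h = constants[["K40"]] * .data$K40 +
      constants[["U238"]] * .data$U238 +
      constants[["Th232"]] * .data$Th232
  )
}

#' Annual effective dose from external exposure
#'
#' Converts an outdoor absorbed dose rate to the annual effective dose of a
#' member of the public:
#' `AED (mSv/y) = D (nGy/h) x hours_per_year x dose_conversion x occupancy x 1e-6`.
#' With the defaults this is exactly 1.2264e-3 mSv/y per nGy/h.
#'
#' @param x Either a numeric vector of dose rates (nGy/h) or a data frame
#'   with a `dose_rate_nGy_h` column.
#' @param params [exposure_params()].
#' @param ... Passed between methods.
#' @return For numeric input, AED in mSv/y; for a data frame, the tibble
#'   with an `aed_external_mSv_y` column added.
#' @examples
#' aed_external(74.18)
#' @export
aed_external <- function(x, params = exposure_params(), ...) {
  UseMethod("aed_external")
}

#' @rdname aed_external
#' @export
aed_external.numeric <- function(x, params = exposure_params(), ...) {
  check_number(x, "dose rate", nonnegative = TRUE)
  x * params$hours_per_year * params$dose_conversion * params$occupancy * 1e-6
}

#' @rdname aed_external
#' @export
aed_external.data.frame <- function(x, params = exposure_params(), ...) {
  x <- as_tibble(x)
  if (!"dose_rate_nGy_h" %in% names(x)) {
    x <- absorbed_dose_rate(x)
  }
  dplyr::mutate(x, aed_external_mSv_y = aed_external(.data$dose_rate_nGy_h, params))
}

#' Representative level index
#'
#' Screening index for soils,
#' \eqn{RLI = C_U/150 + C_{Th}/100 + C_K/1500}; values at or below 1
#' correspond to an annual effective dose of at most about 1 mSv.
#'
#' @inheritParams absorbed_dose_rate
#' @param divisors Divisors from [rli_divisors()].
#' @return The input as a tibble with `rli` and logical
#'   `rli_exceeds_unity` columns added.
#' @examples
#' tibble::tibble(K40 = 647.74, U238 = 43.47, Th232 = 45.61) |> rli()
#' @export
rli <- function(data, divisors = rli_divisors()) {
  data <- as_tibble(data)
  check_activity_columns(data, "rli")
  if ("medium" %in% names(data)) check_medium(data, "soil", "rli")
  dplyr::mutate(
    data,
    rli = .data$U238 / divisors[["U238"]] +
      .data$Th232 / divisors[["Th232"]] +
      .data$K40 / divisors[["K40"]],
    rli_exceeds_unity = .data$rli > 1
  )
}

#' Daily intake of radionuclides from water or food
#'
#' Activity ingested per day for each nuclide: water activity (Bq/L) times
#' the daily water intake, or grain activity (Bq/kg) times the annual grain
#' consumption spread over 365 days.
#'
#' @param data Data frame of water or grain samples with `K40`, `U238`,
#'   `Th232` and a `medium` column of `"water"` or `"grain"`.
#' @param params [exposure_params()].
#' @return The input as a tibble with `intake_K40`, `intake_U238`,
#'   `intake_Th232` columns in Bq/day.
#' @export
daily_intake <- function(data, params = exposure_params()) {
  data <- as_tibble(data)
  check_activity_columns(data, "daily_intake")
  check_medium(data, c("water", "grain"), "daily_intake")
  rate <- ifelse(
    data$medium == "water",
    params$water_intake_l_d,
    params$grain_intake_kg_y / 365
  )
  dplyr::mutate(
    data,
    intake_K40 = .data$K40 * rate,
    intake_U238 = .data$U238 * rate,
    intake_Th232 = .data$Th232 * rate
  )
}

#' Annual effective dose from ingestion
#'
#' Committed effective dose from a year of water or grain consumption,
#' \eqn{AED = 365 \sum_i I_i D_i} summed over the three nuclides, with
#' \eqn{I_i} the daily intake (Bq/d) and \eqn{D_i} the ingestion dose
#' coefficient (Sv/Bq); returned in mSv/y.
#'
#' @inheritParams daily_intake
#' @param coefficients [dose_coefficients()].
#' @return The input as a tibble with the intake columns and
#'   `aed_ingestion_mSv_y` added.
#' @examples
#' tibble::tibble(K40 = 29.86, U238 = 1.00, Th232 = 1.30, medium = "water") |>
#'   aed_ingestion()
#' @export
aed_ingestion <- function(data, params = exposure_params(),
                          coefficients = dose_coefficients()) {
  data <- daily_intake(data, params)
  dplyr::mutate(
    data,
    aed_ingestion_mSv_y = 365 * (
      .data$intake_K40 * coefficients[["K40"]] +
        .data$intake_U238 * coefficients[["U238"]] +
        .data$intake_Th232 * coefficients[["Th232"]]
    ) * 1e3
  )
}

#' Excess lifetime cancer risk
#'
#' `ELCR = AED x DL x RF`: the annual effective dose times the mean
#' lifetime and the stochastic fatal-cancer risk factor. Stored as a pure
#' probability; multiply by 1e3 to express it in the conventional
#' "x 10^-3" reporting units.
#'
#' @param x A numeric vector of annual effective doses in mSv/y, or a data
#'   frame with `aed_external_mSv_y` and/or `aed_ingestion_mSv_y` columns.
#' @param params [exposure_params()].
#' @param ... Passed between methods.
#' @return For numeric input, ELCR as a probability. For a data frame, the
#'   tibble with `elcr_external` / `elcr_ingestion` columns added for each
#'   AED column present.
#' @examples
#' elcr(0.09) * 1e3 # in units of 1e-3
#' @export
elcr <- function(x, params = exposure_params(), ...) {
  UseMethod("elcr")
}

#' @rdname elcr
#' @export
elcr.numeric <- function(x, params = exposure_params(), ...) {
  check_number(x, "AED", nonnegative = TRUE)
  # AED arrives in mSv/y; DL * RF applies to the dose in Sv
  (x * 1e-3) * params$lifetime_y * params$risk_factor
}

#' @rdname elcr
#' @export
elcr.data.frame <- function(x, params = exposure_params(), ...) {
  x <- as_tibble(x)
  has_any <- FALSE
  if ("aed_external_mSv_y" %in% names(x)) {
    x <- dplyr::mutate(x, elcr_external = elcr(.data$aed_external_mSv_y, params))
    has_any <- TRUE
  }
  if ("aed_ingestion_mSv_y" %in% names(x)) {
    x <- dplyr::mutate(x, elcr_ingestion = elcr(.data$aed_ingestion_mSv_y, params))
    has_any <- TRUE
  }
  if (!has_any) {
    abort("`elcr()` needs an `aed_external_mSv_y` or `aed_ingestion_mSv_y` column.")
  }
  x
}

#' Site-level hazard assessment
#'
#' Averages the per-sample activities within each site/medium/basis group
#' and computes every index that applies to the medium: absorbed dose rate,
#' external AED, RLI and external ELCR for soil; ingestion AED and ELCR for
#' water and grain. This is the table-shaped summary a survey report
#' presents per sampled medium.
#'
#' @param data Samples table with columns `site`, `medium` (`soil`, `water`
#'   or `grain`), optionally `basis` (`in_situ` / `lab`), and activities
#'   `K40`, `U238`, `Th232`.
#' @param params [exposure_params()].
#' @param constants [dose_rate_coefficients()].
#' @param divisors [rli_divisors()].
#' @param coefficients [dose_coefficients()].
#' @return A tibble with one row per site x medium x basis: sample count,
#'   mean activities, and columns `dose_rate_nGy_h`, `aed_external_mSv_y`,
#'   `rli`, `elcr_external`, `aed_ingestion_mSv_y`, `elcr_ingestion` (NA
#'   where not applicable), plus `elcr_total = ELCR` of the applicable
#'   pathway in units of 1e-3 under `elcr_x1e3`.
#' @export
assess_site <- function(data, params = exposure_params(),
                        constants = dose_rate_coefficients(),
                        divisors = rli_divisors(),
                        coefficients = dose_coefficients()) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("`data` has no samples.")
  check_activity_columns(data, "assess_site")
  check_medium(data, c("soil", "water", "grain"), "assess_site")
  if (!"site" %in% names(data)) data$site <- "site"
  if (!"basis" %in% names(data)) data$basis <- NA_character_

  means <- data |>
    dplyr::group_by(.data$site, .data$medium, .data$basis) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(the_nuclides), mean),
      .groups = "drop"
    )

  per_row <- function(df) {
    if (df$medium[[1]] == "soil") {
      df |>
        absorbed_dose_rate(constants) |>
        aed_external(params) |>
        rli(divisors) |>
        elcr(params) |>
        dplyr::mutate(aed_ingestion_mSv_y = NA_real_, elcr_ingestion = NA_real_)
    } else {
      df |>
        aed_ingestion(params, coefficients) |>
        elcr(params) |>
        dplyr::mutate(
          dose_rate_nGy_h = NA_real_, aed_external_mSv_y = NA_real_,
          rli = NA_real_, rli_exceeds_unity = NA, elcr_external = NA_real_
        ) |>
        dplyr::select(-dplyr::starts_with("intake_"))
    }
  }

  out <- means |>
    dplyr::group_split(dplyr::row_number(), .keep = FALSE) |>
    purrr::map(per_row) |>
    purrr::list_rbind()

  out |>
    dplyr::mutate(
      elcr_x1e3 = 1e3 * dplyr::coalesce(.data$elcr_external, .data$elcr_ingestion)
    ) |>
    dplyr::select(
      "site", "medium", "basis", "n", dplyr::all_of(the_nuclides),
      "dose_rate_nGy_h", "aed_external_mSv_y", "rli", "rli_exceeds_unity",
      "elcr_external", "aed_ingestion_mSv_y", "elcr_ingestion", "elcr_x1e3"
    )
}
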