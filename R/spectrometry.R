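#' Indicator gamma lines for K-40, U-238 and Th-232
#'
#' Default map from each quantified nuclide to the photopeaks used as its
#' indicators under secular equilibrium: Th-232 through Tl-208 (2614.7 keV)
#' and Ac-228 (911.21 keV); U-238 through Bi-214 (609.31, 1764.5 keV) and
#' Pb-214 (295.21, 351.92 keV); K-40 directly at 1460 keV.
#'
#' Emission probabilities are standard nuclear-data values per decay of the
#' chain parent (the Tl-208 line folds in the 36% Bi-212 alpha branching).
#'
#' @return A tibble with columns `nuclide`, `emitter`, `line_keV`,
#'   `emission_prob`.
#' @export
line_map <- function() {
  tibble(
    nuclide = c("K40", "U238", "U238", "U238", "U238", "Th232", "Th232"),
    emitter = c("K-40", "Pb-214", "Pb-214", "Bi-214", "Bi-214", "Ac-228", "Tl-208"),
    line_keV = c(1460.8, 295.21, 351.92, 609.31, 1764.5, 911.21, 2614.7),
    emission_prob = c(0.1066, 0.184, 0.356, 0.455, 0.153, 0.262, 0.358)
  )
}

#' Full-energy peak efficiency
#'
#' Efficiency of the detector at a photopeak, from counting a source of
#' known activity: the net peak counts divided by the number of gammas
#' emitted during the acquisition,
#' \eqn{\varepsilon = C_{net} / (A \, P_\gamma \, T)}.
#'
#' @param net_counts Net photopeak counts (background subtracted), >= 0.
#' @param activity Source activity in Bq, > 0.
#' @param emission_prob Absolute gamma emission probability in (0, 1].
#' @param live_time Acquisition live time in seconds, > 0.
#' @return Dimensionless efficiency (vectorised).
#' @examples
#' efficiency(25000, activity = 100, emission_prob = 0.5, live_time = 1000)
#' @export
efficiency <- function(net_counts, activity, emission_prob, live_time) {
  check_number(net_counts, "net_counts", nonnegative = TRUE)
  check_number(activity, "activity", positive = TRUE)
  check_number(emission_prob, "emission_prob", positive = TRUE)
  if (any(emission_prob > 1)) abort("`emission_prob` must be <= 1.")
  check_number(live_time, "live_time", positive = TRUE)
  net_counts / (activity * emission_prob * live_time)
}

#' Activity concentration from a photopeak
#'
#' Converts net photopeak counts to activity concentration,
#' \eqn{A = C_{net} / (\gamma \, \varepsilon(E_\gamma) \, T \, M_s)},
#' in Bq/kg for a sample of mass `mass_kg` (use the aliquot volume in litres
#' for water to obtain Bq/L). `net_counts` are counts, not a rate: dividing
#' by the live time here is what turns them into decays per second.
#'
#' @param net_counts Net photopeak counts, >= 0.
#' @param emission_prob Absolute gamma emission probability in (0, 1].
#' @param efficiency Full-energy peak efficiency in (0, 1].
#' @param live_time Live time in seconds, > 0.
#' @param mass_kg Sample mass in kg (or volume in L for water), > 0.
#' @return Activity concentration (vectorised), Bq/kg or Bq/L.
#' @examples
#' activity_concentration(9000,
#'   emission_prob = 0.5, efficiency = 0.1,
#'   live_time = 18000, mass_kg = 0.5
#' )
#' @export
activity_concentration <- function(net_counts, emission_prob, efficiency,
                                   live_time, mass_kg) {
  check_number(net_counts, "net_counts", nonnegative = TRUE)
  check_number(emission_prob, "emission_prob", positive = TRUE)
  check_number(efficiency, "efficiency", positive = TRUE)
  if (any(emission_prob > 1) || any(efficiency > 1)) {
    abort("`emission_prob` and `efficiency` are fractions and must be <= 1.")
  }
  check_number(live_time, "live_time", positive = TRUE)
  check_number(mass_kg, "mass_kg", positive = TRUE)
  net_counts / (emission_prob * efficiency * live_time * mass_kg)
}

#' Currie minimum detectable activity
#'
#' Detection limit of the counting system for a photopeak, from the Currie
#' formula at 95% confidence:
#' \eqn{MDA = (2.71 + 4.65\sqrt{B}) / (\gamma \, \varepsilon \, T \, M_s)}
#' where B are the background counts in the peak region.
#'
#' @param background_counts Background counts in the peak window, >= 0.
#' @inheritParams activity_concentration
#' @return MDA in Bq/kg (vectorised), monotone non-decreasing in background.
#' @export
detection_limit <- function(background_counts, emission_prob, efficiency,
                            live_time, mass_kg) {
  check_number(background_counts, "background_counts", nonnegative = TRUE)
  check_number(emission_prob, "emission_prob", positive = TRUE)
  check_number(efficiency, "efficiency", positive = TRUE)
  check_number(live_time, "live_time", positive = TRUE)
  check_number(mass_kg, "mass_kg", positive = TRUE)
  (2.71 + 4.65 * sqrt(background_counts)) /
    (emission_prob * efficiency * live_time * mass_kg)
}

#' Reduce a peak table to per-line activities
#'
#' Takes a table of photopeak measurements (one row per sample x gamma
#' line), subtracts background, clamps negative net counts at zero with a
#' warning, and attaches the per-line activity concentration and Currie MDA.
#'
#' @param peaks Data frame with columns `sample_id`, `nuclide`, `line_keV`,
#'   `gross_counts`, `background_counts`, `live_time_s`, `emission_prob`,
#'   `efficiency`, `mass_kg`.
#' @return The input as a tibble with `net_counts`, `activity_Bq_kg` and
#'   `mda_Bq_kg` columns added.
#' @export
reduce_peaks <- function(peaks) {
  peaks <- as_tibble(peaks)
  needed <- c(
    "sample_id", "nuclide", "line_keV", "gross_counts", "background_counts",
    "live_time_s", "emission_prob", "efficiency", "mass_kg"
  )
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("`peaks` is missing columns: ", paste(missing, collapse = ", ")))
  }
  check_number(peaks$gross_counts, "gross_counts", nonnegative = TRUE)
  check_number(peaks$background_counts, "background_counts", nonnegative = TRUE)
  net <- peaks$gross_counts - peaks$background_counts
  n_neg <- sum(net < 0)
  if (n_neg > 0) {
    warn(sprintf(
      "%d peak(s) had negative net counts after background subtraction; clamped to 0.",
      n_neg
    ))
    net <- pmax(net, 0)
  }
  dplyr::mutate(
    peaks,
    net_counts = net,
    activity_Bq_kg = activity_concentration(
      net, peaks$emission_prob, peaks$efficiency, peaks$live_time_s, peaks$mass_kg
    ),
    mda_Bq_kg = detection_limit(
      peaks$background_counts, peaks$emission_prob, peaks$efficiency,
      peaks$live_time_s, peaks$mass_kg
    )
  )
}

#' Combine per-line activities into per-nuclide activities
#'
#' Nuclides quantified through several progeny lines (U-238, Th-232) get one
#' activity per sample by combining their per-line estimates: an unweighted
#' arithmetic mean by default, or an inverse-variance weighted mean using
#' Poisson counting variances when `method = "inverse_variance"`.
#'
#' @param peaks A peak table as accepted by [reduce_peaks()]; it is reduced
#'   first if the `activity_Bq_kg` column is absent.
#' @param method Combination rule for multi-line nuclides.
#' @return A tibble with one row per `sample_id` x `nuclide`:
#'   `activity_Bq_kg`, `se_Bq_kg` (Poisson), `n_lines`, `mda_Bq_kg` (max of
#'   the line MDAs).
#' @export
nuclide_activities <- function(peaks, method = c("mean", "inverse_variance")) {
  method <- match.arg(method)
  if (!"activity_Bq_kg" %in% names(peaks)) peaks <- reduce_peaks(peaks)
  if (nrow(peaks) == 0) abort("`peaks` has no rows; at least one mapped line is needed.")
  # per-line Poisson variance of the activity: var(net) ~ gross + background
  denom <- with(peaks, emission_prob * efficiency * live_time_s * mass_kg)
  line_var <- (peaks$gross_counts + peaks$background_counts) / denom^2
  peaks$._var <- pmax(line_var, .Machine$double.eps)
  out <- dplyr::group_by(peaks, .data$sample_id, .data$nuclide)
  out <- dplyr::summarise(
    out,
    activity_Bq_kg = if (method == "mean") {
      mean(.data$activity_Bq_kg)
    } else {
      sum(.data$activity_Bq_kg / .data$._var) / sum(1 / .data$._var)
    },
    se_Bq_kg = if (method == "mean") {
      sqrt(sum(.data$._var)) / dplyr::n()
    } else {
      sqrt(1 / sum(1 / .data$._var))
    },
    n_lines = dplyr::n(),
    mda_Bq_kg = max(.data$mda_Bq_kg),
    .groups = "drop"
  )
  out
}

#' Widen per-nuclide activities into a sample activity table
#'
#' @param activities Output of [nuclide_activities()].
#' @param site,medium,basis Metadata recycled onto every sample row.
#' @return A wide tibble with one row per sample and columns `K40`, `U238`,
#'   `Th232` (Bq/kg or Bq/L), ready for the hazard and transfer functions.
#' @export
activities_wide <- function(activities, site = NA_character_,
                            medium = "soil", basis = "lab") {
  if (nrow(activities) == 0) abort("`activities` is empty.")
  wide <- tidyr::pivot_wider(
    dplyr::select(activities, "sample_id", "nuclide", "activity_Bq_kg"),
    names_from = "nuclide", values_from = "activity_Bq_kg"
  )
  dplyr::mutate(wide, site = site, medium = medium, basis = basis,
                .after = "sample_id")
}
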