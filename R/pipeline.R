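#' Read a samples table
#'
#' Reads the canonical samples CSV (`sample_id`, `site`, `medium`, `basis`,
#' `K40`, `U238`, `Th232`, `unit`) and validates its schema.
#'
#' @param path Path to a CSV file.
#' @return A samples tibble.
#' @export
read_samples <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_activity_columns(data, "read_samples")
  check_medium(data, c("soil", "water", "grain"), "read_samples")
  data
}

#' Read a pipeline run configuration
#'
#' Reads a YAML configuration overriding any dose-model constant and the
#' Monte Carlo block. Recognised keys: `params` (fields of
#' [exposure_params()]), `constants`, `divisors`, `coefficients` (named
#' per-nuclide values), `mcs` (`n_trials`, `seed`, `uncertain_factors`,
#' `factor_relative`), `precision`, `seed`.
#'
#' @param path Path to a YAML file (missing file is an error).
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

resolve_config <- function(config = list()) {
  params <- do.call(exposure_params, config$params %||% list())
  constants <- do.call(dose_rate_coefficients, as.list(config$constants %||% list()))
  divisors <- do.call(rli_divisors, as.list(config$divisors %||% list()))
  coefficients <- do.call(dose_coefficients, as.list(config$coefficients %||% list()))
  mcs <- config$mcs %||% list()
  list(
    params = params, constants = constants, divisors = divisors,
    coefficients = coefficients,
    mcs_n_trials = mcs$n_trials %||% 10000,
    mcs_seed = mcs$seed %||% config$seed %||% 1L,
    mcs_uncertain_factors = isTRUE(mcs$uncertain_factors),
    mcs_factor_relative = mcs$factor_relative %||% 0.10,
    precision = config$precision %||% 2
  )
}

#' Run the full survey risk-assessment pipeline
#'
#' Ties the stages together for a samples table: descriptive statistics
#' per site/medium/nuclide, site-level hazard indices, soil-to-plant
#' transfer factors (when grain and soil samples are present), and a Monte
#' Carlo ELCR per site and exposure pathway. Activity inputs for the Monte
#' Carlo stage are symmetric truncated normals at each group's observed
#' mean/SD; exposure factors stay at their point values unless
#' `mcs.uncertain_factors` requests +/-10% triangular spreads.
#'
#' @param samples Samples tibble (see [read_samples()] for the schema).
#' @param config Optional configuration list (see [read_run_config()]).
#' @return An object of class `norm_report`: tibbles `summary`, `hazard`,
#'   `transfer`, `mcs`, plus a `log` of every constant, seed and sample
#'   count actually used.
#' @examples
#' samples <- generate_site(site_profiles(), seed = 1)
#' report <- run_pipeline(samples, config = list(mcs = list(n_trials = 500)))
#' report$hazard
#' @export
run_pipeline <- function(samples, config = list()) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) abort("`samples` has no rows; nothing to assess.")
  cfg <- resolve_config(config)

  summary <- summarize_activities(samples)
  hazard <- assess_site(
    samples,
    params = cfg$params, constants = cfg$constants,
    divisors = cfg$divisors, coefficients = cfg$coefficients
  )
  transfer <- tryCatch(
    transfer_factors(samples),
    error = function(e) tibble()
  )

  pathway_of <- c(
    soil = "external_soil", water = "ingestion_water", grain = "ingestion_grain"
  )
  groups <- summary |>
    dplyr::filter(.data$variable %in% the_nuclides) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("site", "medium", "basis"))))
  keys <- dplyr::group_keys(groups)
  mcs <- purrr::map(seq_len(nrow(keys)), function(i) {
    g <- dplyr::semi_join(
      dplyr::filter(summary, .data$variable %in% the_nuclides),
      keys[i, ],
      by = names(keys)
    )
    acts <- setNames(
      purrr::map(the_nuclides, function(nu) {
        row <- dplyr::filter(g, .data$variable == nu)
        if (row$sd[[1]] == 0) {
          dist_point(row$mean[[1]])
        } else {
          dist_truncnorm_symmetric(row$mean[[1]], row$sd[[1]])
        }
      }),
      the_nuclides
    )
    factor_dist <- function(value) {
      if (cfg$mcs_uncertain_factors) {
        dist_triangular_pm(value, cfg$mcs_factor_relative)
      } else {
        NULL
      }
    }
    cfg_i <- mcs_config(
      activities = acts,
      n_trials = cfg$mcs_n_trials,
      # decorrelate group streams while keeping the run reproducible
      seed = as.integer(cfg$mcs_seed) + i,
      occupancy = factor_dist(cfg$params$occupancy),
      lifetime_y = factor_dist(cfg$params$lifetime_y),
      risk_factor = factor_dist(cfg$params$risk_factor)
    )
    res <- run_mcs(
      cfg_i,
      pathway = pathway_of[[keys$medium[[i]]]],
      params = cfg$params, constants = cfg$constants,
      coefficients = cfg$coefficients
    )
    dplyr::bind_cols(keys[i, ], tidy(res),
                     tibble(deterministic_x1e3 = 1e3 * res$deterministic))
  }) |> purrr::list_rbind()

  structure(
    list(
      summary = summary,
      hazard = hazard,
      transfer = transfer,
      mcs = mcs,
      log = list(
        n_samples = nrow(samples),
        params = unclass(cfg$params),
        dose_rate_coefficients = as.list(cfg$constants),
        rli_divisors = as.list(cfg$divisors),
        dose_coefficients = as.list(cfg$coefficients),
        mcs_n_trials = cfg$mcs_n_trials,
        mcs_seed = cfg$mcs_seed,
        mcs_uncertain_factors = cfg$mcs_uncertain_factors,
        precision = cfg$precision
      )
    ),
    class = "norm_report"
  )
}

#' @export
print.norm_report <- function(x, ...) {
  cat("NORM survey risk-assessment report\n")
  cat(sprintf(
    "  %d samples, MCS %d trials (seed %s)\n",
    x$log$n_samples, x$log$mcs_n_trials, x$log$mcs_seed
  ))
  cat("\nHazard indices (rounded):\n")
  print(round_report(x$hazard, x$log$precision), n = Inf)
  if (nrow(x$transfer) > 0) {
    cat("\nTransfer factors (rounded):\n")
    print(round_report(x$transfer, x$log$precision), n = Inf)
  }
  cat("\nMonte Carlo ELCR (x 1e-3):\n")
  print(round_report(x$mcs, max(x$log$precision, 3)), n = Inf)
  invisible(x)
}

round_report <- function(tbl, digits) {
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Write a report bundle to disk
#'
#' Writes the rounded report tables as CSV (`summary.csv`, `hazard.csv`,
#' `transfer.csv`, `mcs.csv`) and the complete unrounded results plus the
#' run log as `report.json`. Output is deterministic for a given report
#' object, so identical configuration and seed give byte-identical files.
#'
#' @param report A `norm_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "norm_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digits <- report$log$precision
  readr::write_csv(round_report(report$summary, digits), file.path(dir, "summary.csv"))
  readr::write_csv(round_report(report$hazard, digits), file.path(dir, "hazard.csv"))
  if (nrow(report$transfer) > 0) {
    readr::write_csv(round_report(report$transfer, digits), file.path(dir, "transfer.csv"))
  }
  readr::write_csv(round_report(report$mcs, max(digits, 3)), file.path(dir, "mcs.csv"))
  jsonlite::write_json(
    list(
      summary = report$summary,
      hazard = report$hazard,
      transfer = report$transfer,
      mcs = report$mcs,
      log = report$log
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
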