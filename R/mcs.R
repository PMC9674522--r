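#' Monte Carlo configuration for probabilistic ELCR
#'
#' Bundles the number of trials, the seed and the input-distribution
#' specifications for one exposure pathway. Activities default to point
#' values and are usually given as truncated normals at the site
#' mean/SD; the exposure factors (occupancy, dose conversion, lifetime,
#' risk factor, intake rate) default to their deterministic point values
#' and can be widened (e.g. [dist_triangular_pm()]) to emulate their
#' intrinsic uncertainty.
#'
#' @param activities Named list of [dist_spec]s for `K40`, `U238`, `Th232`.
#'   Bare numbers are promoted to point specs.
#' @param n_trials Number of Monte Carlo trials (default 10000).
#' @param seed Integer seed recorded in, and used by, every run.
#' @param occupancy,dose_conversion,lifetime_y,risk_factor,intake
#'   Optional [dist_spec]s overriding the point defaults taken from
#'   `params` at run time. `intake` is the water intake (L/d) or grain
#'   consumption (kg/y) depending on the pathway.
#' @return An object of class `mcs_config`.
#' @examples
#' cfg <- mcs_config(
#'   activities = list(
#'     K40 = dist_truncnorm_symmetric(412.99, 250.83),
#'     U238 = dist_truncnorm_symmetric(19.83, 17.09),
#'     Th232 = dist_truncnorm_symmetric(20.62, 10.62)
#'   ),
#'   n_trials = 1000, seed = 42
#' )
#' run_mcs(cfg, "external_soil")
#' @export
mcs_config <- function(activities, n_trials = 10000, seed = NULL,
                       occupancy = NULL, dose_conversion = NULL,
                       lifetime_y = NULL, risk_factor = NULL, intake = NULL) {
  if (!is.list(activities) || !all(the_nuclides %in% names(activities))) {
    abort("`activities` must be a named list with K40, U238 and Th232 entries.")
  }
  activities <- purrr::map(activities[the_nuclides], function(a) {
    if (is.numeric(a) && length(a) == 1) a <- dist_point(a)
    if (!inherits(a, "dist_spec")) abort("Each activity must be a dist_spec or a number.")
    a
  })
  check_number(n_trials, "n_trials", positive = TRUE)
  if (n_trials != round(n_trials)) abort("`n_trials` must be a whole number.")
  for (nm in c("occupancy", "dose_conversion", "lifetime_y", "risk_factor", "intake")) {
    v <- get(nm)
    if (!is.null(v) && !inherits(v, "dist_spec")) {
      abort(sprintf("`%s` must be NULL or a dist_spec.", nm))
    }
  }
  structure(
    list(
      activities = activities, n_trials = as.integer(n_trials), seed = seed,
      occupancy = occupancy, dose_conversion = dose_conversion,
      lifetime_y = lifetime_y, risk_factor = risk_factor, intake = intake
    ),
    class = "mcs_config"
  )
}

#' Run a Monte Carlo simulation of the excess lifetime cancer risk
#'
#' Each trial draws every uncertain input from its distribution and
#' evaluates the deterministic dose chain for the pathway: for
#' `external_soil`, activities to absorbed dose rate to external AED to
#' ELCR; for `ingestion_water` / `ingestion_grain`, activities to daily
#' intake to ingestion AED to ELCR. The ELCR sample is summarised by its
#' mean and 5th/95th percentiles (linear-interpolation percentiles).
#'
#' @param config An [mcs_config()].
#' @param pathway One of `"external_soil"`, `"ingestion_water"`,
#'   `"ingestion_grain"`.
#' @param params [exposure_params()] supplying the point values of any
#'   exposure factor without a distribution in `config`.
#' @param constants [dose_rate_coefficients()] (external pathway).
#' @param coefficients [dose_coefficients()] (ingestion pathways).
#' @return An object of class `mcs_result`: pathway, seed, `n_trials`,
#'   `mean`, `p5`, `p95` (pure probabilities), the full `samples` vector,
#'   and the `deterministic` ELCR evaluated at the expectations of the
#'   input distributions.
#' @export
run_mcs <- function(config, pathway = c("external_soil", "ingestion_water",
                                        "ingestion_grain"),
                    params = exposure_params(),
                    constants = dose_rate_coefficients(),
                    coefficients = dose_coefficients()) {
  stopifnot(inherits(config, "mcs_config"))
  pathway <- match.arg(pathway)
  n <- config$n_trials

  factor_spec <- function(spec, default) {
    if (is.null(spec)) dist_point(default) else spec
  }
  default_intake <- if (pathway == "ingestion_water") {
    params$water_intake_l_d
  } else {
    params$grain_intake_kg_y
  }
  specs <- list(
    K40 = config$activities$K40,
    U238 = config$activities$U238,
    Th232 = config$activities$Th232,
    occupancy = factor_spec(config$occupancy, params$occupancy),
    dose_conversion = factor_spec(config$dose_conversion, params$dose_conversion),
    lifetime_y = factor_spec(config$lifetime_y, params$lifetime_y),
    risk_factor = factor_spec(config$risk_factor, params$risk_factor),
    intake = factor_spec(config$intake, default_intake)
  )

  chain <- function(v) {
    # v: named list of equal-length vectors (or scalars) of input values
    if (pathway == "external_soil") {
      d <- constants[["K40"]] * v$K40 + constants[["U238"]] * v$U238 +
        constants[["Th232"]] * v$Th232
      aed <- d * params$hours_per_year * v$dose_conversion * v$occupancy * 1e-6
    } else {
      daily <- if (pathway == "ingestion_water") v$intake else v$intake / 365
      aed <- 365 * (
        v$K40 * daily * coefficients[["K40"]] +
          v$U238 * daily * coefficients[["U238"]] +
          v$Th232 * daily * coefficients[["Th232"]]
      ) * 1e3
    }
    (aed * 1e-3) * v$lifetime_y * v$risk_factor
  }

  run_draws <- function() purrr::map(specs, draw, n = n)
  values <- if (is.null(config$seed)) {
    run_draws()
  } else {
    withr::with_seed(as.integer(config$seed), run_draws())
  }
  samples <- chain(values)
  deterministic <- chain(purrr::map(specs, dist_mean))

  out <- summarize_mcs(samples)
  out$pathway <- pathway
  out$seed <- config$seed
  out$deterministic <- deterministic
  out
}

#' Summarise a Monte Carlo ELCR sample
#'
#' @param samples Non-empty numeric vector of simulated ELCR values.
#' @return An `mcs_result` with `mean`, `p5`, `p95` (linear-interpolation
#'   percentiles), `n_trials` and the sample vector.
#' @examples
#' summarize_mcs(1:100)
#' @export
summarize_mcs <- function(samples) {
  if (length(samples) == 0) abort("`samples` is empty.")
  check_number(samples, "samples")
  q <- unname(quantile(samples, c(0.05, 0.95), type = 7))
  structure(
    list(
      mean = mean(samples), p5 = q[[1]], p95 = q[[2]],
      n_trials = length(samples), samples = samples,
      pathway = NA_character_, seed = NULL, deterministic = NA_real_
    ),
    class = "mcs_result"
  )
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo ELCR (%s, %d trials%s)\n  P5    %.4g\n  mean  %.4g\n  P95   %.4g\n",
    x$pathway %||% "?", x$n_trials,
    if (is.null(x$seed)) "" else sprintf(", seed %s", x$seed),
    x$p5, x$mean, x$p95
  ))
  if (is.finite(x$deterministic)) {
    cat(sprintf("  deterministic %.4g\n", x$deterministic))
  }
  invisible(x)
}

#' Tidiers and plot for Monte Carlo results
#'
#' `tidy()` returns the P5/mean/P95 row in conventional "x 10^-3" reporting
#' units; `glance()` reports run metadata; `autoplot()` draws the ELCR
#' histogram with the percentile band marked.
#'
#' @param x,object An `mcs_result`.
#' @param ... Unused.
#' @export
tidy.mcs_result <- function(x, ...) {
  tibble(
    pathway = x$pathway,
    p5_x1e3 = 1e3 * x$p5,
    mean_x1e3 = 1e3 * x$mean,
    p95_x1e3 = 1e3 * x$p95
  )
}

#' @rdname tidy.mcs_result
#' @export
glance.mcs_result <- function(x, ...) {
  tibble(
    pathway = x$pathway,
    n_trials = x$n_trials,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
    mean = x$mean, p5 = x$p5, p95 = x$p95,
    deterministic = x$deterministic
  )
}

#' @rdname tidy.mcs_result
#' @export
autoplot.mcs_result <- function(object, ...) {
  df <- tibble(elcr_x1e3 = 1e3 * object$samples)
  marks <- tibble(
    stat = c("P5", "mean", "P95"),
    value = 1e3 * c(object$p5, object$mean, object$p95)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$elcr_x1e3)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, linetype = .data$stat),
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = expression(ELCR %*% 10^-3), y = "Trials",
      title = sprintf(
        "Monte Carlo ELCR, %s (%d trials)",
        object$pathway %||% "", object$n_trials
      )
    )
}
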