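#' Point-source energy calibration data
#'
#' Channel/energy pairs from counting a Cs-137 and Co-60 check-source set on
#' the NaI(Tl) spectrometer, used to fit the linear channel-to-energy map.
#'
#' @return A tibble with columns `source`, `channel`, `energy_keV`.
#' @examples
#' fit_energy_calibration(calibration_points())
#' @export
calibration_points <- function() {
  tibble(
    source = c("Cs-137", "Co-60", "Co-60"),
    channel = c(236, 408, 461),
    energy_keV = c(662, 1173, 1332)
  )
}

#' Fit a linear energy calibration
#'
#' Ordinary least-squares fit of gamma-line energy against MCA channel
#' number, `energy = slope * channel + intercept`. NaI(Tl) systems are
#' linear to a good approximation over the terrestrial gamma range, so a
#' straight line with its \eqn{R^2} is the standard calibration model.
#'
#' @param points Data frame with numeric columns `channel` and `energy_keV`
#'   (at least two distinct channels, both positive).
#'
#' @return An object of class `energy_calibration`: a list with `slope`
#'   (keV/channel), `intercept` (keV), `r_squared`, the underlying `lm` fit
#'   and the calibration `points`.
#' @examples
#' cal <- fit_energy_calibration(calibration_points())
#' predict(cal, channel = 408)
#' tidy(cal)
#' @export
fit_energy_calibration <- function(points) {
  points <- as_tibble(points)
  if (!all(c("channel", "energy_keV") %in% names(points))) {
    abort("`points` must have columns `channel` and `energy_keV`.")
  }
  check_number(points$channel, "channel", nonnegative = TRUE)
  check_number(points$energy_keV, "energy_keV", nonnegative = TRUE)
  if (nrow(points) < 2 || length(unique(points$channel)) < 2) {
    abort("Energy calibration needs at least two points with distinct channels.")
  }
  fit <- lm(energy_keV ~ channel, data = points)
  r2 <- summary(fit)$r.squared
  # a saturated 2-point fit has no residual d.f.; R^2 is 1 by construction
  if (is.nan(r2)) r2 <- 1
  slope <- unname(coef(fit)[["channel"]])
  if (slope <= 0) {
    abort("Fitted calibration slope is not positive; check the channel/energy pairs.")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      fit = fit,
      points = points
    ),
    class = "energy_calibration"
  )
}

#' Predict energies from a fitted calibration
#'
#' @param object An `energy_calibration`.
#' @param channel Numeric vector of channel numbers.
#' @param ... Unused.
#' @return Energies in keV.
#' @export
predict.energy_calibration <- function(object, channel, ...) {
  check_number(channel, "channel")
  object$slope * channel + object$intercept
}

#' Invert a calibration: channel at a given energy
#'
#' @param calibration An `energy_calibration`.
#' @param energy_keV Numeric vector of energies in keV.
#' @return Fractional channel positions.
#' @export
channel_of <- function(calibration, energy_keV) {
  stopifnot(inherits(calibration, "energy_calibration"))
  check_number(energy_keV, "energy_keV")
  (energy_keV - calibration$intercept) / calibration$slope
}

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf(
    "Energy calibration: E(keV) = %.4f * channel %+.2f  (R^2 = %.5f, %d points)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$points)
  ))
  invisible(x)
}

#' @rdname fit_energy_calibration
#' @param x An `energy_calibration`.
#' @param ... Unused.
#' @export
tidy.energy_calibration <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    unit = c("keV", "keV/channel")
  )
}

#' @rdname fit_energy_calibration
#' @export
glance.energy_calibration <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    n_points = nrow(x$points),
    sigma_keV = summary(x$fit)$sigma
  )
}

#' @rdname fit_energy_calibration
#' @param object An `energy_calibration`.
#' @export
autoplot.energy_calibration <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$channel, .data$energy_keV)) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      colour = "steelblue"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "MCA channel", y = "Energy (keV)",
      title = "Energy calibration",
      subtitle = sprintf(
        "E = %.3f ch %+.1f keV, R² = %.4f",
        object$slope, object$intercept, object$r_squared
      )
    )
}
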