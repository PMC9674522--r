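#' Input-distribution specifications for Monte Carlo propagation
#'
#' Constructors for the distribution kinds the Monte Carlo engine accepts:
#' a degenerate point value, a normal truncated to an interval (by default
#' at zero, for activity-like quantities that cannot be negative), a
#' triangular distribution, and a uniform distribution.
#'
#' `dist_truncnorm_symmetric()` truncates at `mean +/- min(mean, k * sd)`:
#' the bounds are symmetric about the mean, so the expectation of the draws
#' equals `mean` exactly while staying non-negative.
#'
#' @param value Point value (>= 0 for activity-like quantities).
#' @param mean,sd Location and scale of the parent normal (`sd >= 0`).
#' @param lower,upper Truncation bounds, `lower < upper`.
#' @param min,mode,max Triangular/uniform parameters, `min <= mode <= max`.
#' @param k Half-width of the symmetric truncation in units of `sd`.
#' @param relative Half-width of [dist_triangular_pm()] as a fraction of
#'   the nominal value (default 0.10, i.e. +/-10%).
#' @return An object of class `dist_spec`.
#' @examples
#' draw(dist_truncnorm(20, 17), 5, seed = 1)
#' @name dist_spec
NULL

new_dist_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  check_number(value, "value")
  new_dist_spec("point", value = value)
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, lower = 0, upper = Inf) {
  check_number(mean, "mean")
  check_number(sd, "sd", nonnegative = TRUE)
  if (lower >= upper) abort("`lower` must be below `upper`.")
  new_dist_spec("truncnorm", mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname dist_spec
#' @export
dist_truncnorm_symmetric <- function(mean, sd, k = 3) {
  check_number(mean, "mean", positive = TRUE)
  check_number(sd, "sd", nonnegative = TRUE)
  check_number(k, "k", positive = TRUE)
  half <- min(mean, k * sd)
  if (half == 0) return(dist_point(mean))
  dist_truncnorm(mean, sd, lower = mean - half, upper = mean + half)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max) {
  check_number(c(min, mode, max), "triangular parameters")
  if (!(min <= mode && mode <= max) || min == max) {
    abort("Triangular needs min <= mode <= max with min < max.")
  }
  new_dist_spec("triangular", min = min, mode = mode, max = max)
}

#' @rdname dist_spec
#' @export
dist_triangular_pm <- function(value, relative = 0.10) {
  check_number(value, "value", positive = TRUE)
  check_number(relative, "relative", positive = TRUE)
  dist_triangular(value * (1 - relative), value, value * (1 + relative))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max) {
  check_number(c(min, max), "uniform parameters")
  if (min >= max) abort("Uniform needs min < max.")
  new_dist_spec("uniform", min = min, max = max)
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf(
    "<dist_spec %s: %s>\n", x$kind,
    paste(sprintf("%s=%g", names(pars), unlist(pars)), collapse = ", ")
  ))
  invisible(x)
}

#' Draw random variates from a distribution spec
#'
#' Truncated-normal draws use the inverse-CDF method, so they are exact and
#' reproducible under a seed; a zero-`sd` truncated normal degenerates to
#' its mean.
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws.
#' @param seed Optional integer seed applied locally (the caller's RNG
#'   state is untouched).
#' @return Numeric vector of length `n`.
#' @export
draw <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  check_number(n, "n", positive = TRUE)
  run <- function() {
    switch(spec$kind,
      point = rep(spec$value, n),
      truncnorm = {
        if (spec$sd == 0) {
          rep(spec$mean, n)
        } else {
          plo <- pnorm(spec$lower, spec$mean, spec$sd)
          phi <- pnorm(spec$upper, spec$mean, spec$sd)
          qnorm(runif(n, plo, phi), spec$mean, spec$sd)
        }
      },
      triangular = {
        u <- runif(n)
        a <- spec$min; b <- spec$max; m <- spec$mode
        fc <- (m - a) / (b - a)
        ifelse(
          u < fc,
          a + sqrt(u * (b - a) * (m - a)),
          b - sqrt((1 - u) * (b - a) * (b - m))
        )
      },
      uniform = runif(n, spec$min, spec$max),
      abort(sprintf("Unknown distribution kind '%s'.", spec$kind))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Expectation of a distribution spec
#'
#' Closed-form mean of the spec (truncated normal via the standard
#' truncated-moment formula); used for deterministic baselines.
#'
#' @param spec A [dist_spec].
#' @return The expectation as a scalar.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    point = spec$value,
    truncnorm = {
      if (spec$sd == 0) return(spec$mean)
      a <- (spec$lower - spec$mean) / spec$sd
      b <- (spec$upper - spec$mean) / spec$sd
      z <- pnorm(b) - pnorm(a)
      spec$mean + spec$sd * (dnorm(a) - dnorm(b)) / z
    },
    triangular = (spec$min + spec$mode + spec$max) / 3,
    uniform = (spec$min + spec$max) / 2
  )
}
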