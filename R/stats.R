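#' Descriptive summary of one activity series
#'
#' The summary row a survey table reports for each nuclide: minimum,
#' maximum, mean, sample standard deviation (n-1 divisor), coefficient of
#' variation in percent, adjusted Fisher-Pearson skewness and sample excess
#' kurtosis.
#'
#' @param values Numeric vector of activities (or dose rates), length >= 2.
#' @return A one-row tibble with columns `n`, `min`, `max`, `mean`, `sd`,
#'   `cv_pct`, `skewness`, `kurtosis`. `cv_pct` is `NA` when the mean is 0.
#' @examples
#' site_summary(c(1, 2, 3))
#' @export
site_summary <- function(values) {
  check_number(values, "values")
  n <- length(values)
  if (n < 2) abort("At least two values are needed for a site summary.")
  m <- mean(values)
  s <- sd(values)
  constant <- s == 0
  tibble(
    n = n,
    min = min(values),
    max = max(values),
    mean = m,
    sd = s,
    cv_pct = if (m == 0) NA_real_ else 100 * s / m,
    # a constant series has no shape; report 0 rather than 0/0. The adjusted
    # estimators need n >= 3 (skewness) / n >= 4 (kurtosis): NA below that.
    skewness = if (constant) 0 else if (n < 3) NA_real_ else {
      e1071::skewness(values, type = 2)
    },
    kurtosis = if (constant) 0 else if (n < 4) NA_real_ else {
      e1071::kurtosis(values, type = 2)
    }
  )
}

#' Descriptive statistics per site, medium and nuclide
#'
#' Applies [site_summary()] to each activity column within each
#' site/medium/basis group, reproducing the layout of a survey's
#' descriptive-statistics tables.
#'
#' @param data Samples table with `K40`, `U238`, `Th232` columns and any of
#'   `site`, `medium`, `basis` grouping columns.
#' @param cols Columns to summarise (default the three nuclides plus a
#'   `dose_rate_nGy_h` column when present).
#' @return A long tibble: grouping columns, `variable`, and the
#'   [site_summary()] statistics.
#' @export
summarize_activities <- function(data, cols = NULL) {
  data <- as_tibble(data)
  if (is.null(cols)) {
    cols <- intersect(c(the_nuclides, "dose_rate_nGy_h"), names(data))
  }
  if (length(cols) == 0) abort("No activity columns to summarise.")
  groups <- intersect(c("site", "medium", "basis"), names(data))
  long <- tidyr::pivot_longer(
    dplyr::select(data, dplyr::all_of(c(groups, cols))),
    cols = dplyr::all_of(cols), names_to = "variable", values_to = "value"
  )
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "variable")))) |>
    dplyr::group_modify(~ site_summary(.x$value)) |>
    dplyr::ungroup()
}
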