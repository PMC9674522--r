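#' Soil-to-plant transfer factor for one plant/soil pair
#'
#' Dry-weight transfer (bioaccumulation) factor,
#' \eqn{TF = C_{plant} / C_{soil}}, per nuclide. A nuclide with TF < 1 is
#' absorbed but not accumulated by the crop; TF > 1 indicates accumulation.
#'
#' @param plant Named numeric vector or one-row data frame with `K40`,
#'   `U238`, `Th232` grain activities (Bq/kg dry weight).
#' @param soil Same shape, rooting-zone soil activities (Bq/kg). Nuclides
#'   with zero soil activity yield an undefined TF, returned as `NA` with a
#'   warning.
#' @return A tibble with one row per nuclide: `plant_Bq_kg`, `soil_Bq_kg`,
#'   `tf`, `classification` (`"absorbed"` / `"accumulated"`), and the IAEA
#'   cereal-grain reference value for context.
#' @examples
#' transfer_factor(
#'   plant = c(K40 = 105.85, U238 = 2.19, Th232 = 5.22),
#'   soil = c(K40 = 509.74, U238 = 12.82, Th232 = 16.63)
#' )
#' @export
transfer_factor <- function(plant, soil) {
  take <- function(x, what) {
    if (is.data.frame(x)) {
      if (nrow(x) != 1) abort(sprintf("`%s` must be a single activity vector.", what))
      x <- unlist(x[the_nuclides])
    }
    if (!all(the_nuclides %in% names(x))) {
      abort(sprintf("`%s` must name activities K40, U238, Th232.", what))
    }
    out <- as.numeric(x[the_nuclides])
    check_number(out, what, nonnegative = TRUE)
    out
  }
  p <- take(plant, "plant")
  s <- take(soil, "soil")
  tf <- ifelse(s > 0, p / s, NA_real_)
  if (anyNA(tf)) {
    warn(paste(
      "Transfer factor undefined (zero soil activity) for:",
      paste(the_nuclides[is.na(tf)], collapse = ", ")
    ))
  }
  tibble(
    nuclide = the_nuclides,
    plant_Bq_kg = p,
    soil_Bq_kg = s,
    tf = tf,
    classification = dplyr::case_when(
      is.na(tf) ~ NA_character_,
      tf > 1 ~ "accumulated",
      .default = "absorbed"
    ),
    iaea_cereal_reference = unname(iaea_cereal_tf()[the_nuclides])
  )
}

#' Site transfer factors from a samples table
#'
#' Computes per-site transfer factors from the mean grain and mean soil
#' activities of each site (the mean-of-means convention used in survey
#' reports); a matched per-sample-pair mode is available when grain and
#' soil samples share the same rooting zone and sample order.
#'
#' @param data Samples table with `site`, `medium` (must include `grain`
#'   and `soil` rows per site), optionally `basis`, and `K40`, `U238`,
#'   `Th232` columns.
#' @param soil_basis Which soil measurement basis to pair with the grain
#'   samples when a `basis` column is present (default `"lab"`, the
#'   laboratory analyses of the rooting-zone soils).
#' @param mode `"site_mean"` (default) or `"paired"`; paired mode matches
#'   the i-th grain sample with the i-th soil sample within each site and
#'   returns per-pair TFs.
#' @return A tibble of transfer factors per site (and per pair in paired
#'   mode) with the columns of [transfer_factor()].
#' @export
transfer_factors <- function(data, soil_basis = "lab",
                             mode = c("site_mean", "paired")) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  check_activity_columns(data, "transfer_factors")
  check_medium(data, c("soil", "water", "grain"), "transfer_factors")
  if (!"site" %in% names(data)) data$site <- "site"
  soil <- dplyr::filter(data, .data$medium == "soil")
  if ("basis" %in% names(soil) && any(!is.na(soil$basis))) {
    soil <- dplyr::filter(soil, .data$basis == soil_basis)
  }
  grain <- dplyr::filter(data, .data$medium == "grain")
  sites <- intersect(unique(grain$site), unique(soil$site))
  if (length(sites) == 0) {
    abort("No site has both grain and soil samples; cannot compute transfer factors.")
  }

  one_site <- function(s) {
    g <- dplyr::filter(grain, .data$site == s)
    so <- dplyr::filter(soil, .data$site == s)
    if (mode == "site_mean") {
      tf <- transfer_factor(
        colMeans(g[the_nuclides]),
        colMeans(so[the_nuclides])
      )
      dplyr::mutate(tf, site = s, .before = 1)
    } else {
      if (nrow(g) != nrow(so)) {
        abort(sprintf(
          "Paired mode needs equal grain and soil sample counts at site '%s' (%d vs %d).",
          s, nrow(g), nrow(so)
        ))
      }
      purrr::map(seq_len(nrow(g)), function(i) {
        dplyr::mutate(
          transfer_factor(g[i, ], so[i, ]),
          site = s, pair = i, .before = 1
        )
      }) |> purrr::list_rbind()
    }
  }
  purrr::map(sites, one_site) |> purrr::list_rbind()
}
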