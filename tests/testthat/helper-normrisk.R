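# shared fixtures built in code

table2_points <- function() {
  tibble::tibble(channel = c(236, 408, 461), energy_keV = c(662, 1173, 1332))
}

# closed-form least squares, independent of lm()
ols_line <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

soil_means <- function(site_name, basis_name) {
  dplyr::filter(
    site_means(),
    site == site_name, medium == "soil", basis == basis_name
  )
}

medium_means <- function(site_name, medium_name) {
  dplyr::filter(site_means(), site == site_name, medium == medium_name)
}
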