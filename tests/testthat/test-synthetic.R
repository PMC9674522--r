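test_that("degenerate profiles generate constant samples", {
  prof <- tibble::tibble(
    site = "X", medium = "soil", basis = "lab", nuclide = "K40",
    mean = 400, sd = 0, min = 100, max = 900, skewness = 0.5, n_samples = 10
  )
  out <- generate_site(prof, seed = 1)
  expect_equal(out$K40, rep(400, 10))

  prof$min <- prof$max <- prof$mean <- 250
  out2 <- generate_site(prof, seed = 1, bounds = "strict")
  expect_equal(out2$K40, rep(250, 10))
})

test_that("generated samples track the profile moments", {
  prof <- dplyr::filter(
    site_profiles(), site == "Beryllium", medium == "soil", basis == "lab"
  )
  out <- generate_site(prof, seed = 1)
  expect_equal(nrow(out), 24)
  stats <- summarize_activities(out)
  for (nu in c("K40", "U238", "Th232")) {
    target <- dplyr::filter(prof, nuclide == nu)
    got <- dplyr::filter(stats, variable == nu)
    expect_lt(abs(got$mean - target$mean), 0.10 * target$mean)
    expect_lt(abs(got$sd - target$sd), 0.25 * target$sd)
    expect_true(all(out[[nu]] >= 0))
  }
  # skew sign is reproduced where the truncation leaves it attainable:
  # the right-skewed in-situ uranium profile keeps its positive skew
  insitu <- dplyr::filter(
    site_profiles(), site == "Beryllium", basis == "in_situ", nuclide == "U238"
  )
  got_insitu <- summarize_activities(
    generate_site(insitu, seed = 1), cols = "U238"
  )
  expect_gt(got_insitu$skewness, 0)
})

test_that("strict bounds reject infeasible moment targets with a diagnostic", {
  prof <- dplyr::filter(
    site_profiles(), site == "Beryllium", basis == "lab", nuclide == "U238"
  )
  # printed SD exceeds the half-range: impossible on [min, max]
  expect_error(generate_site(prof, seed = 1, bounds = "strict"), "Infeasible")

  feasible <- tibble::tibble(
    site = "X", medium = "soil", basis = "lab", nuclide = "K40",
    mean = 400, sd = 80, min = 100, max = 900, skewness = 0.5, n_samples = 24
  )
  out <- generate_site(feasible, seed = 2, bounds = "strict")
  expect_true(all(out$K40 >= 100 & out$K40 <= 900))
  expect_lt(abs(mean(out$K40) - 400), 40)
})

test_that("the lognormal family is available as an alternative", {
  prof <- tibble::tibble(
    site = "X", medium = "soil", basis = "lab", nuclide = "Th232",
    mean = 20, sd = 10, min = 0, max = Inf, skewness = 0, n_samples = 24
  )
  out <- generate_site(prof, seed = 3, family = "lognormal")
  expect_true(all(out$Th232 > 0))
  expect_lt(abs(mean(out$Th232) - 20), 2)
})

test_that("zero-activity truth produces a background-only spectrum", {
  sp <- generate_spectrum(c(K40 = 0, U238 = 0, Th232 = 0), seed = 5)
  red <- nuclide_activities(reduce_spectrum(sp))
  # net counts fluctuate around zero; activities must sit below the MDA
  expect_true(all(red$activity_Bq_kg <= red$mda_Bq_kg))
  expect_equal(sum(sp$lines$expected_area), 0)
})

test_that("a K-40-only truth puts a single photopeak near channel 504", {
  sp <- generate_spectrum(c(K40 = 600, U238 = 0, Th232 = 0), seed = 6)
  k_line <- dplyr::filter(sp$lines, nuclide == "K40")
  expect_equal(k_line$channel, 504, tolerance = 0.01)
  excess <- sp$counts - sp$background_counts
  peak_ch <- sp$channel[which.max(excess)]
  expect_lt(abs(peak_ch - 504), 15)
  other <- dplyr::filter(sp$lines, nuclide != "K40")
  expect_equal(sum(other$expected_area), 0)
})

test_that("expected peak areas scale linearly with live time", {
  truth <- c(K40 = 400, U238 = 30, Th232 = 25)
  a <- generate_spectrum(truth, live_time = 9000, seed = 7)
  b <- generate_spectrum(truth, live_time = 18000, seed = 7)
  expect_equal(b$lines$expected_area, 2 * a$lines$expected_area)
})

test_that("spectra whose peaks fall off the MCA range are rejected", {
  tight <- fit_energy_calibration(
    tibble::tibble(channel = c(100, 200), energy_keV = c(500, 1000))
  )
  # 2614.7 keV then lands beyond channel 400 of a 400-channel MCA
  expect_error(
    generate_spectrum(
      c(K40 = 100, U238 = 10, Th232 = 10),
      calibration = tight, n_channels = 400
    ),
    "outside the channel range"
  )
})

test_that("spectrum reduction recovers the truth within Poisson uncertainty", {
  truth <- c(K40 = 500, U238 = 40, Th232 = 30)
  red <- nuclide_activities(reduce_spectrum(generate_spectrum(truth, seed = 8)))
  for (nu in names(truth)) {
    row <- dplyr::filter(red, nuclide == nu)
    expect_lt(abs(row$activity_Bq_kg - truth[[nu]]), 3 * row$se_Bq_kg)
  }
})

test_that("synthetic sites propagate to hazard indices near the profile targets", {
  prof <- dplyr::filter(site_profiles(), site == "Gold", medium == "soil")
  targets <- site_means() |>
    dplyr::filter(site == "Gold", medium == "soil") |>
    rli() |>
    aed_external() |>
    elcr()
  for (rep in 1:20) {
    samples <- generate_site(prof, seed = 100 + rep)
    got <- assess_site(samples)
    for (basis_i in c("in_situ", "lab")) {
      g <- dplyr::filter(got, basis == basis_i)
      t <- dplyr::filter(targets, basis == basis_i)
      expect_lt(abs(g$rli - t$rli), 0.15 * t$rli)
      expect_lt(
        abs(g$aed_external_mSv_y - t$aed_external_mSv_y),
        0.15 * t$aed_external_mSv_y
      )
      expect_lt(
        abs(g$elcr_external - t$elcr_external), 0.15 * t$elcr_external
      )
    }
  }
})
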