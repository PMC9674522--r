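test_that("absorbed dose rate is the UNSCEAR linear combination", {
  expect_equal(
    absorbed_dose_rate(tibble::tibble(K40 = 0, U238 = 0, Th232 = 0))$dose_rate_nGy_h,
    0
  )
  # hand arithmetic on the beryllium lab soil means
  d <- absorbed_dose_rate(
    tibble::tibble(K40 = 509.74, U238 = 12.82, Th232 = 16.63)
  )$dose_rate_nGy_h
  expect_equal(d, 0.0417 * 509.74 + 0.462 * 12.82 + 0.623 * 16.63)
  expect_equal(d, 37.54, tolerance = 1e-4)
  expect_equal(
    absorbed_dose_rate(
      tibble::tibble(K40 = 1500, U238 = 150, Th232 = 100)
    )$dose_rate_nGy_h,
    194.15
  )
  expect_error(
    absorbed_dose_rate(tibble::tibble(K40 = 1, U238 = 1, Th232 = 1, medium = "water")),
    "soil"
  )
})

test_that("external AED applies the occupancy-weighted conversion", {
  expect_equal(aed_external(0), 0)
  expect_equal(aed_external(1000), 1.2264)
  # per-unit-dose-rate constant with defaults
  expect_equal(aed_external(1), 8760 * 0.7 * 0.2 * 1e-6)
  expect_equal(round(aed_external(74.18), 2), 0.09)
  expect_error(aed_external(-1), "non-negative")
  df <- tibble::tibble(K40 = 500, U238 = 10, Th232 = 10)
  out <- aed_external(df)
  expect_equal(out$aed_external_mSv_y, out$dose_rate_nGy_h * 1.2264e-3)
})

test_that("representative level index reproduces the published screening values", {
  expect_equal(
    round(rli(tibble::tibble(K40 = 647.74, U238 = 43.47, Th232 = 45.61))$rli, 2),
    1.18
  )
  expect_equal(
    round(rli(tibble::tibble(K40 = 509.74, U238 = 12.82, Th232 = 16.63))$rli, 2),
    0.59
  )
  unity <- rli(tibble::tibble(K40 = 1500, U238 = 150, Th232 = 100))
  expect_equal(unity$rli, 3)
  expect_true(unity$rli_exceeds_unity)
  expect_false(
    rli(tibble::tibble(K40 = 100, U238 = 10, Th232 = 10))$rli_exceeds_unity
  )
})

test_that("daily intake distinguishes water and grain rates", {
  w <- daily_intake(tibble::tibble(K40 = 10, U238 = 0, Th232 = 0, medium = "water"))
  expect_equal(w$intake_K40, 20)
  g <- daily_intake(tibble::tibble(K40 = 179.62, U238 = 0, Th232 = 0, medium = "grain"))
  expect_equal(g$intake_K40, 179.62 * 24.8 / 365, tolerance = 1e-9)
  expect_equal(g$intake_K40, 12.204, tolerance = 1e-4)
  z <- daily_intake(tibble::tibble(K40 = 0, U238 = 0, Th232 = 0, medium = "water"))
  expect_equal(z$intake_K40 + z$intake_U238 + z$intake_Th232, 0)
  expect_error(
    daily_intake(tibble::tibble(K40 = 1, U238 = 1, Th232 = 1, medium = "soil")),
    "water/grain"
  )
})

test_that("ingestion AED reproduces the published worked rows at 2 d.p.", {
  gw <- aed_ingestion(
    tibble::tibble(K40 = 29.86, U238 = 1.00, Th232 = 1.30, medium = "water")
  )
  expect_equal(round(gw$aed_ingestion_mSv_y, 2), 0.39)
  gg <- aed_ingestion(
    tibble::tibble(K40 = 179.62, U238 = 2.19, Th232 = 4.08, medium = "grain")
  )
  expect_equal(round(gg$aed_ingestion_mSv_y, 2), 0.05)
  zero <- aed_ingestion(
    tibble::tibble(K40 = 0, U238 = 0, Th232 = 0, medium = "grain")
  )
  expect_equal(zero$aed_ingestion_mSv_y, 0)
})

test_that("ELCR is AED times lifetime times risk factor", {
  expect_equal(elcr(0), 0)
  expect_equal(1e3 * elcr(0.09), 0.315)
  expect_equal(elcr(1.0), 3.5e-3)
  expect_error(elcr(-0.1), "non-negative")
  # the ratio ELCR/AED is conserved at DL * RF for any input
  set.seed(3)
  aeds <- runif(50, 0, 5)
  expect_equal(elcr(aeds) / (aeds * 1e-3), rep(70 * 0.05, 50))
})

test_that("hazard indices are homogeneous of degree one in the activities", {
  set.seed(4)
  for (i in 1:20) {
    df <- tibble::tibble(
      K40 = runif(1, 0, 1000), U238 = runif(1, 0, 100), Th232 = runif(1, 0, 100)
    )
    k <- runif(1, 0.1, 10)
    scaled <- df * k
    expect_equal(
      absorbed_dose_rate(scaled)$dose_rate_nGy_h,
      k * absorbed_dose_rate(df)$dose_rate_nGy_h
    )
    expect_equal(rli(scaled)$rli, k * rli(df)$rli)
    gw <- function(d) {
      aed_ingestion(dplyr::mutate(d, medium = "water"))$aed_ingestion_mSv_y
    }
    expect_equal(gw(scaled), k * gw(df))
  }
})

test_that("index of the mean equals mean of the per-sample indices", {
  set.seed(5)
  samples <- tibble::tibble(
    K40 = runif(24, 100, 1000), U238 = runif(24, 1, 100), Th232 = runif(24, 1, 80)
  )
  means <- dplyr::summarise(samples, dplyr::across(dplyr::everything(), mean))
  expect_equal(
    absorbed_dose_rate(means)$dose_rate_nGy_h,
    mean(absorbed_dose_rate(samples)$dose_rate_nGy_h)
  )
  expect_equal(rli(means)$rli, mean(rli(samples)$rli))
})

test_that("assess_site produces a complete per-medium report", {
  one <- tibble::tibble(
    site = "A", medium = "soil", basis = "lab",
    K40 = 509.74, U238 = 12.82, Th232 = 16.63
  )
  res <- assess_site(one)
  expect_equal(nrow(res), 1)
  expect_equal(round(res$rli, 2), 0.59)
  expect_equal(res$elcr_x1e3, 1e3 * elcr(res$aed_external_mSv_y))

  water <- tibble::tibble(
    site = "Gold", medium = "water", basis = "lab",
    K40 = 29.86, U238 = 1.00, Th232 = 1.30
  )
  resw <- assess_site(water)
  expect_equal(round(resw$aed_ingestion_mSv_y, 2), 0.39)
  expect_equal(round(resw$elcr_x1e3, 2), 1.35)
  expect_true(is.na(resw$rli))

  expect_error(assess_site(one[0, ]), "no samples")
})
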