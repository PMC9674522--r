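test_that("distribution specs validate and sample correctly", {
  expect_error(dist_truncnorm(10, -1), "non-negative")
  expect_error(dist_triangular(3, 2, 1), "min <= mode <= max")
  expect_error(dist_uniform(2, 2), "min < max")

  # truncated-normal draws respect the bounds and the seed
  spec <- dist_truncnorm(5, 10, lower = 0, upper = 20)
  x <- draw(spec, 1000, seed = 9)
  expect_true(all(x >= 0 & x <= 20))
  expect_identical(x, draw(spec, 1000, seed = 9))

  # symmetric truncation preserves the mean exactly (closed form)
  sym <- dist_truncnorm_symmetric(19.83, 17.09)
  expect_equal(sym$lower, 19.83 - 19.83)
  expect_equal(sym$upper, 2 * 19.83)
  expect_equal(dist_mean(sym), 19.83, tolerance = 1e-12)

  tri <- dist_triangular(1, 2, 6)
  expect_equal(dist_mean(tri), 3)
  y <- draw(tri, 2000, seed = 10)
  expect_true(all(y >= 1 & y <= 6))
  expect_equal(mean(y), 3, tolerance = 0.1)
})

test_that("empirical summary uses linear-interpolation percentiles", {
  s <- summarize_mcs(1:100)
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)
  expect_equal(s$mean, 50.5)

  const <- summarize_mcs(rep(2.5, 10))
  expect_equal(const$p5, 2.5)
  expect_equal(const$mean, 2.5)
  expect_equal(const$p95, 2.5)

  expect_true(summarize_mcs(rnorm(500))$p5 <= summarize_mcs(rnorm(500))$p95)
  expect_error(summarize_mcs(numeric(0)), "empty")
})

test_that("point-distribution MCS collapses to the deterministic ELCR", {
  means <- soil_means("Beryllium", "in_situ")
  cfg <- mcs_config(
    activities = list(K40 = means$K40, U238 = means$U238, Th232 = means$Th232),
    n_trials = 200, seed = 1
  )
  res <- run_mcs(cfg, "external_soil")
  det <- 1e3 * elcr(aed_external(absorbed_dose_rate(
    means[c("K40", "U238", "Th232")]
  )$dose_rate_nGy_h))
  expect_equal(1e3 * res$mean, det, tolerance = 1e-12)
  expect_equal(res$p5, res$mean)
  expect_equal(res$p95, res$mean)
  expect_equal(res$deterministic, res$mean)
  expect_true(all(res$samples == res$samples[1]))
})

test_that("a single trial yields a degenerate one-draw summary", {
  cfg <- mcs_config(
    activities = list(K40 = dist_truncnorm(400, 100), U238 = 20, Th232 = 20),
    n_trials = 1, seed = 4
  )
  res <- run_mcs(cfg, "external_soil")
  expect_equal(res$n_trials, 1)
  expect_equal(res$p5, res$samples)
  expect_equal(res$p95, res$samples)
})

test_that("symmetric activity uncertainty keeps the MC mean on the deterministic value", {
  prof <- dplyr::filter(site_profiles(), site == "Beryllium", basis == "in_situ")
  acts <- setNames(
    lapply(seq_len(nrow(prof)), function(i) {
      dist_truncnorm_symmetric(prof$mean[[i]], prof$sd[[i]])
    }),
    prof$nuclide
  )
  cfg <- mcs_config(activities = acts, n_trials = 10000, seed = 12)
  res <- run_mcs(cfg, "external_soil")
  mc_se <- sd(res$samples) / sqrt(res$n_trials)
  expect_lt(abs(res$mean - res$deterministic), 3 * mc_se)
  expect_true(res$p5 < res$mean && res$mean < res$p95)
})

test_that("identical seed and config reproduce the result exactly", {
  cfg <- mcs_config(
    activities = list(
      K40 = dist_truncnorm_symmetric(29.86, 5.29),
      U238 = dist_truncnorm_symmetric(1.00, 0.19),
      Th232 = dist_truncnorm_symmetric(1.30, 0.23)
    ),
    n_trials = 2000, seed = 77
  )
  a <- run_mcs(cfg, "ingestion_water")
  b <- run_mcs(cfg, "ingestion_water")
  expect_identical(a$samples, b$samples)
  expect_identical(tidy(a), tidy(b))
})

test_that("the MC mean converges to the deterministic ELCR with trials", {
  acts <- list(
    K40 = dist_truncnorm_symmetric(412.99, 250.83),
    U238 = dist_truncnorm_symmetric(19.83, 17.09),
    Th232 = dist_truncnorm_symmetric(20.62, 10.62)
  )
  err <- sapply(c(1e3, 1e5), function(n) {
    res <- run_mcs(
      mcs_config(activities = acts, n_trials = n, seed = 5), "external_soil"
    )
    abs(res$mean - res$deterministic)
  })
  expect_lt(err[2], err[1])
})

test_that("widening an input distribution does not shrink the P5-P95 band", {
  widths <- c(2, 5, 10, 17)
  bands <- sapply(widths, function(s) {
    cfg <- mcs_config(
      activities = list(
        K40 = dist_truncnorm_symmetric(412.99, 250.83),
        U238 = dist_truncnorm_symmetric(19.83, s),
        Th232 = dist_truncnorm_symmetric(20.62, 10.62)
      ),
      n_trials = 4000, seed = 21
    )
    res <- run_mcs(cfg, "external_soil")
    res$p95 - res$p5
  })
  expect_true(all(diff(bands) > 0))
})

test_that("tidy, glance and autoplot expose the Table-style summary", {
  cfg <- mcs_config(
    activities = list(K40 = dist_truncnorm(100, 20), U238 = 5, Th232 = 5),
    n_trials = 500, seed = 3
  )
  res <- run_mcs(cfg, "ingestion_grain")
  td <- tidy(res)
  expect_equal(td$mean_x1e3, 1e3 * res$mean)
  gl <- glance(res)
  expect_equal(gl$n_trials, 500)
  expect_equal(gl$seed, 3L)
  expect_s3_class(autoplot(res), "ggplot")
})
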