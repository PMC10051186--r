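test_that("alignment pairs common bins and block-averages to coarser steps", {
  ref <- make_series(1:30, "pm25")
  sen <- make_series(1:30 + 0.5, "pm25")
  al <- align_series(sen, ref, step = 1)
  expect_equal(nrow(al$pairs), 30)
  expect_equal(al$presence, 1)

  # 1-min sensor vs 15-min reference cadence: hand-averaged blocks
  ref15 <- sensor_series(minutes_utc(2)[1] + lubridate::minutes(c(0, 15)),
                         c(10, 20), "pm25")
  al15 <- align_series(make_series(1:30, "pm25"), ref15, step = 15)
  expect_equal(al15$pairs$sensor, c(mean(1:15), mean(16:30)))
  expect_equal(al15$pairs$reference, c(10, 20))

  far <- sensor_series(minutes_utc(5, "2020-05-01 00:00:00"), 1:5, "pm25")
  expect_error(align_series(far, ref), class = "wx_config_error")
})

test_that("collocation metrics hit their fixed points and match textbook formulas", {
  ref <- make_series(sin(1:200) + 2, "pm25")
  self <- evaluate_sensor(ref, ref, lfe_cutoff = 30)
  expect_equal(self$metrics$rmse, 0)
  expect_equal(self$metrics$pearson, 1)
  expect_equal(self$metrics$kendall, 1)
  expect_equal(self$metrics$spearman, 1)
  expect_equal(self$metrics$lfe, 1)
  expect_equal(self$ipi, 1, tolerance = 1e-9)

  # anti-correlated pair around zero
  z <- make_series(sin(1:100), "pm25")
  nz <- make_series(-sin(1:100), "pm25")
  anti <- suppressWarnings(evaluate_sensor(nz, z, lfe_cutoff = 20))
  expect_equal(anti$metrics$pearson, -1)

  # textbook-formula oracle on a random pair
  withr::with_seed(77, {
    a <- rnorm(100, 10, 3)
    b <- a + rnorm(100, 0, 2)
  })
  pa <- make_series(a, "pm25")
  pb <- make_series(b, "pm25")
  ev <- evaluate_sensor(pa, pb, lfe_cutoff = 20)
  expect_equal(ev$metrics$rmse, sqrt(mean((a - b)^2)), tolerance = 1e-9)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ev$metrics$pearson, r_hand, tolerance = 1e-9)
  expect_equal(ev$metrics$spearman, cor(rank(a), rank(b)), tolerance = 1e-9)

  const <- make_series(rep(3, 50), "pm25")
  noisy <- make_series(rnorm(50, 3), "pm25")
  cm <- suppressWarnings(evaluate_sensor(const, noisy, lfe_cutoff = 10))
  expect_true(is.na(cm$metrics$pearson))
})

test_that("the match score counts threshold agreement", {
  p <- tibble::tibble(reference = c(rep(0, 90), rep(10, 10)),
                      sensor = rep(0, 100))
  expect_equal(match_score(p, threshold = 5), 0.9)

  agree <- tibble::tibble(reference = 1:100, sensor = 1:100)
  expect_equal(match_score(agree), 1)

  # anti-aligned exceedances: 1 - sum of the two exceedance fractions
  anti <- tibble::tibble(reference = c(rep(10, 10), rep(0, 90)),
                         sensor = c(rep(0, 10), rep(10, 5), rep(0, 85)))
  expect_equal(match_score(anti, threshold = 5), 1 - (0.10 + 0.05))

  low <- tibble::tibble(reference = rep(1, 10), sensor = rep(1, 10))
  expect_warning(s <- match_score(low, threshold = 5), "degenerate")
  expect_equal(s, 1)
})

test_that("low-frequency energy ranks drift above fast error", {
  n <- 720
  t <- seq_len(n)
  base <- make_series(rep(10, n), "pm25")
  slow <- make_series(10 + 2 * sin(2 * pi * t / 360), "pm25")
  fast <- make_series(10 + 2 * sin(2 * pi * t / 10), "pm25")
  lfe_slow <- low_frequency_energy(align_series(slow, base)$pairs)
  lfe_fast <- low_frequency_energy(align_series(fast, base)$pairs)
  expect_lt(lfe_slow, lfe_fast)
  expect_lt(lfe_slow, 0.1)
  expect_gt(lfe_fast, 0.9)

  # white-noise error: score matches the flat-spectrum expectation
  withr::with_seed(11, e <- rnorm(2000))
  white <- low_frequency_energy(tibble::tibble(sensor = e, reference = 0),
                                cutoff_period = 60)
  pg <- stats::spec.pgram(e, taper = 0, detrend = FALSE, demean = TRUE,
                          plot = FALSE, fast = FALSE)
  expect_equal(white, 1 - mean(pg$freq < 1 / 60), tolerance = 0.05)

  expect_true(is.na(low_frequency_energy(
    tibble::tibble(sensor = 1:10, reference = 0), cutoff_period = 60)))
})

test_that("the integrated index weights mapped metrics and degrades monotonically", {
  expect_equal(ipi(list(pearson = 0.66), weights = list(pearson = 1)),
               (0.66 + 1) / 2)
  expect_error(ipi(list(rmse = NA_real_)), class = "wx_config_error")

  # noise ladder: the index never increases with added noise
  ladder <- purrr::map_dbl(c(0, 1, 2.5, 5, 10), function(ns) {
    pair <- generate_reference_pair(1, list(bias = 0, gain = 1, noise_sd = ns,
                                            missing_frac = 0), seed = 88)
    evaluate_sensor(pair$degraded, pair$reference)$ipi
  })
  expect_true(all(diff(ladder) <= 1e-9))

  # common time shift leaves every metric unchanged
  pair <- generate_reference_pair(1, list(bias = 1, gain = 1.1, noise_sd = 2,
                                          missing_frac = 0), seed = 89)
  shift <- function(s) {
    s$timestamp <- s$timestamp + lubridate::hours(6)
    s
  }
  e1 <- evaluate_sensor(pair$degraded, pair$reference)
  e2 <- evaluate_sensor(shift(pair$degraded), shift(pair$reference))
  expect_equal(e1$metrics, e2$metrics)
  expect_equal(e1$ipi, e2$ipi)
})
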