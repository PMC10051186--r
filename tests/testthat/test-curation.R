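test_that("peak detection matches its definition on hand-built cases", {
  expect_equal(detect_peaks(rep(7, 10), k = 2, f = 2), rep(FALSE, 10))

  v <- c(10, 10, 10, 50, 10, 10, 10)
  expect_equal(which(detect_peaks(v, k = 2, f = 2)), 4L)

  # all-missing neighbourhood: position cannot be flagged
  v <- c(NA, NA, 100, NA, NA)
  expect_equal(detect_peaks(v, k = 2, f = 2), rep(FALSE, 5))

  # boundary positions use available neighbours only
  v <- c(100, 10, 10, 10)
  expect_true(detect_peaks(v, k = 2, f = 2)[1])
})

test_that("peak detection equals the brute-force double-loop oracle", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- 200
      v <- rlnorm(n, log(10), 0.6)
      v[sample(n, 8)] <- NA
      k <- sample(1:4, 1)
      f <- runif(1, 1.2, 3)
      expect_identical(detect_peaks(v, k, f), brute_peaks(v, k, f))
    }
  })
})

test_that("range filtering keeps in-range values and counts removals", {
  s <- make_series(c(-5, 10, 2000))
  r <- apply_range_filter(s, c(0, 1000))
  expect_equal(r$series$value, 10)
  expect_equal(nrow(r$removed), 2)

  r2 <- apply_range_filter(s, c(-Inf, Inf))
  expect_equal(r2$series$value, s$value)
  expect_equal(nrow(r2$removed), 0)

  r3 <- apply_range_filter(make_series(c(-5, 3000)), c(0, 1000))
  expect_equal(nrow(r3$series), 0)
  expect_equal(nrow(r3$removed), 2)
})

test_that("particle ordering removes violating minutes from all three channels", {
  pm1 <- make_series(c(1, 5, 2), "pm1")
  pm25 <- make_series(c(2, 2, 4), "pm25")
  pm10 <- make_series(c(3, 3, 6), "pm10")
  r <- enforce_pm_ordering(pm1, pm25, pm10)
  expect_equal(nrow(r$removed), 1)
  expect_equal(nrow(r$pm1), 2)
  expect_equal(r$pm25$value, c(2, 4))

  withr::with_seed(9, {
    a <- make_series(rlnorm(500, log(5), 0.5), "pm1")
    b <- make_series(rlnorm(500, log(6), 0.5), "pm25")
    c <- make_series(rlnorm(500, log(8), 0.5), "pm10")
    r <- enforce_pm_ordering(a, b, c)
    ok <- a$value <= b$value & b$value <= c$value
    expect_equal(sort(r$pm1$timestamp), sort(a$timestamp[ok]))
    expect_equal(nrow(r$removed), sum(!ok))
  })
})

test_that("warm-up trimming removes minutes after every power-on boundary", {
  s <- make_series(rep(5, 10), "no2")
  r <- trim_warmup(s, 3)
  expect_equal(sum(!is.na(r$series$value)), 7)
  expect_equal(nrow(r$removed), 3)

  # a long gap counts as a restart: manual segmentation of the fixture
  t <- c(minutes_utc(10), minutes_utc(10, "2019-10-14 02:00:00"))
  s2 <- sensor_series(t, rep(5, 20), "no2")
  r2 <- trim_warmup(s2, 3)
  expect_equal(sum(!is.na(r2$series$value)), 14)
  expect_equal(nrow(r2$removed), 6)

  r3 <- trim_warmup(s, 0)
  expect_equal(r3$series$value, s$value)
})

test_that("the black-carbon floor is inclusive and one-sided", {
  s <- make_series(c(-100, -2000, 500), "bc")
  r <- floor_bc(s, -1500)
  expect_equal(r$series$value, c(-100, 500))
  expect_equal(nrow(r$removed), 1)

  exact <- make_series(c(-1500, 10), "bc")
  expect_equal(nrow(floor_bc(exact, -1500)$removed), 0)
  expect_equal(nrow(floor_bc(make_series(c(0, 5), "bc"))$removed), 0)
})

test_that("GPS denoising drops teleports and matches a sequential oracle", {
  still <- gps_track(minutes_utc(5), rep(2.13, 5), rep(48.8, 5))
  expect_equal(nrow(denoise_gps(still)$track), 5)

  # one point 500 km away: haversine hand-check says ~500 km in 1 minute
  tp <- gps_track(minutes_utc(3), c(2.13, 8.9, 2.131), c(48.8, 48.8, 48.8))
  expect_gt(hav_m(2.13, 48.8, 8.9, 48.8) / 1000, 400)
  r <- denoise_gps(tp)
  expect_equal(r$track$lon, c(2.13, 2.131))
  expect_equal(nrow(r$removed), 1)

  withr::with_seed(12, {
    n <- 300
    lon <- 2.13 + cumsum(rnorm(n, 0, 1e-4))
    lat <- 48.8 + cumsum(rnorm(n, 0, 1e-4))
    lon[sample(n, 5)] <- lon[sample(n, 5)] + 0.5
    tr <- gps_track(minutes_utc(n), lon, lat)
    got <- denoise_gps(tr, vmax = 130)$track
    # independent sequential oracle on the textbook haversine
    keep <- 1L
    last <- 1L
    for (i in 2:n) {
      d <- hav_m(lon[last], lat[last], lon[i], lat[i])
      vkmh <- (d / 1000) / ((i - last) / 60)
      if (vkmh <= 130) {
        keep <- c(keep, i)
        last <- i
      }
    }
    expect_equal(got$lon, lon[keep])
  })
})

test_that("per-minute speed averages segment speeds at their midpoints", {
  # 1 km in 1 minute is 60 km/h
  tr <- gps_track(minutes_utc(2), c(2.13, 2.13),
                  c(48.8, 48.8 + 1000 / (6378137 * pi / 180)))
  sp <- per_minute_speed(tr)
  expect_equal(sp$value, 60, tolerance = 1e-3)
  expect_equal(sp$timestamp, tr$timestamp[1])

  expect_equal(nrow(per_minute_speed(gps_track(minutes_utc(1), 2.13, 48.8))), 0)

  still <- gps_track(minutes_utc(5), rep(2.13, 5), rep(48.8, 5))
  expect_true(all(per_minute_speed(still)$value < 0.1))
})

test_that("fusion keeps union minutes with at least one sensor measurement", {
  a <- make_series(c(1, 2), "no2")
  b <- sensor_series(minutes_utc(2, "2019-10-14 00:05:00"), c(3, 4), "pm1")
  tab <- fuse(list(no2 = a, pm1 = b))
  expect_equal(nrow(tab), 4)
  expect_equal(sum(!is.na(tab$no2)), 2)
  expect_equal(sum(!is.na(tab$pm1)), 2)

  # a GPS-only minute does not form a row
  gps <- gps_track(minutes_utc(10), rep(2.13, 10), rep(48.8, 10))
  sp <- per_minute_speed(denoise_gps(gps)$track)
  tab2 <- fuse(list(no2 = a), speed = sp, gps = gps)
  expect_equal(nrow(tab2), 2)

  ann <- tibble::tibble(start = minutes_utc(1),
                        end = minutes_utc(1) + lubridate::minutes(2),
                        label = "office")
  tab3 <- fuse(list(no2 = a), annotations = ann)
  expect_equal(tab3$label, c("office", "office"))
})

test_that("curation of a clean bundle removes almost nothing", {
  sched <- generate_schedule(2, seed = 61)
  b <- generate_traces(sched, artifacts = clean_artifact_model(), seed = 62)
  cu <- curate(b)
  expect_lt(cu$report$fraction_removed, 0.01)
})

test_that("curation is a fixed point and its counts are consistent", {
  cu <- default_curation()
  counts <- cu$report$counts
  expect_equal(sum(counts$removed), cu$report$total_removed)
  expect_equal(nrow(cu$report$removed_points), cu$report$total_removed)

  again <- curate(as_bundle(cu$table))
  expect_equal(again$report$total_removed, 0)
})

test_that("curated output honours every filter invariant", {
  tab <- default_curation()$table
  all3 <- !is.na(tab$pm1) & !is.na(tab$pm25) & !is.na(tab$pm10)
  expect_true(all(tab$pm1[all3] <= tab$pm25[all3] &
                    tab$pm25[all3] <= tab$pm10[all3]))
  cfg <- curation_config()
  for (ch in names(cfg$range_limits)) {
    lim <- cfg$range_limits[[ch]]
    expect_true(all(tab[[ch]] >= lim[1] & tab[[ch]] <= lim[2], na.rm = TRUE))
  }
  expect_true(all(tab$bc >= cfg$bc_floor, na.rm = TRUE))
})
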