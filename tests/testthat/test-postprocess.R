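# A hand-built day: home cluster, commute, office cluster, commute back.
commute_day <- function(seed = 1) {
  withr::with_seed(seed, {
    n_home1 <- 420; n_go <- 20; n_off <- 540; n_back <- 20
    n_home2 <- 1440 - n_home1 - n_go - n_off - n_back
    jit <- function(n, lon0, lat0) {
      cbind(lon0 + rnorm(n, 0, 3e-5), lat0 + rnorm(n, 0, 3e-5))
    }
    home <- c(2.1300, 48.8000)
    office <- c(2.1440, 48.8000)  # ~1 km east
    path <- cbind(seq(home[1], office[1], length.out = n_go),
                  seq(home[2], office[2], length.out = n_go))
    pos <- rbind(jit(n_home1, home[1], home[2]), path,
                 jit(n_off, office[1], office[2]), path[n_go:1, ],
                 jit(n_home2, home[1], home[2]))
    lab <- c(rep("home", n_home1), rep("transport", n_go),
             rep("office", n_off), rep("transport", n_back),
             rep("home", n_home2))
    tab <- make_fused(1440)
    tab$lon <- pos[, 1]
    tab$lat <- pos[, 2]
    tab$label <- lab
    tab$speed <- ifelse(lab == "transport", 20, 0.05)
    tab
  })
}

test_that("density grids conserve counts and split distant clusters", {
  tab <- commute_day()
  g <- build_density_grid(tab)
  expect_equal(sum(g$cells$count), nrow(tab))
  expect_equal(g$n_points, nrow(tab))

  one <- build_density_grid(tibble::tibble(lon = rep(2.13, 7), lat = rep(48.8, 7)))
  expect_equal(nrow(one$cells), 1)
  expect_equal(one$cells$count, 7)

  two <- build_density_grid(tibble::tibble(lon = c(rep(2.13, 5), rep(2.1437, 5)),
                                           lat = rep(48.8, 10)), cell_m = 100)
  expect_equal(sort(two$cells$count), c(5, 5))
  expect_equal(nrow(two$cells), 2)

  expect_error(build_density_grid(tibble::tibble(lon = NA_real_, lat = NA_real_)),
               class = "wx_config_error")
})

test_that("stop segmentation recovers the home/office structure of a day", {
  tab <- commute_day()
  g <- build_density_grid(tab)
  segs <- segment_stops(tab, g)
  stops <- segs[segs$kind == "stop", ]
  expect_equal(nrow(stops), 3)  # home, office, home again
  expect_equal(stops$modal_label, c("home", "office", "home"))
  expect_equal(nrow(segs[segs$kind == "move", ]), 2)

  # segments tile the day with no overlap
  expect_equal(sum(segs$n), nrow(tab))
  segs <- dplyr::arrange(segs, start)
  expect_true(all(segs$start[-1] == segs$end[-nrow(segs)]))

  # a continuously moving track yields no stop segments
  n <- 120
  moving <- make_fused(n)
  moving$lon <- 2.13 + seq(0, 0.05, length.out = n)
  moving$lat <- 48.8
  moving$speed <- 25
  gm <- build_density_grid(moving)
  sm <- segment_stops(moving, gm)
  expect_equal(sum(sm$kind == "stop"), 0)
})

test_that("the night-time density rule finds the home site", {
  tab <- commute_day()
  g <- build_density_grid(tab)
  segs <- segment_stops(tab, g)
  # mislabel the home stops as indoor: the rule must recover them
  segs$modal_label[segs$kind == "stop" & segs$modal_label == "home"] <- "indoor"
  fixed <- apply_home_rule(segs, tab, g)
  stops <- fixed[fixed$kind == "stop", ]
  expect_equal(stops$modal_label, c("home", "office", "home"))
  expect_true(any(fixed$home_rule))
  # the inferred home site is the generator's home location (within the
  # one-cell tolerance that grid quantisation imposes)
  home_cell <- strsplit(grid_cell(g, 2.13, 48.8), ":", fixed = TRUE)[[1]]
  for (cell in stops$cell[stops$modal_label == "home"]) {
    xy <- as.integer(strsplit(cell, ":", fixed = TRUE)[[1]])
    expect_lte(max(abs(xy - as.integer(home_cell))), 1)
  }

  # with no night-window positions the rule is skipped
  day_only <- tab[lubridate::hour(lubridate::with_tz(tab$timestamp, "Europe/Paris")) >= 8, ]
  g2 <- build_density_grid(day_only)
  segs2 <- segment_stops(day_only, g2)
  expect_warning(out <- apply_home_rule(segs2, day_only, g2), "skipped")
  expect_equal(out$modal_label, segs2$modal_label)
})

test_that("label smoothing absorbs short runs and is idempotent", {
  expect_equal(smooth_labels(c("A", "A", "B", "A", "A"), 3), rep("A", 5))

  long_runs <- c(rep("A", 5), rep("B", 4))
  expect_equal(smooth_labels(long_runs, 3), long_runs)

  withr::with_seed(5, {
    x <- sample(c("A", "B", "C", NA), 300, replace = TRUE)
    s1 <- smooth_labels(x, 3)
    expect_identical(smooth_labels(s1, 3), s1)
    # missing labels survive untouched
    expect_identical(is.na(s1), is.na(x))
  })
})

test_that("post-processing corrects corrupted labels and reports changes", {
  tab <- commute_day()
  truth <- tab$label
  withr::with_seed(31, {
    noisy <- truth
    flip <- sample(length(noisy), 90)
    noisy[flip] <- sample(environment_classes(), 90, replace = TRUE)
  })
  raw_acc <- mean(noisy == truth)
  pp <- postprocess_labels(tab, noisy)
  post_acc <- mean(pp$labels == truth)
  expect_gte(post_acc, raw_acc)
  expect_gt(post_acc, 0.99)
  expect_true(all(pp$report$minutes_changed >= 0))

  # consistent labels pass through unchanged
  clean <- postprocess_labels(tab, truth)
  expect_equal(clean$labels, truth)

  # determinism
  pp2 <- postprocess_labels(tab, noisy)
  expect_identical(pp$labels, pp2$labels)
})
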