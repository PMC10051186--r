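#' Default campaign occupancy and bout durations
#'
#' Occupancy fractions follow the field campaign's reported time budget
#' (home 68%, office 24%, indoor 3%, outdoor 1%, transport 4%). Mean bout
#' durations are chosen to give a realistic daily rhythm (long home/office
#' sittings, short errands and commutes) while letting a multi-day schedule's
#' realized time budget converge to the requested fractions.
#'
#' @return A named numeric vector over [environment_classes()].
#' @export
default_occupancy <- function() {
  c(home = 0.68, office = 0.24, indoor = 0.03, outdoor = 0.01, transport = 0.04)
}

#' @rdname default_occupancy
#' @export
default_mean_bout <- function() {
  c(home = 300, office = 180, indoor = 40, outdoor = 20, transport = 20)
}

#' Environment-conditional emission model
#'
#' Describes, per (environment, channel), the baseline level and dispersion
#' of each sensor channel, plus an activity "spike" process (cooking-like
#' pollutant peaks at home and in indoor public spaces). Pollutant baselines
#' are log-normal; temperature and humidity are Gaussian. Minute-to-minute
#' values share an AR(1) deviation process (`ar_phi`) so that series are
#' autocorrelated like real ambient measurements rather than white noise.
#'
#' Default levels follow the qualitative ordering of the campaign narrative:
#' transport and indoor peaks for NO2/BC, indoor maxima for PM, low home and
#' office baselines, near-zero speed outside transport.
#'
#' @param separation Dispersion divisor; `separation = 3` shrinks all
#'   standard deviations threefold, giving between-environment mean gaps of
#'   at least three within-environment SDs on the discriminative channels.
#' @param ar_phi AR(1) coefficient of the minute-scale deviation process.
#' @return An object of class `wx_emission`.
#' @export
emission_model <- function(separation = 1, ar_phi = 0.9) {
  stopifnot(separation > 0, ar_phi >= 0, ar_phi < 1)
  env <- environment_classes()
  baseline <- dplyr::bind_rows(
    tibble(channel = "temperature", environment = env,
           mean = c(21, 23, 19, 10, 16), sd = c(1, 1, 1.5, 2, 1.5), dist = "normal"),
    tibble(channel = "humidity", environment = env,
           mean = c(45, 38, 50, 75, 55), sd = c(4, 3, 5, 6, 5), dist = "normal"),
    tibble(channel = "pm1", environment = env,
           mean = c(4, 3, 12, 7, 6), sd = c(1.5, 1, 5, 2.5, 2), dist = "lognormal"),
    tibble(channel = "pm25", environment = env,
           mean = c(6, 5, 16, 9, 8), sd = c(2, 1.5, 6, 3, 2.5), dist = "lognormal"),
    tibble(channel = "pm10", environment = env,
           mean = c(9, 7, 20, 12, 11), sd = c(3, 2, 8, 4, 3.5), dist = "lognormal"),
    tibble(channel = "no2", environment = env,
           mean = c(18, 15, 25, 40, 45), sd = c(5, 4, 8, 10, 10), dist = "lognormal"),
    tibble(channel = "bc", environment = env,
           mean = c(500, 400, 900, 1200, 2000), sd = c(250, 200, 400, 500, 700),
           dist = "lognormal")
  ) %>% mutate(sd = .data$sd / separation)
  spikes <- dplyr::bind_rows(
    tibble(environment = "home", channel = c("pm1", "bc", "no2"),
           rate_per_hour = 0.06, magnitude = 3, duration_min = 15),
    tibble(environment = "indoor", channel = c("pm1", "bc", "no2"),
           rate_per_hour = 0.25, magnitude = 3, duration_min = 12)
  )
  structure(list(baseline = baseline, spikes = spikes, ar_phi = ar_phi,
                 transport_speed_kmh = 28, walk_speed_kmh = 4),
            class = "wx_emission")
}

#' Sensor and GPS artifact model
#'
#' Controls injected measurement artifacts: isolated multiplicative spike
#' glitches (recorded in a ground-truth ledger), per-minute random dropouts,
#' device power-off periods with an electrochemical warm-up bias on the NO2
#' channel after each restart, zero-mean black-carbon instrument noise, GPS
#' position jitter and teleport outliers.
#'
#' @param spike_rate_per_hour Spike glitches per hour per channel.
#' @param spike_factor Multiplicative magnitude of a spike glitch.
#' @param dropout_prob Per-minute per-channel probability of a missing value.
#' @param off_periods_per_day Device power-off periods per day (all channels).
#' @param off_duration_mean Mean power-off duration, minutes.
#' @param warmup_bias Additive NO2 bias (ug/m3) during warm-up minutes after
#'   a restart.
#' @param warmup_minutes Length of the warm-up transient, minutes.
#' @param bc_noise_sd SD of zero-mean BC noise, ng/m3.
#' @param gps_jitter_m SD of GPS position jitter, metres.
#' @param teleport_rate Per-minute probability of a GPS teleport outlier.
#' @param teleport_km Typical teleport displacement, km.
#' @return An object of class `wx_artifacts`.
#' @export
artifact_model <- function(spike_rate_per_hour = 6, spike_factor = 8,
                           dropout_prob = 0.02, off_periods_per_day = 2,
                           off_duration_mean = 45, warmup_bias = 40,
                           warmup_minutes = 3, bc_noise_sd = 300,
                           gps_jitter_m = 5, teleport_rate = 0.002,
                           teleport_km = 8) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, teleport_rate >= 0,
            teleport_rate <= 1, spike_rate_per_hour >= 0, warmup_minutes >= 0,
            off_duration_mean >= 1)
  structure(as.list(environment()), class = "wx_artifacts")
}

#' @rdname artifact_model
#' @export
clean_artifact_model <- function() {
  artifact_model(spike_rate_per_hour = 0, dropout_prob = 0,
                 off_periods_per_day = 0, warmup_bias = 0, bc_noise_sd = 0,
                 gps_jitter_m = 0, teleport_rate = 0)
}

#' Generate a stochastic daily-routine microenvironment schedule
#'
#' Builds the span day by day. Each day's environment budgets are the
#' requested occupancy fractions of 1440 minutes with multiplicative gamma
#' jitter (renormalised to the day), so the realized multi-day time budget
#' converges to the requested fractions. The home budget anchors the night:
#' it is split into a morning block from midnight to a jittered wake time
#' and an evening block closing the day, which keeps participants home in
#' the small hours the way the night-time home rule presupposes. Every other
#' environment's budget is split into bouts of typical length `mean_bout`
#' (durations jittered), non-transport bouts are shuffled across the day,
#' and transport bouts bracket them as commutes. Adjacent identical states
#' are merged.
#'
#' @param days Simulated span in days.
#' @param occupancy Named fractions over environments, summing to 1.
#' @param mean_bout Named typical bout durations in minutes (>= 1).
#' @param seed Integer seed; the schedule is deterministic given it.
#' @param start POSIXct start instant (UTC).
#' @return A tibble `start, end, label` of class `wx_schedule`, tiling the
#'   span with contiguous intervals.
#' @export
generate_schedule <- function(days, occupancy = default_occupancy(),
                              mean_bout = default_mean_bout(), seed = 1,
                              start = lubridate::ymd_hms("2019-10-14 00:00:00", tz = "UTC")) {
  if (abs(sum(occupancy) - 1) > 1e-9) {
    abort("occupancy fractions must sum to 1", class = "wx_config_error")
  }
  if (!all(names(occupancy) %in% environment_classes())) {
    abort("occupancy names must be among environment_classes()", class = "wx_config_error")
  }
  occupancy <- occupancy[occupancy > 0]
  mean_bout <- mean_bout[names(occupancy)]
  if (any(is.na(mean_bout)) || any(mean_bout < 1)) {
    abort("mean_bout must cover every occupied environment with values >= 1",
          class = "wx_config_error")
  }
  total <- round(days * 1440)
  n_days <- ceiling(total / 1440)
  envs <- names(occupancy)

  split_bouts <- function(budget, typical) {
    if (budget <= 0) return(integer(0))
    n_b <- max(1L, round(budget / typical))
    w <- stats::rgamma(n_b, shape = 12, rate = 12)
    d <- floor(budget * w / sum(w))
    d[1] <- d[1] + budget - sum(d)
    d[d > 0]
  }

  one_day <- function() {
    jit <- stats::rgamma(length(envs), shape = 70, rate = 70)
    bud <- occupancy * jit
    bud <- bud / sum(bud) * 1440
    ibud <- floor(bud)
    extra <- 1440L - sum(ibud)
    if (extra > 0) {
      top <- order(bud - ibud, decreasing = TRUE)[seq_len(extra)]
      ibud[top] <- ibud[top] + 1L
    }
    home <- if ("home" %in% envs) ibud[["home"]] else 0L
    mid <- purrr::imap(ibud[setdiff(envs, c("home", "transport"))],
                       ~ tibble(label = .y, dur = split_bouts(.x, mean_bout[[.y]])))
    mid <- bind_rows(mid)
    if (nrow(mid) > 1) mid <- mid[sample.int(nrow(mid)), ]
    tr <- if ("transport" %in% envs) {
      tibble(label = "transport", dur = split_bouts(ibud[["transport"]],
                                                    mean_bout[["transport"]]))
    } else tibble(label = character(), dur = integer())
    day <- if (nrow(tr) >= 2 && nrow(mid) > 0) {
      k <- nrow(tr)
      middle_tr <- tr[seq_len(max(k - 2, 0)) + 1, ]
      at <- if (nrow(middle_tr) > 0) sample(nrow(mid), nrow(middle_tr), replace = TRUE) else integer(0)
      pieces <- list(tr[1, ])
      for (i in seq_len(nrow(mid))) {
        pieces <- c(pieces, list(mid[i, ]), purrr::map(which(at == i), ~ middle_tr[.x, ]))
      }
      bind_rows(c(pieces, list(tr[k, ])))
    } else {
      bind_rows(tr[0, ], mid, tr)
    }
    if (home > 0) {
      morning <- round(home * runif(1, 0.42, 0.52))
      evening <- home - morning
      day <- bind_rows(
        tibble(label = "home", dur = morning),
        day,
        tibble(label = "home", dur = evening)
      )
    }
    day %>% filter(.data$dur > 0)
  }

  out <- withr::with_seed(seed, bind_rows(purrr::map(seq_len(n_days), ~ one_day())))
  cum <- cumsum(out$dur)
  if (cum[length(cum)] > total) {
    keep <- which(cum - out$dur < total)
    out <- out[keep, ]
    out$dur[length(keep)] <- total - (cum[keep[length(keep)]] - out$dur[keep[length(keep)]])
  }
  grp <- cumsum(c(TRUE, out$label[-1] != out$label[-nrow(out)]))
  merged <- out %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(label = first(.data$label), dur = sum(.data$dur), .groups = "drop")
  ends <- cumsum(merged$dur)
  t0 <- start
  sched <- tibble(
    start = t0 + lubridate::minutes(c(0, head(ends, -1))),
    end = t0 + lubridate::minutes(ends),
    label = merged$label
  )
  class(sched) <- c("wx_schedule", class(sched))
  sched
}

# Stationary AR(1) with unit marginal variance.
ar1 <- function(n, phi) {
  if (n == 0) return(numeric(0))
  as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - phi^2)), phi,
                           method = "recursive", init = rnorm(1)))
}

lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log1p((s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Additive activity-peak contribution: linear 4-minute rise, exponential decay.
spike_shape <- function(len, amplitude, duration) {
  rise <- 4L
  tau <- duration / 2
  j <- seq_len(len) - 1
  ifelse(j < rise, amplitude * (j + 1) / rise, amplitude * exp(-(j - rise + 1) / tau))
}

#' Generate labelled multi-sensor traces and a GPS track for one participant
#'
#' Draws per-minute channel values from the environment-conditional emission
#' model (log-normal baselines with AR(1) autocorrelation, additive activity
#' peaks), generates the three particle channels jointly so that clean data
#' satisfy `pm1 <= pm25 <= pm10` by construction, injects sensor artifacts
#' afterwards (recording every spike glitch in a ground-truth ledger), and
#' emits a one-minute-cadence GPS track: jittered stationary clusters at the
#' home/office/indoor sites, walking loops outdoors, and linear paths between
#' sites during transport.
#'
#' @param schedule A `wx_schedule` from [generate_schedule()].
#' @param emission A `wx_emission` from [emission_model()].
#' @param artifacts A `wx_artifacts` from [artifact_model()].
#' @param seed Integer seed; output is deterministic given it.
#' @param participant_id Identifier attached to every output.
#' @param home_lon,home_lat Home site, WGS84 degrees.
#' @return A list of class `wx_bundle` with elements `sensors` (named list of
#'   `wx_series`), `gps` (`wx_track`), `annotations`, `ledger` (ground-truth
#'   artifact record) and `schedule`.
#' @export
generate_traces <- function(schedule, emission = emission_model(),
                            artifacts = artifact_model(), seed = 1,
                            participant_id = "p1",
                            home_lon = 2.13, home_lat = 48.80) {
  stopifnot(inherits(schedule, "wx_schedule"))
  withr::with_seed(seed, {
    minutes <- seq(min(schedule$start), max(schedule$end) - 60, by = "1 min")
    n <- length(minutes)
    env <- label_minutes(minutes, schedule)
    r <- rle(env)
    nb <- length(r$lengths)
    bout_id <- rep(seq_len(nb), r$lengths)
    bout_start <- cumsum(c(1L, head(r$lengths, -1)))
    phi <- emission$ar_phi

    draw_base <- function(ch) {
      b <- emission$baseline %>% filter(.data$channel == ch)
      m <- b$mean[match(env, b$environment)]
      s <- b$sd[match(env, b$environment)]
      z <- ar1(n, phi)
      if (b$dist[1] == "lognormal") {
        lp <- lnorm_pars(m, s)
        exp(lp$meanlog + lp$sdlog * z)
      } else {
        m + s * z
      }
    }

    add_spikes <- function(x, ch) {
      sp <- emission$spikes %>% filter(.data$channel == ch)
      if (nrow(sp) == 0) return(x)
      for (i in seq_len(nb)) {
        row <- sp %>% filter(.data$environment == r$values[i])
        if (nrow(row) == 0) next
        len <- r$lengths[i]
        nev <- stats::rpois(1, row$rate_per_hour * len / 60)
        if (nev == 0) next
        bmean <- emission$baseline %>%
          filter(.data$channel == ch, .data$environment == r$values[i]) %>% pull(.data$mean)
        for (e in seq_len(nev)) {
          at <- sample.int(len, 1)
          amp <- row$magnitude * bmean * stats::rlnorm(1, 0, 0.3)
          span <- min(len - at + 1, ceiling(row$duration_min * 3))
          idx <- bout_start[i] + at - 1 + seq_len(span) - 1
          x[idx] <- x[idx] + spike_shape(span, amp, row$duration_min)
        }
      }
      x
    }

    values <- list()
    values$temperature <- draw_base("temperature")
    values$humidity <- pmin(pmax(draw_base("humidity"), 0), 100)
    values$no2 <- add_spikes(draw_base("no2"), "no2")
    values$bc <- add_spikes(draw_base("bc"), "bc")
    pm1 <- add_spikes(draw_base("pm1"), "pm1")
    ratio_mean <- function(num, den) {
      bn <- emission$baseline %>% filter(.data$channel == num)
      bd <- emission$baseline %>% filter(.data$channel == den)
      m <- bn$mean[match(environment_classes(), bn$environment)] /
        bd$mean[match(environment_classes(), bd$environment)] - 1
      setNames(m, environment_classes())
    }
    r1 <- ratio_mean("pm25", "pm1")
    r2 <- ratio_mean("pm10", "pm25")
    u1 <- stats::rgamma(nb, shape = 6, scale = r1[r$values] / 6)[bout_id]
    u2 <- stats::rgamma(nb, shape = 6, scale = r2[r$values] / 6)[bout_id]
    values$pm1 <- pm1
    values$pm25 <- pm1 * (1 + u1)
    values$pm10 <- values$pm25 * (1 + u2)

    # ---- artifact injection ----
    if (artifacts$bc_noise_sd > 0) {
      # instrument noise is autocorrelated at the 1-minute scale, not white
      values$bc <- values$bc + artifacts$bc_noise_sd * ar1(n, 0.9)
    }
    observed <- rep(TRUE, n)
    if (artifacts$off_periods_per_day > 0) {
      ndays <- ceiling(n / 1440)
      for (d in seq_len(ndays)) {
        for (k in seq_len(artifacts$off_periods_per_day)) {
          st <- (d - 1) * 1440 + sample.int(1440, 1)
          du <- 1L + stats::rpois(1, artifacts$off_duration_mean - 1)
          idx <- st:min(st + du - 1, n)
          idx <- idx[idx <= n & idx >= 1]
          observed[idx] <- FALSE
        }
      }
    }
    if (artifacts$warmup_bias > 0 && any(observed)) {
      obs_idx <- which(observed)
      restart <- obs_idx[c(TRUE, diff(obs_idx) > 1)]
      for (rs in restart) {
        idx <- rs + seq_len(artifacts$warmup_minutes) - 1
        idx <- idx[idx <= n & observed[idx]]
        values$no2[idx] <- values$no2[idx] + artifacts$warmup_bias
      }
    }

    ledger <- list()
    dropmask <- list()
    for (ch in sensor_channels()) {
      drop <- runif(n) < artifacts$dropout_prob
      dropmask[[ch]] <- drop
      cand <- which(observed & !drop)
      if (artifacts$spike_rate_per_hour > 0 && length(cand) > 10) {
        nspike <- stats::rpois(1, length(cand) * artifacts$spike_rate_per_hour / 60)
        pick <- sort(sample(cand, min(nspike, length(cand))))
        # enforce >= 5-minute spacing so glitches stay isolated
        keep <- logical(length(pick))
        lastkept <- -10L
        for (i in seq_along(pick)) {
          if (pick[i] - lastkept >= 5) { keep[i] <- TRUE; lastkept <- pick[i] }
        }
        pick <- pick[keep]
        if (length(pick) > 0) {
          values[[ch]][pick] <- values[[ch]][pick] *
            artifacts$spike_factor * runif(length(pick), 0.9, 1.3)
          ledger[[ch]] <- tibble(participant_id = participant_id, channel = ch,
                                 timestamp = minutes[pick], type = "spike")
        }
      }
    }
    ledger <- if (length(ledger) > 0) bind_rows(ledger) else
      tibble(participant_id = character(), channel = character(),
             timestamp = minutes[0], type = character())

    sensors <- purrr::map(setNames(sensor_channels(), sensor_channels()), function(ch) {
      v <- values[[ch]]
      v[dropmask[[ch]]] <- NA_real_
      sensor_series(minutes[observed], v[observed], ch,
                    participant_id = participant_id)
    })

    # ---- GPS (local metres east/north of home, converted once) ----
    site_of <- function(i) {
      lab <- r$values[i]
      if (lab == "home") c(0, 0)
      else if (lab == "office") office_site
      else if (lab == "indoor") {
        th <- runif(1, 0, 2 * pi); d <- runif(1, 4000, 8000)
        c(d * cos(th), d * sin(th))
      } else NULL
    }
    office_site <- c(10000, 0)
    anchors <- vector("list", nb)
    prev <- c(0, 0)
    for (i in seq_len(nb)) {
      s <- site_of(i)
      if (r$values[i] %in% c("home", "office", "indoor")) {
        anchors[[i]] <- s; prev <- s
      } else {
        anchors[[i]] <- prev  # outdoor loops / transport origin
      }
    }
    xy <- matrix(0, n, 2)
    prev_site <- c(0, 0)
    for (i in seq_len(nb)) {
      len <- r$lengths[i]
      idx <- bout_start[i] + seq_len(len) - 1
      lab <- r$values[i]
      if (lab %in% c("home", "office", "indoor")) {
        xy[idx, ] <- matrix(anchors[[i]], len, 2, byrow = TRUE)
        prev_site <- anchors[[i]]
      } else if (lab == "outdoor") {
        step <- emission$walk_speed_kmh * 1000 / 60
        off <- matrix(0, len, 2)
        cur <- c(0, 0)
        for (j in seq_len(len)) {
          th <- runif(1, 0, 2 * pi)
          cur <- 0.85 * cur + step * c(cos(th), sin(th))
          off[j, ] <- cur
        }
        xy[idx, ] <- matrix(prev_site, len, 2, byrow = TRUE) + off
      } else { # transport
        nxt <- NULL
        for (j in seq(i + 1, length.out = max(nb - i, 0))) {
          if (r$values[j] %in% c("home", "office", "indoor")) { nxt <- anchors[[j]]; break }
        }
        if (is.null(nxt)) nxt <- c(0, 0)
        dist <- sqrt(sum((nxt - prev_site)^2))
        if (dist < 1500) {
          # out-and-back loop at transport speed
          half <- emission$transport_speed_kmh * 1000 / 60 * len / 2
          th <- runif(1, 0, 2 * pi)
          mid <- prev_site + half * c(cos(th), sin(th))
          fr <- seq_len(len) / len
          out <- fr <= 0.5
          xy[idx[out], ] <- outer(2 * fr[out], mid - prev_site) +
            matrix(prev_site, sum(out), 2, byrow = TRUE)
          xy[idx[!out], ] <- outer(2 * (fr[!out] - 0.5), nxt - mid) +
            matrix(mid, sum(!out), 2, byrow = TRUE)
        } else {
          fr <- seq_len(len) / len
          xy[idx, ] <- outer(fr, nxt - prev_site) +
            matrix(prev_site, len, 2, byrow = TRUE)
        }
        prev_site <- nxt
      }
    }
    if (artifacts$gps_jitter_m > 0) {
      xy <- xy + matrix(rnorm(2 * n, 0, artifacts$gps_jitter_m), n, 2)
    }
    if (artifacts$teleport_rate > 0) {
      tp <- which(runif(n) < artifacts$teleport_rate)
      if (length(tp) > 0) {
        th <- runif(length(tp), 0, 2 * pi)
        d <- artifacts$teleport_km * 1000 * runif(length(tp), 0.5, 1.5)
        xy[tp, ] <- xy[tp, , drop = FALSE] + cbind(d * cos(th), d * sin(th))
      }
    }
    lat <- home_lat + xy[, 2] / 110574
    lon <- home_lon + xy[, 1] / (111320 * cos(home_lat * pi / 180))
    gps <- gps_track(minutes, lon, lat, participant_id = participant_id)

    annotations <- tibble(start = schedule$start, end = schedule$end,
                          label = schedule$label)
    structure(list(sensors = sensors, gps = gps, annotations = annotations,
                   ledger = ledger, schedule = schedule,
                   participant_id = participant_id,
                   home = c(lon = home_lon, lat = home_lat)),
              class = "wx_bundle")
  })
}

#' Generate a sensor-versus-reference series pair
#'
#' Produces a clean reference series and a degraded copy
#' `gain * reference + bias + noise` with a fraction of minutes removed at
#' random, for exercising collocation metrics.
#'
#' @param days Duration in days.
#' @param degradation List with elements `bias`, `gain`, `noise_sd`,
#'   `missing_frac` (fraction in `[0, 1)`).
#' @param seed Integer seed.
#' @param channel Channel name for both series.
#' @param level_mean,level_sd Reference level and dispersion.
#' @return List with `wx_series` elements `reference` and `degraded`.
#' @export
generate_reference_pair <- function(days = 1,
                                    degradation = list(bias = 0, gain = 1,
                                                       noise_sd = 0, missing_frac = 0),
                                    seed = 1, channel = "pm25",
                                    level_mean = 10, level_sd = 4) {
  stopifnot(degradation$missing_frac >= 0, degradation$missing_frac < 1)
  withr::with_seed(seed, {
    n <- round(days * 1440)
    t0 <- lubridate::ymd_hms("2019-10-14 00:00:00", tz = "UTC")
    minutes <- t0 + lubridate::minutes(seq_len(n) - 1)
    lp <- lnorm_pars(level_mean, level_sd)
    ref <- exp(lp$meanlog + lp$sdlog * ar1(n, 0.95))
    deg <- degradation$gain * ref + degradation$bias +
      rnorm(n, 0, degradation$noise_sd)
    keep <- runif(n) >= degradation$missing_frac
    list(
      reference = sensor_series(minutes, ref, channel, sensor_id = "reference"),
      degraded = sensor_series(minutes[keep], deg[keep], channel, sensor_id = "sensor")
    )
  })
}

#' Simulate a multi-participant campaign
#'
#' Convenience wrapper drawing one schedule and trace bundle per participant
#' with sub-seeds derived from a single seed, and distinct home sites.
#'
#' @inheritParams generate_traces
#' @inheritParams generate_schedule
#' @param participants Number of participants.
#' @return A list of `wx_bundle`, one per participant.
#' @export
simulate_campaign <- function(participants = 5, days = 7, seed = 1,
                              occupancy = default_occupancy(),
                              mean_bout = default_mean_bout(),
                              emission = emission_model(),
                              artifacts = artifact_model()) {
  subseeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, 2 * participants))
  purrr::map(seq_len(participants), function(i) {
    sched <- generate_schedule(days, occupancy, mean_bout, seed = subseeds[2 * i - 1])
    generate_traces(sched, emission, artifacts, seed = subseeds[2 * i],
                    participant_id = sprintf("p%02d", i),
                    home_lon = 2.13 + 0.03 * (i - 1),
                    home_lat = 48.80 + 0.015 * ((i - 1) %% 3))
  })
}
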