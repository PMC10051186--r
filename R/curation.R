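#' Curation configuration
#'
#' Parameters of the pre-processing chain. Defaults follow the campaign
#' protocol: peak window half-width `k = 2` and factor `f = 2` (a five-minute
#' window, flagging values more than twice the mean of their neighbours),
#' a three-minute warm-up trim for the electrochemical NO2 sensor, a black
#' carbon noise floor at -1500 ng/m3 (the instrument's limit of detection;
#' small negative values above it are retained), and a 130 km/h GPS speed
#' filter. Range limits are configuration-exposed per channel.
#'
#' @param k Peak window half-width in samples (>= 1).
#' @param f Peak factor (> 1).
#' @param range_limits Named list of `c(min, max)` per channel; channels
#'   absent from the list are not range-filtered.
#' @param warmup_minutes Minutes trimmed after every power-on boundary of the
#'   NO2 series.
#' @param warmup_gap Gap (minutes) in a series that counts as a power-on
#'   boundary.
#' @param bc_floor BC noise floor, ng/m3 (inclusive: values equal to the
#'   floor are retained).
#' @param gps_vmax GPS speed threshold, km/h.
#' @return A list of class `wx_curation_config`.
#' @export
curation_config <- function(k = 2, f = 2,
                            range_limits = list(
                              no2 = c(0, 1000),
                              pm1 = c(0, 2000), pm25 = c(0, 2000), pm10 = c(0, 2000),
                              temperature = c(-30, 60), humidity = c(0, 100)
                            ),
                            warmup_minutes = 3, warmup_gap = 10,
                            bc_floor = -1500, gps_vmax = 130) {
  if (k < 1) abort("k must be >= 1", class = "wx_config_error")
  if (f <= 1) abort("f must be > 1", class = "wx_config_error")
  if (warmup_minutes < 0) abort("warmup_minutes must be >= 0", class = "wx_config_error")
  if (bc_floor >= 0) abort("bc_floor must be negative", class = "wx_config_error")
  bad <- purrr::keep(range_limits, ~ .x[1] >= .x[2])
  if (length(bad) > 0) abort("range limits must satisfy min < max", class = "wx_config_error")
  structure(list(k = k, f = f, range_limits = range_limits,
                 warmup_minutes = warmup_minutes, warmup_gap = warmup_gap,
                 bc_floor = bc_floor, gps_vmax = gps_vmax),
            class = "wx_curation_config")
}

series_values <- function(series) {
  if (is.data.frame(series)) series$value else as.double(series)
}

#' Detect peak artifacts with a windowed-mean rule
#'
#' A value `s[i]` is flagged as a peak when it strictly exceeds `f` times the
#' mean of its up-to-`2k` windowed neighbours (indices `i-k .. i+k`,
#' excluding `i`). Missing neighbours are excluded from the mean; a position
#' with fewer than `max(k, 2)` usable neighbours (including at the series
#' boundaries) is never flagged. The rule is one-sided: only high excursions
#' are peaks.
#'
#' @param series A `wx_series` tibble or numeric vector.
#' @param k Window half-width in samples.
#' @param f Peak factor.
#' @return A logical mask, one entry per value.
#' @export
detect_peaks <- function(series, k = 2, f = 2) {
  if (k < 1) abort("k must be >= 1", class = "wx_config_error")
  if (f <= 1) abort("f must be > 1", class = "wx_config_error")
  v <- series_values(series)
  n <- length(v)
  if (n == 0) return(logical(0))
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  cs <- cumsum(c(0, v0))
  cn <- cumsum(c(0, as.integer(ok)))
  i <- seq_len(n)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, n)
  wsum <- cs[hi + 1] - cs[lo]
  wcnt <- cn[hi + 1] - cn[lo]
  nsum <- wsum - ifelse(ok, v, 0)
  ncnt <- wcnt - as.integer(ok)
  need <- max(k, 2)
  mask <- ok & ncnt >= need & v > f * (nsum / ncnt)
  mask[is.na(mask)] <- FALSE
  mask
}

drop_rows <- function(series, drop, invalidate = FALSE) {
  removed <- series[drop, c("timestamp", "value")]
  if (invalidate) {
    series$value[drop] <- NA_real_
    return(list(series = series, removed = removed))
  }
  list(series = series[!drop, , drop = FALSE], removed = removed)
}

#' Range-filter a sensor series
#'
#' Removes observations outside `[min, max]`; missing values are untouched.
#'
#' @param series A `wx_series` tibble.
#' @param limits Numeric `c(min, max)`.
#' @param invalidate Set removed values to missing (keeping rows) instead of
#'   dropping rows; used by [curate()] so that re-curation sees a stable
#'   minute grid.
#' @return List with elements `series` (survivors) and `removed` (a tibble of
#'   the removed rows).
#' @export
apply_range_filter <- function(series, limits, invalidate = FALSE) {
  if (limits[1] >= limits[2]) abort("range limits must satisfy min < max",
                                    class = "wx_config_error")
  v <- series$value
  drop <- !is.na(v) & (v < limits[1] | v > limits[2])
  drop_rows(series, drop, invalidate)
}

#' Enforce particle-size ordering across the three PM channels
#'
#' Minutes where all three channels carry a value but `pm1 <= pm25 <= pm10`
#' fails are removed from all three channels.
#'
#' @param pm1,pm25,pm10 `wx_series` tibbles on a common minute grid.
#' @param invalidate Set discarded values to missing instead of dropping
#'   rows.
#' @return List with the three filtered series and `removed` (timestamps of
#'   discarded minutes).
#' @export
enforce_pm_ordering <- function(pm1, pm25, pm10, invalidate = FALSE) {
  trip <- dplyr::inner_join(
    dplyr::inner_join(
      pm1 %>% select("timestamp", v1 = "value"),
      pm25 %>% select("timestamp", v2 = "value"), by = "timestamp"),
    pm10 %>% select("timestamp", v3 = "value"), by = "timestamp") %>%
    filter(!is.na(.data$v1), !is.na(.data$v2), !is.na(.data$v3))
  bad <- trip %>% filter(!(.data$v1 <= .data$v2 & .data$v2 <= .data$v3))
  cut1 <- function(s) {
    if (invalidate) {
      s$value[s$timestamp %in% bad$timestamp] <- NA_real_
      s
    } else {
      s %>% filter(!.data$timestamp %in% bad$timestamp)
    }
  }
  list(pm1 = cut1(pm1), pm25 = cut1(pm25), pm10 = cut1(pm10),
       removed = bad %>% select("timestamp"))
}

#' Trim warm-up minutes after power-on boundaries
#'
#' A power-on boundary is the first recorded minute of a series and every
#' recorded minute following a row gap larger than `gap_threshold` minutes.
#' The first `n` minutes of data after each boundary are discarded (warm-up
#' transient of electrochemical cells). Discarding invalidates the values
#' (rows are kept with a missing value) so that boundaries do not shift and
#' re-curation of already-curated data removes nothing further.
#'
#' @param series A `wx_series` tibble.
#' @param n Warm-up length in minutes (>= 0).
#' @param gap_threshold Gap defining a power-on boundary, minutes.
#' @return List with `series` (warm-up values set missing) and `removed`
#'   (the previously non-missing rows that were invalidated).
#' @export
trim_warmup <- function(series, n = 3, gap_threshold = 10) {
  if (n < 0) abort("n must be >= 0", class = "wx_config_error")
  if (n == 0 || nrow(series) == 0) {
    return(list(series = series, removed = series[0, c("timestamp", "value")]))
  }
  t <- as.double(series$timestamp)
  gap <- c(Inf, diff(t) / 60)
  boundaries <- t[gap > gap_threshold]
  inwin <- rep(FALSE, nrow(series))
  for (b in boundaries) {
    inwin <- inwin | (t >= b & t < b + n * 60)
  }
  removed <- series[inwin & !is.na(series$value), c("timestamp", "value")]
  series$value[inwin] <- NA_real_
  list(series = series, removed = removed)
}

#' Apply the black-carbon noise floor
#'
#' Values below the floor are removed; small negative values at or above the
#' floor are retained to preserve the instrument's measurement variability.
#'
#' @param series A `wx_series` tibble.
#' @param floor Floor in ng/m3 (negative; boundary inclusive).
#' @param invalidate Set removed values to missing instead of dropping rows.
#' @return List with `series` and `removed`.
#' @export
floor_bc <- function(series, floor = -1500, invalidate = FALSE) {
  if (floor >= 0) abort("floor must be negative", class = "wx_config_error")
  v <- series$value
  drop_rows(series, !is.na(v) & v < floor, invalidate)
}

#' Denoise a GPS track with a sequential speed filter
#'
#' Single forward pass: the great-circle (haversine) speed from the last
#' retained point to each candidate is computed; candidates implying a speed
#' above `vmax` are dropped, as are candidates with zero time delta but
#' nonzero displacement. After the pass every consecutive retained pair
#' implies a speed of at most `vmax`.
#'
#' @param track A `wx_track` tibble, time-sorted.
#' @param vmax Speed threshold, km/h.
#' @return List with `track` and `removed`.
#' @export
denoise_gps <- function(track, vmax = 130) {
  n <- nrow(track)
  if (n <= 1) return(list(track = track, removed = track[0, ]))
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  tsec <- as.double(track$timestamp)
  p <- cbind(track$lon, track$lat)
  for (i in 2:n) {
    dt <- tsec[i] - tsec[last]
    d <- geosphere::distHaversine(p[last, ], p[i, ])
    if (dt <= 0) {
      if (d > 0) next          # zero time delta, nonzero displacement: drop
      keep[i] <- TRUE; last <- i; next
    }
    if ((d / 1000) / (dt / 3600) > vmax) next
    keep[i] <- TRUE; last <- i
  }
  list(track = track[keep, , drop = FALSE], removed = track[!keep, , drop = FALSE])
}

#' Per-minute mean speed from a denoised track
#'
#' Speeds of consecutive-point segments are assigned to the minute containing
#' the segment midpoint and averaged per minute. Minutes without any segment
#' are absent from the result.
#'
#' @param track A denoised `wx_track`.
#' @return A `wx_series` with channel `"speed"` (km/h).
#' @export
per_minute_speed <- function(track) {
  n <- nrow(track)
  pid <- if (n > 0) track$participant_id[1] else "p1"
  if (n < 2) {
    return(sensor_series(track$timestamp[0], double(0), "speed", participant_id = pid))
  }
  p1 <- cbind(track$lon[-n], track$lat[-n])
  p2 <- cbind(track$lon[-1], track$lat[-1])
  d <- geosphere::distHaversine(p1, p2)
  dt <- as.double(diff(track$timestamp), units = "secs")
  mid <- track$timestamp[-n] + dt / 2
  segs <- tibble(minute = floor_minute(mid),
                 speed = (d / 1000) / (dt / 3600)) %>%
    filter(is.finite(.data$speed)) %>%
    group_by(.data$minute) %>%
    summarise(speed = mean(.data$speed), .groups = "drop")
  sensor_series(segs$minute, segs$speed, "speed", participant_id = pid)
}

#' Fuse curated channels into a single per-minute table
#'
#' Builds the per-minute multi-channel table: one row per minute carrying at
#' least one of the seven sensor measurements (a minute with only GPS or
#' speed data does not form a row). Sub-minute GPS samples are reduced to a
#' per-minute centroid position, and labels are assigned from the covering
#' annotation interval.
#'
#' @param channels Named list of `wx_series` (sensor channels).
#' @param speed Optional `wx_series` of per-minute speed.
#' @param gps Optional `wx_track` for per-minute positions.
#' @param annotations Optional annotation tibble `start,end,label`
#'   (non-overlapping; checked before fusion).
#' @param participant_id Identifier stored in the table.
#' @return A fused table tibble.
#' @export
fuse <- function(channels, speed = NULL, gps = NULL, annotations = NULL,
                 participant_id = NULL) {
  if (!is.null(annotations)) validate_annotations(annotations)
  pid <- participant_id %||%
    purrr::map_chr(channels, ~ .x$participant_id[1] %||% "p1")[1]
  wide <- purrr::imap(channels, function(s, ch) {
    s %>% select("timestamp", !!ch := "value")
  }) %>%
    purrr::reduce(full_join, by = "timestamp")
  for (ch in setdiff(sensor_channels(), names(wide))) wide[[ch]] <- NA_real_
  sens <- as.matrix(wide[sensor_channels()])
  wide <- wide[rowSums(!is.na(sens)) > 0, , drop = FALSE]
  if (!is.null(speed) && nrow(speed) > 0) {
    wide <- left_join(wide, speed %>% select("timestamp", speed = "value"),
                      by = "timestamp")
  } else {
    wide$speed <- NA_real_
  }
  if (!is.null(gps) && nrow(gps) > 0) {
    pos <- gps %>%
      mutate(minute = floor_minute(.data$timestamp)) %>%
      group_by(.data$minute) %>%
      summarise(lon = mean(.data$lon), lat = mean(.data$lat), .groups = "drop")
    wide <- left_join(wide, pos, by = c(timestamp = "minute"))
  } else {
    wide$lon <- NA_real_
    wide$lat <- NA_real_
  }
  wide$label <- if (!is.null(annotations)) {
    label_minutes(wide$timestamp, annotations)
  } else NA_character_
  out <- wide %>%
    arrange(.data$timestamp) %>%
    select(all_of(fused_columns()))
  out$participant_id <- pid
  out
}

#' Run the full curation chain on a participant bundle
#'
#' Applies, in a frozen order: NO2 warm-up trim, range filtering, windowed
#' peak removal, the BC noise floor, particle-size ordering, the GPS speed
#' filter, per-minute speed derivation, and fusion into a single per-minute
#' table. Every rule's removals are counted per channel, and each removed
#' point is recorded so lossy steps are fully auditable.
#'
#' @param bundle A `wx_bundle` (list with `sensors`, `gps`, `annotations`) as
#'   produced by [generate_traces()], or any list with those elements.
#' @param config A [curation_config()].
#' @return A list of class `wx_curation` with elements `table` (fused table)
#'   and `report` (per-rule counts, removed fraction, removed points, GPS
#'   removals).
#' @export
curate <- function(bundle, config = curation_config()) {
  stopifnot(inherits(config, "wx_curation_config"))
  sensors <- bundle$sensors
  input_values <- sum(purrr::map_int(sensors, ~ sum(!is.na(.x$value))))
  removed_points <- list()
  note <- function(ch, rule, removed) {
    if (nrow(removed) > 0) {
      removed_points[[length(removed_points) + 1]] <<-
        removed %>% mutate(channel = ch, rule = rule)
    }
  }

  if ("no2" %in% names(sensors) && config$warmup_minutes > 0) {
    r <- trim_warmup(sensors$no2, config$warmup_minutes, config$warmup_gap)
    note("no2", "warmup", r$removed)
    sensors$no2 <- r$series
  }
  for (ch in names(sensors)) {
    lim <- config$range_limits[[ch]]
    if (!is.null(lim)) {
      r <- apply_range_filter(sensors[[ch]], lim, invalidate = TRUE)
      note(ch, "range", r$removed)
      sensors[[ch]] <- r$series
    }
  }
  # peak removal can expose a neighbouring excursion, so the rule is applied
  # to convergence; removed values are invalidated in place
  for (ch in names(sensors)) {
    repeat {
      mask <- detect_peaks(sensors[[ch]], config$k, config$f)
      if (!any(mask)) break
      r <- drop_rows(sensors[[ch]], mask, invalidate = TRUE)
      note(ch, "peak", r$removed)
      sensors[[ch]] <- r$series
    }
  }
  if ("bc" %in% names(sensors)) {
    r <- floor_bc(sensors$bc, config$bc_floor, invalidate = TRUE)
    note("bc", "bc_floor", r$removed)
    sensors$bc <- r$series
  }
  if (all(c("pm1", "pm25", "pm10") %in% names(sensors))) {
    r <- enforce_pm_ordering(sensors$pm1, sensors$pm25, sensors$pm10,
                             invalidate = TRUE)
    for (ch in c("pm1", "pm25", "pm10")) {
      note(ch, "pm_order", r$removed %>% mutate(value = NA_real_))
      sensors[[ch]] <- r[[ch]]
    }
  }

  gps <- bundle$gps
  gps_removed <- 0L
  speed <- NULL
  if (!is.null(gps) && nrow(gps) > 0) {
    g <- denoise_gps(gps, config$gps_vmax)
    gps <- g$track
    gps_removed <- nrow(g$removed)
    speed <- per_minute_speed(gps)
  }

  table <- fuse(sensors, speed = speed, gps = gps,
                annotations = bundle$annotations,
                participant_id = bundle$participant_id)

  removed_points <- if (length(removed_points) > 0) {
    bind_rows(removed_points) %>% select("channel", "rule", "timestamp", "value")
  } else {
    tibble(channel = character(), rule = character(),
           timestamp = lubridate::ymd_hms(character(), tz = "UTC"), value = double())
  }
  counts <- removed_points %>%
    count(.data$channel, .data$rule, name = "removed") %>%
    tidyr::complete(channel = names(bundle$sensors),
                    rule = c("peak", "range", "pm_order", "warmup", "bc_floor"),
                    fill = list(removed = 0L))
  report <- structure(list(
    counts = counts,
    total_removed = nrow(removed_points),
    input_values = input_values,
    fraction_removed = nrow(removed_points) / max(input_values, 1),
    removed_points = removed_points,
    gps_removed = gps_removed
  ), class = "wx_removal_report")
  structure(list(table = table, report = report), class = "wx_curation")
}

#' Rebuild a participant bundle from a fused table
#'
#' Splits a fused table back into per-channel series (one row per table
#' minute, missing values preserved), e.g. to feed an already-curated table
#' through [curate()] again. The GPS track cannot be reconstructed from
#' per-minute centroids and is left empty.
#'
#' @param table A fused table.
#' @param annotations Optional annotation tibble.
#' @return A list of class `wx_bundle`.
#' @export
as_bundle <- function(table, annotations = NULL) {
  pid <- if ("participant_id" %in% names(table)) table$participant_id[1] else "p1"
  sensors <- purrr::map(setNames(sensor_channels(), sensor_channels()), function(ch) {
    sensor_series(table$timestamp, table[[ch]], ch, participant_id = pid)
  })
  structure(list(sensors = sensors, gps = NULL, annotations = annotations,
                 participant_id = pid),
            class = "wx_bundle")
}

#' @export
print.wx_removal_report <- function(x, ...) {
  cat("Curation removal report\n")
  cat(sprintf("  input values: %d, removed: %d (%.2f%%), GPS points removed: %d\n",
              x$input_values, x$total_removed, 100 * x$fraction_removed,
              x$gps_removed))
  print(x$counts %>% filter(.data$removed > 0))
  invisible(x)
}
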