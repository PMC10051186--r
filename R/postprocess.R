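#' Build a spatial density grid from per-minute positions
#'
#' Positions are projected with a local equirectangular projection around
#' the track centroid (adequate at city scale) and binned into square cells;
#' the per-cell count of located minutes is the density. Counts are
#' conserved: they sum to the number of located minutes.
#'
#' @param positions Tibble with `lon`, `lat` columns (rows with missing
#'   position are ignored).
#' @param cell_m Cell size in metres.
#' @return An object of class `wx_grid` with the cell table and projection
#'   parameters.
#' @export
build_density_grid <- function(positions, cell_m = 100) {
  located <- positions %>% filter(!is.na(.data$lon), !is.na(.data$lat))
  if (nrow(located) == 0) abort("no located minutes", class = "wx_config_error")
  lon0 <- mean(located$lon)
  lat0 <- mean(located$lat)
  g <- structure(list(lon0 = lon0, lat0 = lat0, cell_m = cell_m,
                      mx = 111320 * cos(lat0 * pi / 180), my = 110574),
                 class = "wx_grid")
  key <- grid_cell(g, located$lon, located$lat)
  g$cells <- tibble(cell = key) %>% count(.data$cell, name = "count")
  g$n_points <- nrow(located)
  g
}

#' @rdname build_density_grid
#' @param grid A `wx_grid`.
#' @param lon,lat Coordinates to map to cell keys.
#' @export
grid_cell <- function(grid, lon, lat) {
  cx <- floor((lon - grid$lon0) * grid$mx / grid$cell_m)
  cy <- floor((lat - grid$lat0) * grid$my / grid$cell_m)
  ifelse(is.na(cx) | is.na(cy), NA_character_, paste(cx, cy, sep = ":"))
}

#' Segment a labelled track into stops and moves
#'
#' Minutes lying in grid cells at or above the `stop_quantile` of the cell
#' count distribution, with speed below `stop_speed_kmh` (or unknown), are
#' stop candidates; runs of at least `min_stop_minutes` candidates become
#' stop segments and everything else becomes move segments. Segments tile
#' the table's rows without overlap. The default quantile is the median:
#' at one-minute GPS cadence the cell population mixes a handful of dense
#' site pixels with transit pixels only a few counts high, so the median
#' separates them while the speed and duration gates exclude slow transit.
#'
#' @param table Fused table rows of one participant, time-sorted, with a
#'   `label` column (typically model predictions).
#' @param grid A `wx_grid` built from the same table.
#' @param stop_quantile Density quantile defining stops.
#' @param min_stop_minutes Minimum stop length, minutes.
#' @param stop_speed_kmh Speed below which a minute can belong to a stop;
#'   the default sits below walking pace but above the apparent speed of
#'   GPS jitter, so outdoor strolling near a site is not swallowed into its
#'   stop.
#' @return A tibble of segments: `segment, kind, start, end, n, modal_label,
#'   lon, lat, cell` (`end` is the minute after the last row of the
#'   segment).
#' @export
segment_stops <- function(table, grid, stop_quantile = 0.5,
                          min_stop_minutes = 5, stop_speed_kmh = 2) {
  cell <- grid_cell(grid, table$lon, table$lat)
  dens <- grid$cells$count[match(cell, grid$cells$cell)]
  thr <- quantile(grid$cells$count, stop_quantile, names = FALSE)
  slow <- is.na(table$speed) | table$speed < stop_speed_kmh
  cand <- !is.na(dens) & dens >= thr & slow
  r <- rle(cand)
  is_stop <- r$values & r$lengths >= min_stop_minutes
  seg_id <- rep(seq_along(r$lengths), r$lengths)
  # merge adjacent non-stop runs into single move segments
  kind <- ifelse(is_stop, "stop", "move")[seg_id]
  seg2 <- cumsum(c(TRUE, kind[-1] != kind[-length(kind)] |
                     (kind[-1] == "stop" &
                        seg_id[-1] != seg_id[-length(seg_id)])))
  tibble(row = seq_len(nrow(table)), segment = seg2, kind = kind,
         timestamp = table$timestamp, label = table$label,
         lon = table$lon, lat = table$lat) %>%
    group_by(.data$segment, .data$kind) %>%
    summarise(start = min(.data$timestamp),
              end = max(.data$timestamp) + 60,
              n = n(),
              modal_label = modal_value(.data$label),
              lon = mean(.data$lon, na.rm = TRUE),
              lat = mean(.data$lat, na.rm = TRUE),
              first_row = min(.data$row), last_row = max(.data$row),
              .groups = "drop") %>%
    mutate(cell = grid_cell(grid, .data$lon, .data$lat)) %>%
    arrange(.data$start)
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1]
}

#' Identify the home site from night-time density and relabel home stops
#'
#' The home site is the grid cell (or cells, on ties) with the highest count
#' of located minutes between 02:00 and 05:00 local clock time across the
#' participant's whole record. Stop segments sitting in a home cell or one
#' of its eight neighbours are relabelled `home` — site identity must
#' tolerate a one-cell offset, since grid quantisation can split a single
#' physical site across a cell boundary. With no located night-time minutes
#' the rule is skipped with a warning.
#'
#' @param segments Segment tibble from [segment_stops()].
#' @param table The same participant's fused table.
#' @param grid The `wx_grid` used for segmentation.
#' @param night Numeric `c(from, to)` local hours of the night window.
#' @param tz Time zone used to interpret local clock time.
#' @return `segments` with `modal_label` re-labelled and a logical
#'   `home_rule` column marking changed segments.
#' @export
apply_home_rule <- function(segments, table, grid, night = c(2, 5),
                            tz = "Europe/Paris") {
  hr <- lubridate::hour(lubridate::with_tz(table$timestamp, tz))
  at_night <- hr >= night[1] & hr < night[2] & !is.na(table$lon) & !is.na(table$lat)
  segments$home_rule <- FALSE
  if (!any(at_night)) {
    warn("no located minutes in the night window; home rule skipped")
    return(segments)
  }
  counts <- tibble(cell = grid_cell(grid, table$lon[at_night], table$lat[at_night])) %>%
    count(.data$cell, name = "n")
  home_cells <- counts$cell[counts$n == max(counts$n)]
  home_area <- unique(unlist(lapply(strsplit(home_cells, ":", fixed = TRUE),
                                    function(p) {
    cx <- as.integer(p[1])
    cy <- as.integer(p[2])
    as.vector(outer(cx + (-1:1), cy + (-1:1), paste, sep = ":"))
  })))
  hit <- segments$kind == "stop" & segments$cell %in% home_area
  segments$home_rule <- hit &
    (is.na(segments$modal_label) | segments$modal_label != "home")
  segments$modal_label[hit] <- "home"
  segments
}

#' Smooth a minute-level label sequence
#'
#' Label runs shorter than `min_bout` are absorbed into the adjoining longer
#' run (shortest runs first; ties prefer the earlier neighbour). Missing
#' labels are left untouched and never absorb their neighbours. The
#' operation is idempotent.
#'
#' @param labels Character vector of labels (`NA` allowed).
#' @param min_bout Minimum run length, minutes.
#' @return The smoothed label vector.
#' @export
smooth_labels <- function(labels, min_bout = 3) {
  n <- length(labels)
  if (n == 0 || min_bout <= 1) return(labels)
  sent <- "\r<na>"
  x <- ifelse(is.na(labels), sent, labels)
  skip <- character(0)
  repeat {
    r <- rle(x)
    len <- r$lengths
    lab <- r$values
    k <- length(len)
    cand <- which(lab != sent & len < min_bout &
                    !paste(cumsum(len), lab) %in% skip)
    if (length(cand) == 0 || k == 1) break
    i <- cand[order(len[cand])][1]
    prev <- if (i > 1 && lab[i - 1] != sent) i - 1 else NA
    nxt <- if (i < k && lab[i + 1] != sent) i + 1 else NA
    target <- if (is.na(prev) && is.na(nxt)) NA
    else if (is.na(nxt)) prev
    else if (is.na(prev)) nxt
    else if (len[nxt] > len[prev]) nxt else prev
    if (is.na(target)) {
      skip <- c(skip, paste(cumsum(len)[i], lab[i]))
      next
    }
    r$values[i] <- lab[target]
    x <- inverse.rle(r)
  }
  out <- ifelse(x == sent, NA_character_, x)
  out
}

#' Rule-based post-processing of model labels
#'
#' Applies, per participant: (1) stop segmentation on the density grid with
#' a modal-label vote inside each stop segment, (2) the night-time home
#' rule, and (3) minute-level label smoothing. The stop vote only overrides
#' label runs that lie entirely inside the segment and are shorter than
#' `min_stop_minutes`: flickering disagreement is corrected, while
#' sustained sub-episodes and runs crossing the segment boundary (arrival
#' and departure minutes of a genuinely different environment) are left
#' alone. The home rule, whose job is to fix sustained misclassification at
#' the home site, overrides unconditionally. Participants without located
#' minutes only get the smoothing step.
#'
#' @param table Fused table (may span several participants) aligned with
#'   `labels`.
#' @param labels Character vector of model labels, one per table row.
#' @param cell_m,stop_quantile,min_stop_minutes,stop_speed_kmh,min_bout,night,tz
#'   Post-processing parameters; see the individual rule functions.
#' @return A list of class `wx_postprocess` with `labels` (corrected vector)
#'   and `report` (minutes changed per rule).
#' @export
postprocess_labels <- function(table, labels, cell_m = 100,
                               stop_quantile = 0.5, min_stop_minutes = 5,
                               stop_speed_kmh = 2, min_bout = 3,
                               night = c(2, 5), tz = "Europe/Paris") {
  stopifnot(length(labels) == nrow(table))
  if (!"participant_id" %in% names(table)) table$participant_id <- "p1"
  changed <- c(stop_vote = 0L, home_rule = 0L, smoothing = 0L)
  out <- labels
  for (pid in unique(table$participant_id)) {
    rows <- which(table$participant_id == pid)
    tb <- table[rows, ]
    tb$label <- labels[rows]
    lab <- tb$label
    if (any(!is.na(tb$lon) & !is.na(tb$lat))) {
      grid <- build_density_grid(tb, cell_m = cell_m)
      segs <- segment_stops(tb, grid, stop_quantile, min_stop_minutes,
                            stop_speed_kmh)
      segs <- apply_home_rule(segs, tb, grid, night = night, tz = tz)
      stops <- segs %>% filter(.data$kind == "stop", !is.na(.data$modal_label))
      # run structure of the raw model labels, for the contained-run guard
      rr <- rle(ifelse(is.na(lab), "
<na>", lab))
      run_len <- rep(rr$lengths, rr$lengths)
      run_last <- rep(cumsum(rr$lengths), rr$lengths)
      run_first <- run_last - run_len + 1L
      for (i in seq_len(nrow(stops))) {
        idx <- stops$first_row[i]:stops$last_row[i]
        new <- stops$modal_label[i]
        if (stops$home_rule[i]) {
          ov <- idx[!is.na(lab[idx]) & lab[idx] != new]
          changed["home_rule"] <- changed["home_rule"] + length(ov)
        } else {
          ov <- idx[!is.na(lab[idx]) & lab[idx] != new &
                      run_first[idx] >= idx[1] & run_last[idx] <= idx[length(idx)] &
                      run_len[idx] < min_stop_minutes]
          changed["stop_vote"] <- changed["stop_vote"] + length(ov)
        }
        lab[ov] <- new
      }
    }
    sm <- smooth_labels(lab, min_bout)
    changed["smoothing"] <- changed["smoothing"] +
      sum(!is.na(lab) & !is.na(sm) & sm != lab)
    out[rows] <- sm
  }
  structure(list(labels = out,
                 report = tibble(rule = names(changed),
                                 minutes_changed = as.integer(changed))),
            class = "wx_postprocess")
}
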