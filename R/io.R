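#' Construct a per-minute sensor series
#'
#' A sensor series is a tibble with columns `timestamp` (POSIXct, UTC),
#' `value` (double, `NA` allowed), `channel`, `participant_id` and
#' `sensor_id`. Timestamps must be strictly increasing with spacing of at
#' least one minute.
#'
#' @param timestamp POSIXct vector (converted to UTC).
#' @param value Numeric vector, same length as `timestamp`.
#' @param channel One of [sensor_channels()] (or `"speed"` for derived
#'   series).
#' @param participant_id,sensor_id Opaque identifier strings.
#' @return A tibble of class `wx_series`.
#' @export
sensor_series <- function(timestamp, value, channel,
                          participant_id = "p1", sensor_id = channel) {
  if (!channel %in% model_channels()) {
    abort(paste0("unknown channel '", channel, "'"), class = "wx_config_error")
  }
  if (length(timestamp) != length(value)) {
    abort("timestamp and value must have equal length", class = "wx_config_error")
  }
  timestamp <- lubridate::with_tz(timestamp, "UTC")
  out <- tibble(
    timestamp = timestamp, value = as.double(value),
    channel = channel, participant_id = participant_id, sensor_id = sensor_id
  ) %>% arrange(.data$timestamp)
  if (nrow(out) > 1) {
    dt <- as.double(diff(out$timestamp), units = "secs")
    if (any(dt < 60)) {
      abort("sensor series timestamps must be strictly increasing with >= 1 minute spacing",
            class = "wx_invariant_error")
    }
  }
  class(out) <- c("wx_series", class(out))
  out
}

#' Construct a GPS track
#'
#' @param timestamp POSIXct vector (non-decreasing; sub-minute cadence
#'   allowed).
#' @param lon,lat WGS84 decimal degrees.
#' @param participant_id Identifier string.
#' @return A tibble of class `wx_track`.
#' @export
gps_track <- function(timestamp, lon, lat, participant_id = "p1") {
  if (any(lat < -90 | lat > 90, na.rm = TRUE)) {
    abort("latitude out of [-90, 90]", class = "wx_range_error")
  }
  if (any(lon < -180 | lon > 180, na.rm = TRUE)) {
    abort("longitude out of [-180, 180]", class = "wx_range_error")
  }
  out <- tibble(
    timestamp = lubridate::with_tz(timestamp, "UTC"),
    lon = as.double(lon), lat = as.double(lat),
    participant_id = participant_id
  ) %>% arrange(.data$timestamp)
  class(out) <- c("wx_track", class(out))
  out
}

floor_minute <- function(t) lubridate::floor_date(t, "minute")

parse_iso_times <- function(x, what = "timestamp") {
  t <- readr::parse_datetime(x)
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad) > 0) {
    abort(paste0("malformed ", what, " at line ", bad[1] + 1L, ": '", x[bad[1]], "'"),
          class = "wx_parse_error")
  }
  lubridate::with_tz(t, "UTC")
}

#' Read a single-channel sensor CSV
#'
#' Expects columns `timestamp,value` with ISO-8601 timestamps. Rows are
#' sorted by time; exact duplicate timestamps keep the last occurrence
#' (count reported via a message); samples are then floored to the containing
#' minute and averaged within each minute.
#'
#' @param path CSV file path.
#' @param channel One of [sensor_channels()].
#' @param participant_id,sensor_id Identifiers attached to the series.
#' @return A `wx_series` tibble.
#' @export
read_sensor_csv <- function(path, channel, participant_id = "p1",
                            sensor_id = channel) {
  if (!channel %in% sensor_channels()) {
    abort(paste0("unknown channel '", channel, "'"), class = "wx_config_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("empty sensor file: ", path), class = "wx_parse_error")
  }
  if (!all(c("timestamp", "value") %in% names(raw))) {
    abort("sensor CSV must have columns timestamp,value", class = "wx_parse_error")
  }
  t <- parse_iso_times(raw$timestamp)
  v <- readr::parse_double(raw$value)
  df <- tibble(timestamp = t, value = v) %>% arrange(.data$timestamp)
  ndup <- sum(duplicated(df$timestamp))
  if (ndup > 0) {
    inform(paste0(ndup, " duplicate timestamp(s) collapsed (kept last) in ", path))
    df <- df %>%
      group_by(.data$timestamp) %>% slice(n()) %>% ungroup()
  }
  df <- df %>%
    mutate(timestamp = floor_minute(.data$timestamp)) %>%
    group_by(.data$timestamp) %>%
    summarise(value = if (all(is.na(.data$value))) NA_real_ else
      mean(.data$value, na.rm = TRUE), .groups = "drop")
  sensor_series(df$timestamp, df$value, channel, participant_id, sensor_id)
}

#' Read a GPS track from CSV or GeoJSON
#'
#' The CSV dialect has columns `timestamp,lon,lat` (ISO-8601). The GeoJSON
#' dialect accepts a FeatureCollection of Point features carrying a `time`
#' property, or a (Multi)Feature LineString whose properties carry a `times`
#' array aligned with the coordinates.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"geojson"`.
#' @param participant_id Identifier attached to the track.
#' @return A `wx_track` tibble sorted by time.
#' @export
read_gps <- function(path, dialect = c("csv", "geojson"), participant_id = "p1") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (!all(c("timestamp", "lon", "lat") %in% names(raw))) {
      abort("GPS CSV must have columns timestamp,lon,lat", class = "wx_parse_error")
    }
    t <- parse_iso_times(raw$timestamp)
    lon <- readr::parse_double(raw$lon)
    lat <- readr::parse_double(raw$lat)
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- if (identical(gj$type, "FeatureCollection")) gj$features
             else if (identical(gj$type, "Feature")) list(gj)
             else abort("GeoJSON root must be a Feature or FeatureCollection",
                        class = "wx_parse_error")
    pts <- purrr::map(feats, function(f) {
      geom <- f$geometry
      if (is.null(geom) || is.null(geom$type)) {
        abort("GeoJSON feature missing geometry", class = "wx_parse_error")
      }
      if (geom$type == "Point") {
        tm <- f$properties$time %||% abort("Point feature missing 'time' property",
                                           class = "wx_parse_error")
        tibble(time = tm,
               lon = geom$coordinates[[1]], lat = geom$coordinates[[2]])
      } else if (geom$type == "LineString") {
        times <- f$properties$times %||% f$properties$time %||%
          abort("LineString feature missing 'times' property", class = "wx_parse_error")
        coords <- geom$coordinates
        if (length(times) != length(coords)) {
          abort("LineString 'times' length differs from coordinates", class = "wx_parse_error")
        }
        tibble(time = purrr::map_chr(times, identity),
               lon = purrr::map_dbl(coords, 1), lat = purrr::map_dbl(coords, 2))
      } else {
        abort(paste0("unsupported GeoJSON geometry: ", geom$type), class = "wx_parse_error")
      }
    }) %>% bind_rows()
    t <- parse_iso_times(pts$time)
    lon <- pts$lon
    lat <- pts$lat
  }
  gps_track(t, lon, lat, participant_id = participant_id)
}

#' Read or write an annotation set
#'
#' Annotations are intervals `start,end,label` with labels among
#' [environment_classes()]. Intervals must be non-overlapping and satisfy
#' `start < end`.
#'
#' @param path CSV file path.
#' @param annotations A tibble with columns `start`, `end`, `label`.
#' @return `read_annotations()` returns the annotation tibble.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("start", "end", "label") %in% names(raw))) {
    abort("annotation CSV must have columns start,end,label", class = "wx_parse_error")
  }
  out <- tibble(
    start = parse_iso_times(raw$start, "start"),
    end = parse_iso_times(raw$end, "end"),
    label = raw$label
  )
  validate_annotations(out)
  out
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_csv(
    annotations %>% mutate(
      start = format(.data$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      end = format(.data$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ),
    path)
  invisible(path)
}

validate_annotations <- function(annotations) {
  if (!all(annotations$label %in% environment_classes())) {
    abort("annotation labels must be among environment_classes()",
          class = "wx_config_error")
  }
  if (any(annotations$end <= annotations$start)) {
    abort("annotation intervals must satisfy start < end", class = "wx_invariant_error")
  }
  a <- annotations %>% arrange(.data$start)
  if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)])) {
    abort("annotation intervals overlap", class = "wx_invariant_error")
  }
  invisible(annotations)
}

#' Validate a fused per-minute table
#'
#' Checks the fused-table invariants: every row carries at least one of the
#' seven sensor measurements (GPS-derived speed or position alone does not
#' qualify a row), and wherever all three particle channels are present they
#' satisfy `pm1 <= pm25 <= pm10`.
#'
#' @param table A fused table tibble.
#' @return The table, invisibly; errors on invariant breach.
#' @export
validate_fused_table <- function(table) {
  miss <- setdiff(fused_columns(), names(table))
  if (length(miss) > 0) {
    abort(paste0("fused table missing columns: ", paste(miss, collapse = ", ")),
          class = "wx_parse_error")
  }
  sens <- as.matrix(table[sensor_channels()])
  if (any(rowSums(!is.na(sens)) == 0)) {
    abort("fused table row with all sensor channels missing", class = "wx_invariant_error")
  }
  all3 <- !is.na(table$pm1) & !is.na(table$pm25) & !is.na(table$pm10)
  if (any(all3 & !(table$pm1 <= table$pm25 & table$pm25 <= table$pm10))) {
    abort("fused table violates pm1 <= pm25 <= pm10", class = "wx_invariant_error")
  }
  invisible(table)
}

#' Write and read a fused table CSV
#'
#' The on-disk format is a CSV with fixed header order
#' `timestamp,temperature,humidity,pm1,pm25,pm10,no2,bc,speed,lon,lat,label`
#' (a `participant_id` column, when present, is appended last). Missing
#' values round-trip as empty fields.
#'
#' @param table A fused table satisfying [validate_fused_table()].
#' @param path CSV file path.
#' @return `read_fused_table()` returns the fused table tibble.
#' @export
write_fused_table <- function(table, path) {
  validate_fused_table(table)
  cols <- c(fused_columns(), intersect("participant_id", names(table)))
  out <- table %>%
    select(all_of(cols)) %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_fused_table
#' @export
read_fused_table <- function(path) {
  spec <- readr::cols(
    timestamp = readr::col_character(),
    label = readr::col_character(),
    participant_id = readr::col_character(),
    .default = readr::col_double()
  )
  raw <- readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  out <- raw %>% mutate(timestamp = parse_iso_times(.data$timestamp))
  if ("participant_id" %in% names(raw)) {
    out$participant_id <- as.character(raw$participant_id)
  }
  validate_fused_table(out)
  out
}

# Per-minute environment labels from an annotation set; NA outside intervals.
#' Label minutes from annotation intervals
#'
#' @param timestamps POSIXct minute instants.
#' @param annotations Tibble `start,end,label`; intervals are treated as
#'   half-open `[start, end)`.
#' @return Character vector of labels (`NA` where uncovered).
#' @export
label_minutes <- function(timestamps, annotations) {
  validate_annotations(annotations)
  lab <- rep(NA_character_, length(timestamps))
  for (i in seq_len(nrow(annotations))) {
    inside <- timestamps >= annotations$start[i] & timestamps < annotations$end[i]
    lab[inside] <- annotations$label[i]
  }
  lab
}
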