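#' Daily means with a completeness rule
#'
#' Computes one mean per participant-day for a channel; a day enters only if
#' strictly more than `min_completeness` of its 1440 minutes carry a value
#' (representativeness rule; exactly the threshold is excluded). Days are
#' delimited in local clock time.
#'
#' @param table Fused table (optionally multi-participant).
#' @param channel Channel name.
#' @param min_completeness Fraction in `(0, 1]`.
#' @param tz Time zone delimiting days.
#' @return Tibble `participant_id, date, n_minutes, completeness, mean`.
#' @export
daily_means <- function(table, channel, min_completeness = 0.2,
                        tz = "Europe/Paris") {
  stopifnot(min_completeness > 0, min_completeness <= 1)
  if (!"participant_id" %in% names(table)) table$participant_id <- "p1"
  table %>%
    mutate(date = lubridate::as_date(lubridate::with_tz(.data$timestamp, tz))) %>%
    filter(!is.na(.data[[channel]])) %>%
    group_by(.data$participant_id, .data$date) %>%
    summarise(n_minutes = n(), mean = mean(.data[[channel]]), .groups = "drop") %>%
    mutate(completeness = .data$n_minutes / 1440) %>%
    filter(.data$completeness > min_completeness) %>%
    select("participant_id", "date", "n_minutes", "completeness", "mean")
}

#' Multi-resolution exposure statistics
#'
#' The campaign-style summary for one channel: the pooled mean of qualifying
#' daily means; the mean, SD and median of hourly means (each hour needing
#' at least one observation); and the 95th percentile of raw minute values.
#' Percentiles use linear interpolation between order statistics.
#'
#' @inheritParams daily_means
#' @return One-row tibble `day_mean, hour_mean, hour_sd, hour_median,
#'   minute_p95, n_days, n_hours, n_minutes`.
#' @export
resolution_stats <- function(table, channel, min_completeness = 0.2,
                             tz = "Europe/Paris") {
  v <- table[[channel]]
  if (all(is.na(v))) abort("no observations for channel", class = "wx_config_error")
  dm <- daily_means(table, channel, min_completeness, tz)
  if (!"participant_id" %in% names(table)) table$participant_id <- "p1"
  hourly <- table %>%
    filter(!is.na(.data[[channel]])) %>%
    mutate(hour = lubridate::floor_date(.data$timestamp, "hour")) %>%
    group_by(.data$participant_id, .data$hour) %>%
    summarise(mean = mean(.data[[channel]]), .groups = "drop")
  minutes <- v[!is.na(v)]
  tibble(
    channel = channel,
    day_mean = mean(dm$mean),
    hour_mean = mean(hourly$mean),
    hour_sd = sd(hourly$mean),
    hour_median = median(hourly$mean),
    minute_p95 = quantile(minutes, 0.95, names = FALSE, type = 7),
    n_days = nrow(dm), n_hours = nrow(hourly), n_minutes = length(minutes)
  )
}

#' Per-environment boxplot statistics
#'
#' Minute-level distribution per environment label: percentiles p10, p25,
#' p50, p75, p90 (whisker/box/median convention of the campaign figures)
#' plus the mean and support. Environments with fewer than 30 minutes are
#' flagged low-support.
#'
#' @param table Fused table with final labels in `label`.
#' @param channel Channel name.
#' @return Tibble of class `wx_env_stats`, one row per environment.
#' @export
environment_stats <- function(table, channel) {
  labelled <- table %>% filter(!is.na(.data$label), !is.na(.data[[channel]]))
  if (nrow(labelled) == 0) abort("no labelled minutes", class = "wx_config_error")
  out <- labelled %>%
    group_by(environment = .data$label) %>%
    summarise(
      n = n(),
      p10 = quantile(.data[[channel]], 0.10, names = FALSE),
      p25 = quantile(.data[[channel]], 0.25, names = FALSE),
      p50 = quantile(.data[[channel]], 0.50, names = FALSE),
      p75 = quantile(.data[[channel]], 0.75, names = FALSE),
      p90 = quantile(.data[[channel]], 0.90, names = FALSE),
      mean = mean(.data[[channel]]),
      .groups = "drop"
    ) %>%
    mutate(channel = channel, low_support = .data$n < 30)
  class(out) <- c("wx_env_stats", class(out))
  out
}

#' Time budget over environments
#'
#' Fraction of labelled minutes spent in each environment; fractions sum
#' to 1.
#'
#' @param labels Character vector of final labels (or a fused table with a
#'   `label` column).
#' @return Tibble `environment, minutes, fraction`.
#' @export
time_budget <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) abort("no labelled minutes", class = "wx_config_error")
  tibble(environment = labels) %>%
    count(.data$environment, name = "minutes") %>%
    mutate(fraction = .data$minutes / sum(.data$minutes))
}

#' WHO 24-hour air-quality guideline values
#'
#' 24-hour guideline levels: NO2 25, PM2.5 15 and PM10 45 micrograms per
#' cubic metre. PM1 and BC carry no guideline.
#'
#' @return Tibble `channel, guideline`.
#' @export
who_guidelines <- function() {
  tibble(channel = c("no2", "pm25", "pm10"), guideline = c(25, 15, 45))
}

#' Compare daily means against 24-hour guidelines
#'
#' Flags each qualifying participant-day whose mean exceeds the channel's
#' 24-hour guideline. Channels without a guideline (PM1, BC) are skipped
#' with a note.
#'
#' @param table Fused table.
#' @param channels Channels to assess.
#' @param guidelines Guideline tibble, by default [who_guidelines()].
#' @inheritParams daily_means
#' @return Tibble `channel, guideline, n_days, n_exceeding, fraction_exceeding`.
#' @export
who_compare <- function(table, channels = c("no2", "pm25", "pm10"),
                        guidelines = who_guidelines(),
                        min_completeness = 0.2, tz = "Europe/Paris") {
  purrr::map(channels, function(ch) {
    g <- guidelines$guideline[guidelines$channel == ch]
    if (length(g) == 0) {
      inform(paste0("channel '", ch, "' has no 24-hour guideline; skipped"))
      return(NULL)
    }
    dm <- daily_means(table, ch, min_completeness, tz)
    tibble(channel = ch, guideline = g, n_days = nrow(dm),
           n_exceeding = sum(dm$mean > g),
           fraction_exceeding = if (nrow(dm) == 0) NA_real_ else
             mean(dm$mean > g))
  }) %>% bind_rows()
}
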