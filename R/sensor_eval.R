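#' Align a sensor series with a reference series
#'
#' Both series are block-averaged onto a common time step (reference
#' instruments often report at 5- or 15-minute cadence) and paired on bins
#' where both carry a value. The presence ratio is the fraction of expected
#' bins in the overlapping span where the sensor recorded at least one
#' value.
#'
#' @param sensor,reference `wx_series` tibbles.
#' @param step Common step in minutes.
#' @return A list with `pairs` (tibble `timestamp, sensor, reference`),
#'   `presence` and `step`.
#' @export
align_series <- function(sensor, reference, step = 1) {
  stopifnot(step >= 1)
  bin <- function(s) {
    s %>%
      filter(!is.na(.data$value)) %>%
      mutate(bin = lubridate::floor_date(.data$timestamp, lubridate::minutes(step))) %>%
      group_by(.data$bin) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  }
  bs <- bin(sensor)
  br <- bin(reference)
  lo <- max(min(bs$bin), min(br$bin))
  hi <- min(max(bs$bin), max(br$bin))
  if (lo > hi) abort("sensor and reference spans do not overlap", class = "wx_config_error")
  expected <- seq(lo, hi, by = paste(step, "mins"))
  pairs <- dplyr::inner_join(bs %>% rename(sensor = "value"),
                             br %>% rename(reference = "value"), by = "bin") %>%
    filter(.data$bin >= lo, .data$bin <= hi) %>%
    rename(timestamp = "bin")
  presence <- sum(bs$bin >= lo & bs$bin <= hi) / length(expected)
  list(pairs = pairs, presence = min(presence, 1), step = step)
}

#' Threshold match score of a paired series
#'
#' Fraction of pairs where sensor and reference agree on exceeding (or not
#' exceeding) a threshold, by default the reference's 90th percentile. If
#' the reference never exceeds the threshold the score is degenerate and a
#' warning is raised.
#'
#' @param pairs Tibble with `sensor` and `reference` columns.
#' @param threshold Exceedance threshold; defaults to reference p90.
#' @return A fraction in `[0, 1]`.
#' @export
match_score <- function(pairs, threshold = NULL) {
  threshold <- threshold %||% quantile(pairs$reference, 0.9, names = FALSE)
  if (!any(pairs$reference > threshold)) {
    warn("reference never exceeds the threshold; match score is degenerate")
  }
  mean((pairs$sensor > threshold) == (pairs$reference > threshold))
}

#' Low-frequency energy score of the sensor error
#'
#' One minus the normalised periodogram energy of the sensor-minus-reference
#' error at periods longer than `cutoff_period`: a score of 1 means no
#' low-frequency drift in the error signal. Series shorter than twice the
#' cutoff give `NA`.
#'
#' @param pairs Tibble with `sensor` and `reference` columns, evenly spaced.
#' @param cutoff_period Cutoff period in steps (minutes at 1-minute pairing).
#' @return A score in `[0, 1]`, or `NA` for too-short input.
#' @export
low_frequency_energy <- function(pairs, cutoff_period = 60) {
  err <- pairs$sensor - pairs$reference
  if (length(err) < 2 * cutoff_period) return(NA_real_)
  if (sd(err) == 0) return(1)
  pg <- stats::spec.pgram(err, taper = 0, detrend = FALSE, demean = TRUE,
                          plot = FALSE, fast = FALSE)
  low <- pg$freq < 1 / cutoff_period
  1 - sum(pg$spec[low]) / sum(pg$spec)
}

#' Integrated performance index
#'
#' Maps each collocation metric onto `[0, 1]` (RMSE through
#' `1 / (1 + rmse / scale)` with the reference IQR as scale, correlations
#' through `(r + 1) / 2`, presence/match/LFE natively) and aggregates the
#' defined metrics by a weighted mean. A perfect sensor scores 1.
#'
#' @param metrics Named list or vector with elements among `rmse`,
#'   `pearson`, `kendall`, `spearman`, `presence`, `match`, `lfe`.
#' @param rmse_scale Scale used to normalise RMSE (reference IQR).
#' @param weights Named weights; defaults to equal weight for every defined
#'   metric.
#' @return The index in `[0, 1]`.
#' @export
ipi <- function(metrics, rmse_scale = 1, weights = NULL) {
  m <- as.list(metrics)
  mapped <- c(
    rmse = if (!is.null(m$rmse) && !is.na(m$rmse))
      1 / (1 + m$rmse / rmse_scale) else NA_real_,
    pearson = if (is.null(m$pearson)) NA_real_ else (m$pearson + 1) / 2,
    kendall = if (is.null(m$kendall)) NA_real_ else (m$kendall + 1) / 2,
    spearman = if (is.null(m$spearman)) NA_real_ else (m$spearman + 1) / 2,
    presence = m$presence %||% NA_real_,
    match = m$match %||% NA_real_,
    lfe = m$lfe %||% NA_real_
  )
  ok <- !is.na(mapped)
  if (!any(ok)) abort("all metrics missing; cannot compute the index",
                      class = "wx_config_error")
  w <- rep(1, length(mapped))
  names(w) <- names(mapped)
  if (!is.null(weights)) {
    w[] <- 0
    w[names(weights)] <- unlist(weights)
  }
  sum(mapped[ok] * w[ok]) / sum(w[ok])
}

#' Evaluate a sensor against a reference instrument
#'
#' Aligns the two series on a common step and computes the seven
#' qualification metrics: RMSE, Pearson/Kendall/Spearman correlations, the
#' presence ratio of recorded over expected samples, the threshold match
#' score and the low-frequency energy score, aggregated into the integrated
#' performance index (IPI; 1 = ideal sensor). Correlations of a constant
#' series are undefined and reported as missing.
#'
#' @param sensor,reference `wx_series` tibbles.
#' @param step Comparison step in minutes.
#' @param match_threshold Optional match-score threshold (default reference
#'   p90).
#' @param lfe_cutoff LFE cutoff period in steps.
#' @param weights Optional IPI weights.
#' @return An object of class `wx_sensor_eval`.
#' @export
evaluate_sensor <- function(sensor, reference, step = 1,
                            match_threshold = NULL, lfe_cutoff = 60,
                            weights = NULL) {
  al <- align_series(sensor, reference, step)
  p <- al$pairs
  if (nrow(p) < 3) abort("fewer than 3 aligned pairs", class = "wx_config_error")
  err <- p$sensor - p$reference
  consts <- sd(p$sensor) == 0 || sd(p$reference) == 0
  corr <- function(method) {
    if (consts) NA_real_ else cor(p$sensor, p$reference, method = method)
  }
  iqr_ref <- stats::IQR(p$reference)
  metrics <- list(
    rmse = sqrt(mean(err^2)),
    pearson = corr("pearson"),
    kendall = corr("kendall"),
    spearman = corr("spearman"),
    presence = al$presence,
    match = match_score(p, match_threshold),
    lfe = low_frequency_energy(p, lfe_cutoff)
  )
  structure(list(
    metrics = metrics,
    ipi = ipi(metrics, rmse_scale = if (iqr_ref > 0) iqr_ref else 1,
              weights = weights),
    n_pairs = nrow(p), step = step, channel = sensor$channel[1]
  ), class = "wx_sensor_eval")
}

#' @export
print.wx_sensor_eval <- function(x, ...) {
  cat(sprintf("Sensor evaluation (%s, %d pairs at %d-min step)\n",
              x$channel %||% "?", x$n_pairs, x$step))
  m <- x$metrics
  cat(sprintf("  RMSE %.3g | r %.3f | tau %.3f | rho %.3f | presence %.3f | match %.3f | LFE %.3f\n",
              m$rmse, m$pearson, m$kendall, m$spearman, m$presence, m$match,
              m$lfe %||% NA))
  cat(sprintf("  IPI: %.3f\n", x$ipi))
  invisible(x)
}

#' @rdname tidy.wx_environment_model
#' @export
tidy.wx_sensor_eval <- function(x, ...) {
  tibble(metric = names(x$metrics),
         value = purrr::map_dbl(x$metrics, ~ .x %||% NA_real_))
}

#' @rdname tidy.wx_environment_model
#' @export
glance.wx_sensor_eval <- function(x, ...) {
  tibble(ipi = x$ipi, n_pairs = x$n_pairs, step = x$step)
}
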