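#' Extract per-minute view features from a fused table
#'
#' For every minute and every channel ("view"), summary features of the
#' trailing `W`-minute window of that channel are computed: mean, SD, min,
#' max, median, IQR, OLS slope (per minute) and the fraction of missing
#' minutes. Windows are time-based: the table is expanded to a complete
#' minute grid per participant before windowing, so gaps count as missing
#' rather than being skipped. A view whose window holds no observation is
#' absent (its features are `NA` and `frac_missing` is 1), never
#' zero-filled.
#'
#' @param table A fused table (optionally with `participant_id` and `label`
#'   columns).
#' @param W Window length in minutes (>= 1).
#' @return A tibble with one row per input table row: `timestamp`,
#'   `participant_id`, `label` (if present) and `<view>_<feature>` columns
#'   for the eight views.
#' @export
extract_views <- function(table, W = 15) {
  stopifnot(W >= 1)
  if (!"participant_id" %in% names(table)) table$participant_id <- "p1"
  feats <- table %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(df, key) {
      grid <- tibble(timestamp = seq(min(df$timestamp), max(df$timestamp), by = "1 min"))
      full <- left_join(grid, df, by = "timestamp")
      keep <- grid$timestamp %in% df$timestamp
      cols <- purrr::map(setNames(model_channels(), model_channels()), function(ch) {
        m <- .roll_view_features(full[[ch]], as.integer(W))[keep, , drop = FALSE]
        colnames(m) <- paste(ch, colnames(m), sep = "_")
        as_tibble(m)
      })
      out <- dplyr::bind_cols(tibble(timestamp = grid$timestamp[keep]), cols)
      if ("label" %in% names(df)) {
        out$label <- df$label[match(out$timestamp, df$timestamp)]
      }
      out
    }) %>%
    ungroup()
  feats %>% select("timestamp", "participant_id", any_of("label"), dplyr::everything())
}

view_feature_names <- function() {
  c("mean", "sd", "min", "max", "median", "iqr", "slope", "frac_missing")
}

feature_columns <- function(view) paste(view, view_feature_names(), sep = "_")
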