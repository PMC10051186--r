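#' Undersample majority classes
#'
#' Classes with more than `target_count` rows are reduced to `target_count`
#' by uniform random sampling without replacement; smaller classes pass
#' through unchanged. Deterministic given `seed`.
#'
#' @param data Tibble with a label column.
#' @param target_count Positive integer target per class.
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return The subsampled tibble.
#' @export
undersample_majority <- function(data, target_count, seed = 1, label_col = "label") {
  if (target_count <= 0) abort("target_count must be positive", class = "wx_config_error")
  withr::with_seed(seed, {
    data %>%
      group_by(.data[[label_col]]) %>%
      dplyr::group_modify(function(df, key) {
        if (nrow(df) > target_count) df[sample.int(nrow(df), target_count), ] else df
      }) %>%
      ungroup()
  })
}

#' SMOTE oversampling of a minority class
#'
#' Each synthetic row is `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)`
#' and `x_nn` one of the `k_neighbors` nearest minority neighbours of a
#' randomly chosen minority row `x` (Euclidean distance on the numeric
#' feature columns). Missing feature values are imputed with the column
#' median before interpolation (with a warning).
#'
#' @param data Tibble of minority-class feature rows (numeric columns are
#'   interpolated; non-numeric columns are returned as `NA`).
#' @param n_new Number of synthetic rows to create.
#' @param k_neighbors Neighbourhood size (reduced with a warning when the
#'   minority is too small).
#' @param seed Integer seed.
#' @return A tibble of `n_new` synthetic rows; the `"provenance"` attribute
#'   records, per row, the base row index, neighbour index and `lambda`, so
#'   each synthetic point can be reconstructed exactly.
#' @export
smote_oversample <- function(data, n_new, k_neighbors = 5, seed = 1) {
  if (n_new == 0) return(data[0, , drop = FALSE])
  n <- nrow(data)
  if (n < 2) abort("SMOTE needs at least 2 minority rows", class = "wx_config_error")
  if (n <= k_neighbors) {
    k_neighbors <- n - 1
    warn(paste0("minority class too small; reducing k_neighbors to ", k_neighbors))
  }
  num_cols <- names(data)[purrr::map_lgl(data, is.numeric)]
  x <- as.matrix(data[num_cols])
  if (anyNA(x)) {
    inform("missing feature values imputed with column medians before SMOTE")
    for (j in seq_len(ncol(x))) {
      x[is.na(x[, j]), j] <- median(x[, j], na.rm = TRUE)
    }
    x[is.na(x)] <- 0
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) nn[i, ] <- order(d[i, ])[seq_len(k_neighbors)]
  withr::with_seed(seed, {
    base <- sample.int(n, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    lambda <- runif(n_new)
    synth <- x[base, , drop = FALSE] +
      lambda * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
    out <- data[rep(1L, n_new), , drop = FALSE]
    for (col in names(out)) {
      out[[col]] <- if (col %in% num_cols) synth[, col] else out[[col]][NA]
    }
    attr(out, "provenance") <- tibble(base = base, neighbour = pick,
                                      lambda = lambda)
    out
  })
}

#' Balance labelled feature windows
#'
#' Produces a class-balanced training set: classes above the target count
#' are undersampled, classes below it are topped up with SMOTE synthetic
#' rows. The default target is the median original class count. A
#' `.provenance` column distinguishes original from synthetic rows, and the
#' per-class bookkeeping is attached as the `"report"` attribute.
#'
#' @param data Labelled feature tibble (one row per window).
#' @param target `"median"` or a positive integer target per class.
#' @param k_neighbors SMOTE neighbourhood size.
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return A tibble with equal class counts and a `.provenance` column;
#'   `attr(, "report")` holds per-class original/final counts.
#' @export
balance_classes <- function(data, target = "median", k_neighbors = 5, seed = 1,
                            label_col = "label") {
  counts <- data %>% count(.data[[label_col]], name = "original")
  if (nrow(counts) < 2) abort("balancing needs at least 2 classes", class = "wx_config_error")
  target_count <- if (identical(target, "median")) {
    as.integer(round(median(counts$original)))
  } else {
    as.integer(target)
  }
  if (target_count <= 0) abort("target must be positive", class = "wx_config_error")
  down <- undersample_majority(data, target_count, seed = seed, label_col = label_col) %>%
    mutate(.provenance = "original")
  feature_cols <- setdiff(names(data), c(label_col, "timestamp", "participant_id"))
  synth <- counts %>%
    filter(.data$original < target_count) %>%
    purrr::pmap(function(...) {
      row <- list(...)
      lab <- row[[label_col]]
      minority <- data %>% filter(.data[[label_col]] == lab)
      new <- smote_oversample(minority[feature_cols], target_count - row$original,
                              k_neighbors = k_neighbors,
                              seed = seed + match(lab, counts[[label_col]]))
      new[[label_col]] <- lab
      new %>% mutate(.provenance = "synthetic")
    }) %>%
    bind_rows()
  out <- bind_rows(down, synth)
  prov <- out %>%
    count(.data[[label_col]], .data$.provenance) %>%
    tidyr::pivot_wider(names_from = ".provenance", values_from = "n",
                       values_fill = 0L)
  if (!"synthetic" %in% names(prov)) prov$synthetic <- 0L
  report <- counts %>%
    left_join(prov %>% rename(kept_original = "original"), by = label_col) %>%
    mutate(final = .data$kept_original + .data$synthetic)
  attr(out, "report") <- report
  out
}
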