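# Shared fixture builders and a cache for the expensive simulated campaigns,
# so several test files can reuse the same study without re-simulating.

wx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(wx_cache[[key]])) wx_cache[[key]] <- force(expr)
  wx_cache[[key]]
}

minutes_utc <- function(n, start = "2019-10-14 00:00:00") {
  lubridate::ymd_hms(start, tz = "UTC") + lubridate::minutes(seq_len(n) - 1)
}

make_series <- function(values, channel = "pm25", start = "2019-10-14 00:00:00") {
  sensor_series(minutes_utc(length(values), start), values, channel)
}

# Small labelled fused table on a minute grid, stationary position.
make_fused <- function(n = 60, label = "home", seed = 1) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      timestamp = minutes_utc(n),
      temperature = rnorm(n, 21, 1), humidity = rnorm(n, 45, 3),
      pm1 = rlnorm(n, log(4), 0.3), pm25 = NA_real_, pm10 = NA_real_,
      no2 = rlnorm(n, log(18), 0.3), bc = rlnorm(n, log(500), 0.4),
      speed = 0, lon = 2.13, lat = 48.8, label = label,
      participant_id = "p1"
    )
    df$pm25 <- df$pm1 * 1.5
    df$pm10 <- df$pm1 * 2.2
    df
  })
}

# Independent haversine (textbook formula), used as the GPS oracle.
hav_m <- function(lon1, lat1, lon2, lat2) {
  r <- 6378137
  to <- pi / 180
  dlat <- (lat2 - lat1) * to
  dlon <- (lon2 - lon1) * to
  a <- sin(dlat / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Brute-force double-loop peak oracle, straight from the rule's definition.
brute_peaks <- function(v, k, f) {
  n <- length(v)
  mask <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    js <- setdiff(max(1, i - k):min(n, i + k), i)
    nb <- v[js]
    nb <- nb[!is.na(nb)]
    if (length(nb) < max(k, 2)) next
    mask[i] <- v[i] > f * mean(nb)
  }
  mask
}

# One default 7-day participant bundle plus its curation.
default_bundle <- function() {
  cached("bundle", {
    sched <- generate_schedule(7, seed = 401)
    generate_traces(sched, seed = 402)
  })
}

default_curation <- function() {
  cached("curation", curate(default_bundle()))
}

# Ten participant-weeks at 3-SD emission separation: the classifier study.
sep3_campaign <- function() {
  cached("sep3", simulate_campaign(participants = 10, days = 7, seed = 501,
                                   emission = emission_model(separation = 3)))
}

# Curated, truth-labelled fused tables of the separation-3 study, in the
# row order predict() uses.
sep3_tables <- function() {
  cached("sep3_tabs", {
    purrr::map(sep3_campaign(), function(b) {
      tab <- curate(b)$table
      tab$label <- label_minutes(tab$timestamp, b$annotations)
      dplyr::arrange(tab, participant_id, timestamp)
    })
  })
}

sep3_features <- function() {
  cached("sep3_feats", dplyr::bind_rows(purrr::map(sep3_tables(), extract_views)))
}

# Held-out accuracy on a class-stratified subsample (equal minutes per
# class), under which any truth-independent classifier scores 1/k exactly.
stratified_accuracy <- function(pred_labels, truth, seed = 1) {
  ok <- !is.na(truth)
  pred <- pred_labels[ok]
  tr <- truth[ok]
  k <- min(table(tr))
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(tr), tr), function(i) sample(i, k)))
  })
  mean(!is.na(pred[idx]) & pred[idx] == tr[idx])
}

# Label-shuffled control model on the same training participants.
sep3_null_fit <- function() {
  cached("null_fit", {
    feats <- sep3_features()
    train <- feats[feats$participant_id %in% sprintf("p%02d", 1:7) &
                     !is.na(feats$label), ]
    train <- train[setdiff(names(train), c("timestamp", "participant_id"))]
    train <- withr::with_seed(601, {
      train$label <- sample(train$label)
      train
    })
    bal <- balance_classes(train, seed = 602)
    model <- train_environment_model(bal, num_trees = 100, meta_trees = 150,
                                     seed = 603)
    test_p <- sprintf("p%02d", 8:10)
    test_tab <- dplyr::bind_rows(sep3_tables())
    test_tab <- dplyr::arrange(
      test_tab[test_tab$participant_id %in% test_p, ],
      participant_id, timestamp)
    pred <- predict(model, feats[feats$participant_id %in% test_p, ])
    list(model = model,
         accuracy = stratified_accuracy(pred$label, test_tab$label, seed = 604))
  })
}

# Grouped participant split, trained model and held-out predictions.
sep3_model_fit <- function() {
  cached("sep3_fit", {
    feats <- sep3_features()
    train_p <- sprintf("p%02d", 1:7)
    test_p <- sprintf("p%02d", 8:10)
    train <- feats[feats$participant_id %in% train_p & !is.na(feats$label), ]
    train <- train[setdiff(names(train), c("timestamp", "participant_id"))]
    bal <- balance_classes(train, seed = 502)
    model <- train_environment_model(bal, seed = 503)
    test_tab <- dplyr::bind_rows(sep3_tables())
    test_tab <- dplyr::arrange(
      test_tab[test_tab$participant_id %in% test_p, ],
      participant_id, timestamp)
    pred <- predict(model, feats[feats$participant_id %in% test_p, ])
    list(model = model, test_tab = test_tab, pred = pred,
         raw_eval = evaluate_labels(pred, test_tab$label))
  })
}
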