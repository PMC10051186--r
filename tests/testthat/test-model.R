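test_that("window features follow closed forms on simple signals", {
  tab <- make_fused(30)
  tab$no2 <- 7
  tab$pm1 <- seq_len(30)
  tab$pm25 <- tab$pm1 * 1.5
  tab$pm10 <- tab$pm1 * 2.2
  f <- extract_views(tab, W = 15)
  expect_equal(nrow(f), 30)
  # constant channel: zero SD and slope
  expect_equal(f$no2_sd[20], 0)
  expect_equal(f$no2_slope[20], 0)
  expect_equal(f$no2_mean[20], 7)
  # arithmetic ramp 1..15 in the window ending at minute 15
  expect_equal(f$pm1_mean[15], 8)
  expect_equal(f$pm1_slope[15], 1)
  expect_equal(f$pm1_median[15], 8)
  expect_equal(f$pm1_iqr[15], quantile(1:15, .75)[[1]] - quantile(1:15, .25)[[1]])
})

test_that("views with empty windows are absent, not zero-filled", {
  tab <- make_fused(20)
  tab$bc <- NA_real_
  tab$speed <- NA_real_
  f <- extract_views(tab, W = 15)
  expect_true(all(is.na(f$bc_mean)))
  expect_true(all(f$bc_frac_missing == 1))
  # missingness fraction reflects gaps inside the window
  tab2 <- make_fused(20)
  tab2$no2[5:20] <- NA
  f2 <- extract_views(tab2, W = 15)
  expect_equal(f2$no2_frac_missing[15], 11 / 15)
})

test_that("windows are time-based across row gaps", {
  tab <- make_fused(40)[c(1:10, 31:40), ]
  f <- extract_views(tab, W = 15)
  expect_equal(nrow(f), 20)
  # at row 11 (minute 31) the trailing window covers minutes 17..31: only 1 seen
  expect_equal(f$no2_frac_missing[11], 14 / 15)
  expect_equal(f$no2_mean[11], tab$no2[11])
})

test_that("training, prediction and the meta-input layout behave as designed", {
  fit <- sep3_model_fit()
  model <- fit$model
  expect_s3_class(model, "wx_environment_model")
  expect_setequal(names(model$views), model_channels())
  expect_setequal(model$classes, environment_classes())

  # meta input: one (class, probability) pair per view
  oof <- purrr::map(
    setNames(model_channels()[1:4], model_channels()[1:4]),
    ~ matrix(c(0.6, 0.2, 0.1, 0.05, 0.05), 1, 5,
             dimnames = list(NULL, model$classes)))
  mf <- wearexpo:::meta_features(oof, 1, model$classes)
  expect_equal(ncol(mf), 8)
  expect_equal(sum(grepl("_class$", names(mf))), 4)
  expect_equal(sum(grepl("_prob$", names(mf))), 4)

  # prediction is a pure function of window contents: row order irrelevant
  feats <- sep3_features()
  sub <- feats[feats$participant_id == "p08", ][1:500, ]
  p1 <- predict(model, sub)
  p2 <- predict(model, sub[sample.int(nrow(sub)), ])
  expect_equal(dplyr::arrange(p1, timestamp), dplyr::arrange(p2, timestamp))

  empty <- predict(model, feats[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the classifier separates well-separated synthetic environments", {
  fit <- sep3_model_fit()
  expect_gte(fit$raw_eval$accuracy, 0.90)

  # meta-learner does not trail the best single view by more than 2 points
  feats <- sep3_features()
  test <- feats[feats$participant_id %in% sprintf("p%02d", 8:10), ]
  truth <- fit$test_tab$label
  view_acc <- purrr::map_dbl(names(fit$model$views), function(v) {
    rows <- !is.na(test[[paste0(v, "_mean")]]) & !is.na(truth)
    pr <- stats::predict(fit$model$views[[v]],
                         data = test[rows, wearexpo:::feature_columns(v)],
                         num.threads = 1)$predictions
    mean(colnames(pr)[max.col(pr, ties.method = "first")] == truth[rows])
  })
  expect_gte(fit$raw_eval$accuracy, max(view_acc) - 0.02)
})

test_that("label-shuffled training collapses to chance accuracy", {
  expect_lt(abs(sep3_null_fit()$accuracy - 0.20), 0.05)
})

test_that("training is deterministic and degenerate cases error", {
  feats <- sep3_features()
  small <- feats[feats$participant_id == "p01" & !is.na(feats$label), ][1:600, ]
  small <- small[setdiff(names(small), c("timestamp", "participant_id"))]
  m1 <- train_environment_model(small, num_trees = 50, meta_trees = 50, seed = 9)
  m2 <- train_environment_model(small, num_trees = 50, meta_trees = 50, seed = 9)
  probe <- feats[feats$participant_id == "p02", ][1:200, ]
  expect_identical(predict(m1, probe), predict(m2, probe))

  one_class <- small[small$label == small$label[1], ]
  expect_error(train_environment_model(one_class), class = "wx_config_error")
})

test_that("evaluation accounting matches hand counts", {
  pred <- tibble::tibble(timestamp = minutes_utc(4),
                         label = c("home", "home", "office", "home"))
  truth <- c("home", "home", "office", "office")
  ev <- evaluate_labels(pred, truth)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.integer(table(factor(truth)))))
  expect_equal(ev$per_class$recall[ev$per_class$label == "office"], 0.5)

  perfect <- evaluate_labels(pred, pred$label)
  expect_equal(perfect$accuracy, 1)

  expect_error(evaluate_labels(pred, rep(NA_character_, 4)),
               class = "wx_config_error")
})

test_that("broom accessors expose per-view and model-level summaries", {
  fit <- sep3_model_fit()
  td <- tidy(fit$model)
  expect_equal(nrow(td), 8)
  expect_true(all(td$oob_accuracy > 0 & td$oob_accuracy <= 1))
  gl <- glance(fit$model)
  expect_equal(gl$n_classes, 5)
  ev <- fit$raw_eval
  expect_equal(sum(tidy(ev)$n), glance(ev)$n_minutes)
})
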