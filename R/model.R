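#' Train the multi-view microenvironment classifier
#'
#' Fits one first-level probability forest per channel view on that view's
#' window features, then a meta-learner on the concatenated first-level
#' outputs (predicted class and its probability for each of the eight
#' views). Meta-training uses out-of-fold first-level predictions (K-fold
#' stacking) so the meta-learner never sees in-sample first-level output.
#' Views with no data in the training set are excluded with a warning.
#'
#' @param data Labelled window-feature tibble (from [extract_views()],
#'   typically balanced with [balance_classes()]); must contain a `label`
#'   column and `<view>_<feature>` columns.
#' @param num_trees,meta_trees Forest sizes of the first-level and meta
#'   learners.
#' @param k_folds Stacking folds.
#' @param seed Integer seed; training is deterministic given it.
#' @param W Window length (metadata recorded in the model).
#' @return An object of class `wx_environment_model`.
#' @export
train_environment_model <- function(data, num_trees = 200, meta_trees = 300,
                                    k_folds = 5, seed = 1, W = 15) {
  data <- data %>% filter(!is.na(.data$label))
  classes <- sort(unique(data$label))
  if (length(classes) < 2) abort("training needs at least 2 classes", class = "wx_config_error")
  n <- nrow(data)
  views <- model_channels()
  present <- purrr::map(setNames(views, views),
                        ~ !is.na(data[[paste0(.x, "_mean")]]))
  usable <- views[purrr::map_int(present, sum) > 0]
  if (length(usable) < length(views)) {
    warn(paste0("views with no training data excluded: ",
                paste(setdiff(views, usable), collapse = ", ")))
  }
  y <- factor(data$label, levels = classes)

  fit_view <- function(view, rows, s) {
    df <- data[rows, feature_columns(view)]
    df$.y <- y[rows]
    ranger::ranger(dependent.variable.name = ".y", data = df,
                   probability = TRUE, num.trees = num_trees,
                   seed = s, num.threads = 1, respect.unordered.factors = "order")
  }
  predict_view <- function(fit, view, rows) {
    out <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
    if (any(rows)) {
      p <- stats::predict(fit, data = data[rows, feature_columns(view)],
                          num.threads = 1)$predictions
      out[rows, colnames(p)] <- p
    }
    out
  }

  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  oof <- purrr::map(setNames(usable, usable), ~ matrix(NA_real_, n, length(classes),
                                                       dimnames = list(NULL, classes)))
  for (k in seq_len(k_folds)) {
    hold <- folds == k
    for (v in usable) {
      rows_train <- present[[v]] & !hold
      if (sum(rows_train) == 0) next
      fit <- fit_view(v, rows_train, seed + 31 * k + match(v, views))
      p <- predict_view(fit, v, present[[v]] & hold)
      oof[[v]][present[[v]] & hold, ] <- p[present[[v]] & hold, ]
    }
  }
  meta_df <- meta_features(oof, n, classes)
  meta_df$.y <- y
  meta <- ranger::ranger(dependent.variable.name = ".y", data = meta_df,
                         probability = TRUE, num.trees = meta_trees,
                         seed = seed + 7, num.threads = 1,
                         respect.unordered.factors = "order")
  view_fits <- purrr::imap(setNames(usable, usable), function(v, nm) {
    fit_view(v, present[[v]], seed + match(v, views))
  })
  structure(list(views = view_fits, meta = meta, classes = classes,
                 W = W, seed = seed,
                 num_trees = num_trees, meta_trees = meta_trees,
                 k_folds = k_folds, n_train = n,
                 class_counts = table(y)),
            class = "wx_environment_model")
}

# Concatenate first-level outputs into the meta-learner input: per view the
# predicted class (sentinel "absent" where the view has no data, with a
# uniform probability) and its probability.
meta_features <- function(prob_list, n, classes) {
  out <- purrr::imap(prob_list, function(p, v) {
    cls <- rep("absent", n)
    prob <- rep(1 / length(classes), n)
    has <- !is.na(p[, 1])
    if (any(has)) {
      idx <- max.col(p[has, , drop = FALSE], ties.method = "first")
      cls[has] <- classes[idx]
      prob[has] <- p[cbind(which(has), idx)]
    }
    tibble(!!paste0(v, "_class") := factor(cls, levels = c(classes, "absent")),
           !!paste0(v, "_prob") := prob)
  })
  dplyr::bind_cols(out)
}

#' Predict microenvironments for a fused table
#'
#' Extracts trailing-window view features (unless `newdata` already is a
#' feature table), lets every available view emit a class and probability,
#' imputes absent views with the sentinel class and a uniform probability,
#' and maps the concatenated vector through the meta-learner. Minutes with
#' no available view get a missing label.
#'
#' @param object A `wx_environment_model`.
#' @param newdata A fused table or a window-feature tibble.
#' @param ... Unused.
#' @return A tibble `timestamp, participant_id, label, confidence`.
#' @export
predict.wx_environment_model <- function(object, newdata, ...) {
  feats <- if (any(paste0(model_channels(), "_mean") %in% names(newdata))) {
    newdata
  } else {
    extract_views(newdata, W = object$W)
  }
  feats <- feats %>% arrange(.data$participant_id, .data$timestamp)
  n <- nrow(feats)
  classes <- object$classes
  out <- tibble(timestamp = feats$timestamp,
                participant_id = feats$participant_id,
                label = NA_character_, confidence = NA_real_)
  if (n == 0) return(out)
  probs <- purrr::imap(object$views, function(fit, v) {
    p <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
    rows <- !is.na(feats[[paste0(v, "_mean")]])
    if (any(rows)) {
      pr <- stats::predict(fit, data = feats[rows, feature_columns(v)],
                           num.threads = 1)$predictions
      p[rows, colnames(pr)] <- pr
    }
    p
  })
  meta_df <- meta_features(probs, n, classes)
  any_view <- purrr::reduce(purrr::map(object$views %>% names(),
                                       ~ !is.na(feats[[paste0(.x, "_mean")]])), `|`)
  if (any(any_view)) {
    mp <- stats::predict(object$meta, data = meta_df[any_view, , drop = FALSE],
                         num.threads = 1)$predictions
    idx <- max.col(mp, ties.method = "first")
    out$label[any_view] <- colnames(mp)[idx]
    out$confidence[any_view] <- mp[cbind(seq_len(nrow(mp)), idx)]
  }
  out
}

#' Evaluate predicted minute labels against ground truth
#'
#' @param predictions Tibble with `timestamp` and predicted `label` (and
#'   optionally `participant_id`).
#' @param truth Either an annotation tibble `start,end,label` or a character
#'   vector of true labels aligned with `predictions`.
#' @return An object of class `wx_evaluation` with overall accuracy,
#'   per-class recall and a confusion matrix (rows = truth).
#' @export
evaluate_labels <- function(predictions, truth) {
  true_lab <- if (is.data.frame(truth)) {
    label_minutes(predictions$timestamp, truth)
  } else {
    as.character(truth)
  }
  pred_lab <- predictions$label
  ok <- !is.na(true_lab)
  if (!any(ok)) abort("no labelled minutes overlap the predictions", class = "wx_config_error")
  true_lab <- true_lab[ok]
  pred_lab <- pred_lab[ok]
  levels <- sort(unique(c(true_lab, stats::na.omit(pred_lab))))
  confusion <- table(truth = factor(true_lab, levels),
                     predicted = factor(pred_lab, levels), useNA = "no")
  correct <- sum(!is.na(pred_lab) & pred_lab == true_lab)
  per_class <- tibble(label = levels,
                      support = as.integer(table(factor(true_lab, levels)))) %>%
    mutate(recall = purrr::map2_dbl(.data$label, .data$support, function(l, s) {
      if (s == 0) return(NA_real_)
      sum(pred_lab == l & true_lab == l, na.rm = TRUE) / s
    }))
  structure(list(accuracy = correct / length(true_lab),
                 n = length(true_lab),
                 per_class = per_class,
                 confusion = confusion),
            class = "wx_evaluation")
}

#' @export
print.wx_evaluation <- function(x, ...) {
  cat(sprintf("Minute-level accuracy: %.3f on %d labelled minutes\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' @export
print.wx_environment_model <- function(x, ...) {
  cat("Multi-view environment classifier\n")
  cat("  views:", paste(names(x$views), collapse = ", "), "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  window: %d min; %d training rows; stacking folds: %d\n",
              x$W, x$n_train, x$k_folds))
  invisible(x)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns per-view out-of-bag accuracy of the first-level
#' learners; `glance()` returns one-row model-level metadata including the
#' meta-learner's out-of-bag accuracy.
#'
#' @param x A `wx_environment_model` or `wx_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wx_environment_model <- function(x, ...) {
  tibble(view = names(x$views),
         oob_accuracy = purrr::map_dbl(x$views, ~ 1 - .x$prediction.error))
}

#' @rdname tidy.wx_environment_model
#' @export
glance.wx_environment_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_views = length(x$views),
         n_classes = length(x$classes), window_min = x$W,
         meta_oob_accuracy = 1 - x$meta$prediction.error)
}

#' @rdname tidy.wx_environment_model
#' @export
tidy.wx_evaluation <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion)) %>%
    rename(truth = "truth", predicted = "predicted", n = "Freq")
}

#' @rdname tidy.wx_environment_model
#' @export
glance.wx_evaluation <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_minutes = x$n)
}
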