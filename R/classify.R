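# Feature-based (decision tree / random forest) and event-sequence group
# classifiers, with the repeated stratified 80/20 + k-fold validation
# protocol and the 20-event window preparation for the sequence learner.

#' The seven significance-selected features
#'
#' The reduced feature set used by the random forest: the metrics whose
#' group contrasts reach significance in the group models (speech rate,
#' total pause time, pause count, mean pause duration, vocal duration
#' variability, mean short pause duration, long pause count). Configurable
#' wherever it is consumed.
#'
#' @return Character vector of 7 metric names.
#' @export
selected_features <- function() {
  c("speech_rate_wpm", "total_pause_time_s", "pause_count", "mean_pause_ms",
    "vocal_cv", "mean_short_pause_ms", "long_pause_count")
}

#' Build the classifier feature matrix from a cohort table
#'
#' @param cohort A cohort table.
#' @param feature_set `"all13"` (decision tree) or `"selected7"` (random
#'   forest), or an explicit character vector of metric columns.
#' @return List `x` (numeric matrix, deterministic column order), `y`
#'   (factor of groups, levels AWNS/AWS), `ids`, and `n_dropped` (rows
#'   removed for missing features).
#' @export
build_feature_matrix <- function(cohort, feature_set = c("all13", "selected7")) {
  feats <- if (length(feature_set) == 1 && !feature_set[1] %in% c("all13", "selected7"))
    feature_set
  else switch(match.arg(feature_set), all13 = metric_names(),
              selected7 = selected_features())
  missing_cols <- setdiff(feats, names(cohort))
  if (length(missing_cols) > 0)
    stopf("cohort lacks feature columns: %s", paste(missing_cols, collapse = ", "))
  x <- as.matrix(cohort[feats])
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("dropping %d rows with missing features", n_dropped))
  if (!any(keep)) stopf("no complete rows for the requested feature set")
  list(x = x[keep, , drop = FALSE],
       y = factor(cohort$group[keep], levels = c("AWNS", "AWS")),
       ids = cohort$participant_id[keep],
       n_dropped = n_dropped)
}

# Stratified index sample: about `frac` of each class into the training set.
stratified_split <- function(y, frac) {
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- max(1L, round(length(idx) * frac))
    n_tr <- min(n_tr, length(idx) - 1L)  # keep at least one test row per class
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_learner <- function(learner, x, y) {
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  if (learner == "decision_tree")
    rpart::rpart(.y ~ ., data = df, method = "class")
  else
    randomForest::randomForest(x, y)
}

predict_learner <- function(learner, fit, x) {
  if (learner == "decision_tree") {
    df <- data.frame(x, check.names = FALSE)
    cl <- predict(fit, df, type = "class")
  } else cl <- predict(fit, x)
  cl
}

#' Evaluate a feature-based group classifier
#'
#' Runs (a) `n_repeats` repetitions of stratified 80/20 random resampling
#' and (b) stratified `cv_folds`-fold cross-validation, with all randomness
#' governed by `seed`. Splits missing a class are redrawn (and logged).
#' The confusion matrix aggregates held-out predictions over the
#' resampling repeats.
#'
#' @param matrix A feature matrix from [build_feature_matrix()].
#' @param learner `"decision_tree"` or `"random_forest"`.
#' @param n_repeats Resampling repetitions (default 10).
#' @param train_frac Training fraction (default 0.8).
#' @param cv_folds Cross-validation folds (default 3; set to the sample
#'   size for leave-one-out).
#' @param seed Integer seed.
#' @return List `accuracies` (per repeat), `mean_accuracy`,
#'   `cv_accuracies` (per fold), `cv_mean_accuracy`, `confusion`
#'   (aggregated held-out confusion matrix), `seed`, `learner`.
#' @export
evaluate_feature_classifier <- function(matrix, learner = c("random_forest",
                                                            "decision_tree"),
                                        n_repeats = 10, train_frac = 0.8,
                                        cv_folds = 3, seed = 1) {
  learner <- match.arg(learner)
  x <- matrix$x; y <- matrix$y
  if (min(table(y)) < 2) stopf("need at least two rows per class")
  with_local_seed(seed, {
    acc <- numeric(n_repeats)
    conf <- table(factor(character(0), levels(y)),
                  factor(character(0), levels(y)))
    for (r in seq_len(n_repeats)) {
      repeat {
        tr <- stratified_split(y, train_frac)
        if (length(unique(y[tr])) == nlevels(y) &&
            length(unique(y[-tr])) >= 1) break
        message("split missing a class; resampling")
      }
      fit <- fit_learner(learner, x[tr, , drop = FALSE], y[tr])
      pred <- predict_learner(learner, fit, x[-tr, , drop = FALSE])
      acc[r] <- mean(pred == y[-tr])
      conf <- conf + table(factor(pred, levels(y)), y[-tr])
    }
    fold <- stratified_folds(y, cv_folds)
    cv_acc <- vapply(seq_len(max(fold)), function(k) {
      tr <- which(fold != k)
      if (length(unique(y[tr])) < nlevels(y)) return(NA_real_)
      fit <- fit_learner(learner, x[tr, , drop = FALSE], y[tr])
      mean(predict_learner(learner, fit, x[-tr, , drop = FALSE]) == y[-tr])
    }, 0)
    list(accuracies = acc, mean_accuracy = mean(acc),
         cv_accuracies = cv_acc, cv_mean_accuracy = mean(cv_acc, na.rm = TRUE),
         confusion = conf, seed = seed, learner = learner)
  })
}

# Per-event feature rows for one recording: the 7 recording-level metrics
# (constant within the recording) + event type code + event duration.
event_feature_rows <- function(events, metric_row,
                               type_codes = c(vocal = 1, short = -0.5,
                                              long = -1)) {
  code <- ifelse(events$kind == "vocal", type_codes[["vocal"]],
                 ifelse(events$subtype == "short", type_codes[["short"]],
                        type_codes[["long"]]))
  base <- matrix(rep(as.numeric(metric_row), each = nrow(events)),
                 nrow = nrow(events))
  colnames(base) <- names(metric_row)
  cbind(base, event_type = code, event_duration_ms = events$duration_ms)
}

#' Build normalized 20-event windows for the sequence classifier
#'
#' Cuts each recording's event sequence into non-overlapping windows of
#' `window` consecutive events (trailing remainders are discarded;
#' recordings with fewer than `window` events are excluded with a
#' warning), attaches the nine per-event features (the seven
#' recording-level metrics, an event-type code, and the event duration),
#' and z-scores every feature using statistics estimated on the training
#' recordings only -- the split is made at the recording level before
#' windowing, so no test information leaks into the normalization.
#'
#' @param event_seqs Named list of `event_sequence` objects (names are
#'   recording ids).
#' @param cohort Cohort table holding the per-recording metrics and groups.
#' @param split Named list of recording-id vectors: `train`, `test`, and
#'   optionally `validation`.
#' @param window Events per window (default 20).
#' @param features Recording-level metric columns (default
#'   [selected_features()]).
#' @param type_codes Numeric encoding of event type (vocal = 1, short pause
#'   = -0.5, long pause = -1 by default).
#' @return List `x` (windows x (window * 9) matrix of flattened windows),
#'   `y` (group factor per window), `recording` (id per window), `role`
#'   (train/test/validation per window), `norm` (training means/sds),
#'   `window`, `n_features`.
#' @export
build_event_windows <- function(event_seqs, cohort, split, window = 20,
                                features = selected_features(),
                                type_codes = c(vocal = 1, short = -0.5,
                                               long = -1)) {
  ids <- names(event_seqs)
  stopifnot(!is.null(ids), all(unlist(split) %in% ids))
  rows_by_rec <- list()
  for (id in ids) {
    ev <- event_seqs[[id]]
    if (nrow(ev) < window) {
      warning(sprintf("recording %s has %d < %d events; excluded",
                      id, nrow(ev), window), call. = FALSE)
      next
    }
    mrow <- unlist(cohort[cohort$participant_id == id, features])
    rows_by_rec[[id]] <- event_feature_rows(ev, mrow, type_codes)
  }
  if (length(rows_by_rec) == 0) stopf("no recording has enough events")

  role_of <- function(id) {
    if (id %in% split$train) "train"
    else if (id %in% split$test) "test"
    else if (!is.null(split$validation) && id %in% split$validation) "validation"
    else NA_character_
  }

  # normalization statistics from training recordings only
  train_rows <- do.call(rbind, rows_by_rec[names(rows_by_rec) %in% split$train])
  mu <- colMeans(train_rows)
  sdv <- apply(train_rows, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1

  xs <- list(); ys <- character(0); recs <- character(0); roles <- character(0)
  for (id in names(rows_by_rec)) {
    role <- role_of(id)
    if (is.na(role)) next
    z <- sweep(sweep(rows_by_rec[[id]], 2, mu), 2, sdv, "/")
    n_win <- nrow(z) %/% window
    for (w in seq_len(n_win)) {
      block <- z[((w - 1) * window + 1):(w * window), , drop = FALSE]
      xs[[length(xs) + 1]] <- as.numeric(t(block))  # event-major flattening
      ys <- c(ys, cohort$group[cohort$participant_id == id])
      recs <- c(recs, id)
      roles <- c(roles, role)
    }
  }
  x <- do.call(rbind, xs)
  colnames(x) <- paste0("e", rep(seq_len(window), each = ncol(train_rows)),
                        "_", rep(colnames(train_rows), window))
  list(x = x, y = factor(ys, levels = c("AWNS", "AWS")), recording = recs,
       role = roles, norm = list(mean = mu, sd = sdv), window = window,
       n_features = ncol(train_rows))
}

#' Augment training windows by event-order rotation
#'
#' For every training window, adds copies whose 20-event sequence is
#' circularly shifted by each offset in `shifts`. Labels are preserved and
#' the multiset of events within a window is unchanged; augmentation is
#' applied to training windows only.
#'
#' @param windows Output of [build_event_windows()].
#' @param shifts Circular shift offsets in events (default 5, 10, 15).
#' @return The `windows` list with augmented training rows appended.
#' @export
augment_rotation <- function(windows, shifts = c(5, 10, 15)) {
  w <- windows$window; nf <- windows$n_features
  tr <- which(windows$role == "train")
  if (length(tr) == 0 || length(shifts) == 0) return(windows)
  extra_x <- list(); extra_y <- character(0); extra_rec <- character(0)
  for (i in tr) {
    block <- matrix(windows$x[i, ], nrow = w, byrow = TRUE)
    for (s in shifts) {
      rot <- block[((seq_len(w) - 1 + s) %% w) + 1, , drop = FALSE]
      extra_x[[length(extra_x) + 1]] <- as.numeric(t(rot))
      extra_y <- c(extra_y, as.character(windows$y[i]))
      extra_rec <- c(extra_rec, windows$recording[i])
    }
  }
  windows$x <- rbind(windows$x, do.call(rbind, extra_x))
  windows$y <- factor(c(as.character(windows$y), extra_y),
                      levels = levels(windows$y))
  windows$recording <- c(windows$recording, extra_rec)
  windows$role <- c(windows$role, rep("train", length(extra_y)))
  windows
}

# Recording-level stratified split into train/test(/validation) counts.
split_recordings <- function(ids, groups, n_test, n_validation = 0) {
  y <- factor(groups, levels = c("AWNS", "AWS"))
  test <- character(0); val <- character(0)
  # stratified draw proportional to class sizes
  for (lev in levels(y)) {
    idx <- ids[y == lev]
    k_t <- round(n_test * length(idx) / length(ids))
    k_v <- round(n_validation * length(idx) / length(ids))
    pick <- sample(idx, min(length(idx) - 1, k_t + k_v))
    test <- c(test, head(pick, k_t))
    val <- c(val, pick[seq_len(length(pick) - k_t) + k_t])
  }
  # top up if rounding lost slots
  remaining <- setdiff(ids, c(test, val))
  while (length(test) < n_test && length(remaining) > 2) {
    pick <- sample(remaining, 1); test <- c(test, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(train = setdiff(ids, c(test, val)), test = test, validation = val)
}

f1_score <- function(pred, truth, positive = "AWS") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Evaluate the event-sequence group classifier
#'
#' Repeats, for `n_splits` seeded recording-level splits: build normalized
#' 20-event windows (training-set statistics only), augment the training
#' windows by rotation, train a random-forest window classifier on the
#' flattened windows, predict held-out windows, and aggregate window
#' predictions to recording predictions by majority vote (ties broken
#' toward AWS, the clinically conservative direction). Reports per-split
#' recording-level accuracy and F1 (positive class AWS).
#'
#' @param event_seqs Named list of `event_sequence` objects.
#' @param cohort Cohort table with metrics and groups for those recordings.
#' @param n_splits Number of train/test splits (default 5).
#' @param n_test,n_validation Recordings held out per split (defaults 4 and
#'   2, proportional to a 29/4/2 partition of 35; scale for other cohort
#'   sizes).
#' @param window Events per window (default 20).
#' @param shifts Rotation offsets for augmentation.
#' @param seed Base seed; split `s` uses `seed + s`.
#' @return Data frame with one row per split: `split`, `seed`, `accuracy`,
#'   `f1`, `n_test_recordings`, `n_train_windows`.
#' @export
evaluate_sequence_classifier <- function(event_seqs, cohort, n_splits = 5,
                                         n_test = 4, n_validation = 2,
                                         window = 20, shifts = c(5, 10, 15),
                                         seed = 1) {
  ids <- names(event_seqs)
  groups <- cohort$group[match(ids, cohort$participant_id)]
  rows <- lapply(seq_len(n_splits), function(s) {
    with_local_seed(seed + s, {
      split <- split_recordings(ids, groups, n_test, n_validation)
      win <- build_event_windows(event_seqs, cohort, split, window = window)
      win <- augment_rotation(win, shifts)
      tr <- win$role == "train"; te <- win$role == "test"
      if (!any(te) || length(unique(win$y[tr])) < 2)
        return(data.frame(split = s, seed = seed + s, accuracy = NA_real_,
                          f1 = NA_real_, n_test_recordings = length(split$test),
                          n_train_windows = sum(tr)))
      fit <- randomForest::randomForest(win$x[tr, , drop = FALSE], win$y[tr])
      pred <- predict(fit, win$x[te, , drop = FALSE])
      # majority vote per recording, ties toward AWS
      rec_pred <- tapply(as.character(pred), win$recording[te], function(p) {
        if (sum(p == "AWS") >= sum(p == "AWNS")) "AWS" else "AWNS"
      })
      truth <- cohort$group[match(names(rec_pred), cohort$participant_id)]
      data.frame(split = s, seed = seed + s,
                 accuracy = mean(rec_pred == truth),
                 f1 = f1_score(rec_pred, truth),
                 n_test_recordings = length(rec_pred),
                 n_train_windows = sum(tr))
    })
  })
  do.call(rbind, rows)
}
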