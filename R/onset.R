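#' Downsample a joystick trace to the 10 Hz feature grid
#'
#' Applies the same 300 ms moving-average windows (200 ms overlap) used for
#' the ECoG features to the joystick x/y traces and returns the radial
#' extension sqrt(x^2 + y^2) of the averaged position at each step.
#'
#' @param joystick_xy 2 x samples matrix (x and y in screen units).
#' @param fs sampling rate in Hz.
#' @return numeric vector of radial extensions, one per 100 ms step.
#' @export
downsample_joystick <- function(joystick_xy, fs = 1200) {
  stopifnot(nrow(joystick_xy) == 2)
  n_steps <- n_steps_for(ncol(joystick_xy), fs)
  if (n_steps < 1) stop("joystick trace shorter than one 300 ms window")
  w <- win_len(fs)
  s <- step_len(fs)
  # windowed means via cumulative sums
  cx <- c(0, cumsum(joystick_xy[1, ]))
  cy <- c(0, cumsum(joystick_xy[2, ]))
  starts <- (seq_len(n_steps) - 1L) * s
  mx <- (cx[starts + w + 1L] - cx[starts + 1L]) / w
  my <- (cy[starts + w + 1L] - cy[starts + 1L]) / w
  sqrt(mx^2 + my^2)
}

#' First strict threshold crossing of a radial series
#'
#' @param radial numeric series of radial extensions.
#' @param max_extension maximum radial extension of the joystick.
#' @return 1-based index of the first value strictly greater than
#'   `max_extension / 8`, or `NA` if the series never crosses.
#' @export
first_crossing <- function(radial, max_extension) {
  stopifnot(max_extension > 0)
  idx <- which(radial > max_extension / 8)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Label movement onsets from the downsampled joystick
#'
#' For each trial, the onset step is the first 100 ms step (after cursor
#' presentation) at which the moving-averaged radial extension strictly
#' exceeds one eighth of the maximum radial extension. All steps from the
#' beginning of the trial (target presentation) up to the onset are labeled
#' not-onset. Trials whose radial extension never crosses the threshold are
#' marked invalid and excluded from training and evaluation.
#'
#' @param radial 10 Hz radial series from [downsample_joystick()].
#' @param trials data.frame with `target_time` and `cursor_time` (seconds);
#'   an optional `hit_time` bounds the search window.
#' @param max_extension maximum radial extension (screen units).
#' @param fs sampling rate the radial series was derived from.
#' @return object of class `onset_labels`: data.frame with one row per trial
#'   (`trial`, `start_step`, `onset_step`, `valid`).
#' @export
label_onset <- function(radial, trials, max_extension, fs = 1200) {
  n_steps <- length(radial)
  stimes <- step_end_times(n_steps, fs)
  out <- data.frame(trial = trials$trial %||% seq_len(nrow(trials)),
                    start_step = NA_integer_, onset_step = NA_integer_,
                    valid = FALSE)
  for (i in seq_len(nrow(trials))) {
    upper <- if (!is.null(trials$hit_time)) trials$hit_time[i] + 0.5 else
      if (i < nrow(trials)) trials$target_time[i + 1] else
        stimes[n_steps]
    win <- which(stimes > trials$cursor_time[i] & stimes <= upper)
    if (length(win) == 0) next
    cross <- first_crossing(radial[win], max_extension)
    start <- max(first_step_after(trials$target_time[i]), 1L)
    out$start_step[i] <- start
    if (!is.na(cross)) {
      out$onset_step[i] <- win[cross]
      out$valid[i] <- TRUE
    }
  }
  structure(out, class = c("onset_labels", "data.frame"))
}

# Flattened 1 s FIFO-buffer dataset for the onset detector: for each valid
# trial, every step s from (start + buffer) to the onset step contributes the
# features of steps s-buffer .. s-1 as one row; the row is labeled "onset"
# iff s is the trial's onset step.
onset_dataset <- function(features, labels, buffer_len = 10,
                          selected = NULL) {
  vals <- features$values
  if (!is.null(selected)) vals <- vals[, selected, drop = FALSE]
  rows <- list(); ys <- list(); steps <- list(); trials <- list()
  for (i in which(labels$valid)) {
    s_first <- labels$start_step[i] + buffer_len
    s_last <- labels$onset_step[i]
    if (s_last < s_first || s_last > nrow(vals)) next
    ss <- s_first:s_last
    block <- t(vapply(ss, function(s)
      as.vector(vals[(s - buffer_len):(s - 1), , drop = FALSE]),
      numeric(buffer_len * ncol(vals))))
    rows[[length(rows) + 1]] <- block
    ys[[length(ys) + 1]] <- ss == s_last
    steps[[length(steps) + 1]] <- ss
    trials[[length(trials) + 1]] <- rep(labels$trial[i], length(ss))
  }
  if (length(rows) == 0) stop("no usable onset-labeled steps")
  list(x = do.call(rbind, rows),
       y = factor(ifelse(unlist(ys), "onset", "rest"),
                  levels = c("rest", "onset")),
       step = unlist(steps), trial = unlist(trials))
}

#' Train the class-weighted onset SVM
#'
#' Fits an RBF-kernel SVM on flattened 1 s (10-step) feature buffers with
#' per-class penalties set to the inverse ratio of the class sizes, so the
#' rare onset class is not swamped by the not-onset class. Probabilities are
#' obtained by Platt-style sigmoid calibration on the training data. RBF
#' hyperparameters (C, gamma) are chosen by a grid search on trial-wise
#' cross-validation folds of the training set when a grid with more than one
#' point is supplied.
#'
#' @param features a [feature_series()].
#' @param labels an `onset_labels` object from [label_onset()].
#' @param selected integer indices of the features to use (e.g. from
#'   [forward_feature_selection()]); `NULL` uses all.
#' @param buffer_len FIFO buffer length in steps (default 10 = 1 s).
#' @param threshold onset probability threshold (default 0.3).
#' @param cost_grid,gamma_grid candidate C and gamma values; `NULL` gamma
#'   defaults to 1 / n_input_dims.
#' @param tune_folds folds for the internal hyperparameter search.
#' @param seed seed for fold assignment.
#' @return object of class `onset_model`.
#' @export
train_onset <- function(features, labels, selected = NULL, buffer_len = 10,
                        threshold = 0.3, cost_grid = c(1, 10),
                        gamma_grid = NULL, tune_folds = 3, seed = 1) {
  ds <- onset_dataset(features, labels, buffer_len, selected)
  if (nlevels(droplevels(ds$y)) < 2) {
    stop("training data contain a single class; cannot fit onset detector")
  }
  ctr <- colMeans(ds$x)
  scl <- apply(ds$x, 2, stats::sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(ds$x, 2, ctr), 2, scl, "/")
  n_by <- table(ds$y)
  wts <- c(rest = 1, onset = as.numeric(n_by["rest"] / n_by["onset"]))
  if (is.null(gamma_grid)) gamma_grid <- 1 / ncol(x)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  if (nrow(grid) > 1) {
    folds <- assign_folds(ds$trial, tune_folds, seed)
    score <- vapply(seq_len(nrow(grid)), function(g) {
      f1s <- vapply(seq_len(tune_folds), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(ds$y[tr])) < 2 || !any(!tr)) return(NA_real_)
        fit <- with_seed(seed, e1071::svm(
          x[tr, , drop = FALSE], ds$y[tr], kernel = "radial",
          cost = grid$cost[g], gamma = grid$gamma[g], class.weights = wts,
          probability = TRUE, scale = FALSE))
        p <- svm_onset_prob(fit, x[!tr, , drop = FALSE])
        f1_from_pred(p > threshold, ds$y[!tr] == "onset")
      }, numeric(1))
      mean(f1s, na.rm = TRUE)
    }, numeric(1))
    best <- grid[which.max(score), ]
  } else {
    best <- grid[1, ]
  }
  fit <- with_seed(seed, e1071::svm(
    x, ds$y, kernel = "radial", cost = best$cost, gamma = best$gamma,
    class.weights = wts, probability = TRUE, scale = FALSE))
  structure(list(svm = fit, center = ctr, scale = scl, selected = selected,
                 buffer_len = buffer_len, threshold = threshold,
                 class_weights = wts, cost = best$cost, gamma = best$gamma),
            class = "onset_model")
}

#' @export
print.onset_model <- function(x, ...) {
  cat(sprintf(paste0("<onset_model> weighted RBF SVM (C = %g, gamma = %g, ",
                     "onset penalty x%.1f), buffer %d steps, threshold %g\n"),
              x$cost, x$gamma, x$class_weights[["onset"]], x$buffer_len,
              x$threshold))
  invisible(x)
}

svm_onset_prob <- function(fit, x) {
  pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
  as.numeric(pr[, "onset"])
}

f1_from_pred <- function(pred, truth) {
  f1_score(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                FN = sum(!pred & truth), TN = sum(!pred & !truth)),
           quiet = TRUE)
}

#' Onset probability from a full feature buffer
#'
#' @param model an `onset_model`.
#' @param buffer a buffer_len x k matrix of the selected features over the
#'   last 1 s (or the equivalent flattened vector). A partial buffer yields
#'   `NA` ("not ready"), never a prediction.
#' @return probability of an onset at the next step, in `[0, 1]`, or `NA` if
#'   the buffer is not full.
#' @export
predict_onset_probability <- function(model, buffer) {
  k <- length(model$center) / model$buffer_len
  if (is.matrix(buffer)) {
    if (nrow(buffer) < model$buffer_len) return(NA_real_)
    stopifnot(nrow(buffer) == model$buffer_len, ncol(buffer) == k)
    buffer <- as.vector(buffer)
  } else if (length(buffer) != model$buffer_len * k) {
    return(NA_real_)
  }
  x <- (buffer - model$center) / model$scale
  svm_onset_prob(model$svm, matrix(x, 1))
}

#' Per-step onset probabilities for labeled trials
#'
#' Runs the detector over every labeled step of every valid trial (each
#' trial starts with an empty buffer; predictions begin once 1 s of features
#' has accumulated, and stop at the trial's onset step).
#'
#' @param model an `onset_model`.
#' @param features a [feature_series()].
#' @param labels an `onset_labels` object.
#' @return data.frame with `trial`, `step`, `p` and logical `is_onset`.
#' @export
detect_onsets <- function(model, features, labels) {
  ds <- onset_dataset(features, labels, model$buffer_len, model$selected)
  x <- sweep(sweep(ds$x, 2, model$center), 2, model$scale, "/")
  data.frame(trial = ds$trial, step = ds$step,
             p = svm_onset_prob(model$svm, x),
             is_onset = ds$y == "onset")
}

#' Threshold a probability series into predicted onset steps
#'
#' @param p_series numeric probabilities (one per step).
#' @param threshold decision threshold; steps with `p > threshold` are
#'   flagged (default 0.3).
#' @return integer indices of the flagged steps.
#' @export
threshold_onsets <- function(p_series, threshold = 0.3) {
  which(p_series > threshold)
}

#' F1-score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; true negatives never enter, which makes
#' the score robust to the extreme class imbalance of per-step onset
#' detection. A zero denominator (no positives anywhere) returns 0 with a
#' warning.
#'
#' @param counts list or vector with elements `TP`, `FP`, `FN`.
#' @param quiet suppress the zero-denominator warning.
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(counts, quiet = FALSE) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  denom <- 2 * tp + fp + fn
  if (denom == 0) {
    if (!quiet) warning("F1 undefined (no positives); returning 0")
    return(0)
  }
  2 * tp / denom
}

#' Score predicted onset steps against the labels
#'
#' Per-step scoring over the labeled evaluation steps: a prediction at a
#' trial's true onset step is a TP, a miss there is a FN, and predictions at
#' not-onset steps are FPs. FPs more than 200 ms (2 steps) away from every
#' true onset are additionally counted in `FP_far`.
#'
#' @param predicted integer step indices flagged as onsets.
#' @param detections data.frame from [detect_onsets()] (provides the
#'   evaluation steps and truth), or any data.frame with `step` and
#'   `is_onset`.
#' @return object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`, `FP_far`.
#' @export
evaluate_onsets <- function(predicted, detections) {
  eval_steps <- detections$step
  truth <- detections$is_onset
  pred <- eval_steps %in% predicted
  onset_steps <- eval_steps[truth]
  fp_steps <- eval_steps[pred & !truth]
  far <- if (length(fp_steps)) {
    vapply(fp_steps, function(s) min(abs(s - onset_steps)) > 2, logical(1))
  } else logical(0)
  structure(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                 FN = sum(!pred & truth), TN = sum(!pred & !truth),
                 FP_far = sum(far)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d (far: %d)  FN %d  TN %d   F1 = %.4f\n",
              x$TP, x$FP, x$FP_far, x$FN, x$TN, f1_score(x, quiet = TRUE)))
  invisible(x)
}

#' Cross-validated onset detection
#'
#' Trial-wise 5-fold cross-validation of the full onset pipeline: the
#' weighted SVM is trained on four folds of trials and applied to the
#' held-out trials; predictions are pooled over folds and scored per step.
#'
#' @inheritParams train_onset
#' @param n_folds number of folds.
#' @return list with pooled `counts` (a `confusion_counts`), `f1`, and the
#'   per-step `detections` data.frame (with fold assignment).
#' @export
evaluate_onset_cv <- function(features, labels, selected = NULL,
                              buffer_len = 10, threshold = 0.3,
                              cost_grid = 1, gamma_grid = NULL,
                              n_folds = 5, seed = 1) {
  valid_trials <- labels$trial[labels$valid]
  folds <- assign_folds(valid_trials, n_folds, seed)
  parts <- list()
  for (f in seq_len(n_folds)) {
    tr_labels <- labels[labels$trial %in% valid_trials[folds != f], ]
    te_labels <- labels[labels$trial %in% valid_trials[folds == f], ]
    if (!nrow(te_labels)) next
    model <- train_onset(features, tr_labels, selected, buffer_len,
                         threshold, cost_grid, gamma_grid, seed = seed)
    det <- detect_onsets(model, features, te_labels)
    det$fold <- f
    parts[[f]] <- det
  }
  detections <- do.call(rbind, parts)
  predicted <- detections$step[detections$p > threshold]
  counts <- evaluate_onsets(predicted, detections)
  list(counts = counts, f1 = f1_score(counts, quiet = TRUE),
       detections = detections)
}

#' Per-feature onset-prediction confidence map
#'
#' For each feature taken alone, runs the onset detector through `n_reps`
#' randomly re-folded 5-fold cross-validations, producing `n_reps` F1
#' values, and tests whether their mean exceeds zero (one-sided t-test).
#' The p-value is reported as a confidence index `-log(p)` (natural log);
#' an index above 3 corresponds to `p < 0.05`. Zero-variance F1 samples make
#' the t-test degenerate; such features are flagged and reported with a
#' `+Inf` (all F1 > 0) or 0 (all F1 = 0) index instead of a fabricated
#' p-value.
#'
#' @inheritParams train_onset
#' @param feature_subset indices of features to map (default: all).
#' @param n_reps number of re-folded cross-validation runs (default 20).
#' @param n_folds folds per run.
#' @return data.frame with `feature`, `mean_f1`, `p_value`, `confidence`,
#'   `degenerate`.
#' @export
feature_confidence_map <- function(features, labels, feature_subset = NULL,
                                   n_reps = 20, n_folds = 5, buffer_len = 10,
                                   threshold = 0.3, seed = 1) {
  if (is.null(feature_subset)) feature_subset <- seq_len(ncol(features$values))
  res <- lapply(feature_subset, function(j) {
    f1s <- vapply(seq_len(n_reps), function(r) {
      evaluate_onset_cv(features, labels, selected = j,
                        buffer_len = buffer_len, threshold = threshold,
                        n_folds = n_folds,
                        seed = seed * 1000L + r)$f1
    }, numeric(1))
    if (stats::sd(f1s) == 0) {
      conf <- if (mean(f1s) > 0) Inf else 0
      data.frame(feature = j, mean_f1 = mean(f1s), p_value = NA_real_,
                 confidence = conf, degenerate = TRUE)
    } else {
      p <- stats::t.test(f1s, mu = 0, alternative = "greater")$p.value
      data.frame(feature = j, mean_f1 = mean(f1s), p_value = p,
                 confidence = -log(p), degenerate = FALSE)
    }
  })
  do.call(rbind, res)
}
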