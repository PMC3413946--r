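#' Feature series container
#'
#' Holds the per-step ECoG features: for every 100 ms step and every channel,
#' the mu (8--12 Hz), beta (18--26 Hz) and high-gamma (70--170 Hz) mean
#' spectral amplitudes plus the local motor potential (LMP, the raw window
#' mean). `values` is a steps x M matrix with M = 4 x n_channels.
#'
#' @param values numeric matrix, steps x M.
#' @param step_times numeric vector of window-end times in seconds.
#' @param labels data.frame with columns `channel` and `band`
#'   (`"mu"`, `"beta"`, `"gamma"`, `"lmp"`), one row per column of `values`.
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(values, step_times, labels) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(step_times), ncol(values) == nrow(labels))
  if (length(step_times) > 1) {
    stopifnot(max(abs(diff(step_times) - STEP_S)) < 1e-8)
  }
  stopifnot(all(labels$band %in% c("mu", "beta", "gamma", "lmp")))
  colnames(values) <- paste0("ch", labels$channel, "_", labels$band)
  structure(list(values = values, step_times = as.numeric(step_times),
                 labels = labels),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d steps x %d features (%d channels x 4 bands)\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels$channel))))
  cat(sprintf("  time %.1f .. %.1f s (100 ms steps)\n",
              x$step_times[1], x$step_times[length(x$step_times)]))
  invisible(x)
}

#' Common average reference (CAR) spatial filter
#'
#' Subtracts the across-channel mean from every sample, removing signal
#' components common to all electrodes (reference drift, spatially broad
#' noise). Requires at least two channels.
#'
#' @param signal channels x samples numeric matrix.
#' @return matrix of the same shape with zero column means.
#' @export
apply_car <- function(signal) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2) {
    stop("CAR needs at least 2 channels; got ", nrow(signal))
  }
  sweep(signal, 2, colMeans(signal), "-")
}

# complex exponential basis for evaluating an AR transfer function at the
# integer frequencies; rows = frequencies, cols = lag 1..order
ar_basis <- function(freqs, order, fs) {
  exp(-2i * pi * outer(freqs, seq_len(order)) / fs)
}

#' Autoregressive amplitude spectrum of one analysis window
#'
#' Fits an AR model of the given order by Burg's method and evaluates the
#' square root of its power spectral density at integer frequencies
#' 0--200 Hz (1 Hz bins). A constant (zero-variance) window cannot support a
#' spectral estimate; it yields an all-zero spectrum flagged with
#' `attr(, "degenerate") = TRUE` rather than an error.
#'
#' @param window numeric vector, one channel's samples (300 ms, i.e. 360
#'   samples at 1200 Hz).
#' @param fs sampling rate in Hz; must exceed 400 so that the 0--200 Hz range
#'   is below Nyquist.
#' @param order AR model order (default 25).
#' @return numeric vector of 201 non-negative amplitudes, one per 1 Hz bin.
#' @export
ar_spectrum <- function(window, fs = 1200, order = 25) {
  stopifnot(fs > 400, order < length(window))
  freqs <- 0:200
  if (stats::var(window) < .Machine$double.eps) {
    out <- rep(0, length(freqs))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::ar.burg(window, aic = FALSE, order.max = order,
                        demean = TRUE)
  ar_amplitudes(fit$ar, fit$var.pred, ar_basis(freqs, order, fs), fs)
}

ar_amplitudes <- function(coefs, var_pred, basis, fs) {
  denom <- Mod(1 - as.vector(basis %*% coefs))^2
  sqrt(pmax(var_pred / fs / denom, 0))
}

# inclusive integer-Hz band edges
BAND_BINS <- list(mu = 8:12, beta = 18:26, gamma = 70:170)

#' Band-average features from an amplitude spectrum
#'
#' Arithmetic means of the 1 Hz amplitude bins over the mu (8--12 Hz), beta
#' (18--26 Hz) and high-gamma (70--170 Hz) bands, edges inclusive.
#'
#' @param spec numeric vector of 201 amplitudes (bins 0--200 Hz).
#' @return named numeric vector `c(mu =, beta =, gamma =)`.
#' @export
band_features <- function(spec) {
  stopifnot(length(spec) == 201)
  vapply(BAND_BINS, function(bins) mean(spec[bins + 1]), numeric(1))
}

#' Local motor potential of one window
#'
#' The LMP is the mean of the raw time-domain signal over the 300 ms window;
#' this slow component of the motor-cortical signal carries movement
#' information not visible in the band amplitudes.
#'
#' @param window numeric vector of samples.
#' @return scalar mean.
#' @export
lmp <- function(window) {
  mean(window)
}

#' Extract the per-step feature series from a session
#'
#' Applies the CAR filter, then for every 100 ms step converts each channel's
#' 300 ms window (200 ms overlap) into 1 Hz amplitude bins (0--200 Hz) with a
#' Burg AR model of order 25, averages the mu/beta/gamma bands and computes
#' the LMP on the same (CAR-filtered) window. Channels listed in
#' `exclude_channels` (e.g. occipital electrodes) are dropped before
#' re-referencing.
#'
#' @param session an `ecog_session` (see [generate_session()]) or a list with
#'   elements `signal` (channels x samples) and `fs`.
#' @param exclude_channels integer channel indices to drop, or `NULL`.
#' @param ar_order AR model order for the spectral estimate.
#' @return a [feature_series()].
#' @export
extract_features <- function(session, exclude_channels = NULL, ar_order = 25) {
  signal <- session$signal
  fs <- session$fs %||% 1200
  if (!is.null(exclude_channels) && length(exclude_channels)) {
    keep <- setdiff(seq_len(nrow(signal)), exclude_channels)
    channel_ids <- keep
    signal <- signal[keep, , drop = FALSE]
  } else {
    channel_ids <- seq_len(nrow(signal))
  }
  n_steps <- n_steps_for(ncol(signal), fs)
  if (n_steps < 1) {
    stop("session too short for a single 300 ms window")
  }
  signal <- apply_car(signal)
  w <- win_len(fs)
  s <- step_len(fs)
  basis <- ar_basis(0:200, ar_order, fs)
  nch <- nrow(signal)
  values <- matrix(0, n_steps, 4L * nch)
  for (ci in seq_len(nch)) {
    x <- signal[ci, ]
    col0 <- (ci - 1L) * 4L
    for (i in seq_len(n_steps)) {
      win <- x[((i - 1L) * s + 1L):((i - 1L) * s + w)]
      if (stats::var(win) < .Machine$double.eps) {
        bands <- c(mu = 0, beta = 0, gamma = 0)
      } else {
        fit <- stats::ar.burg(win, aic = FALSE, order.max = ar_order,
                              demean = TRUE)
        bands <- band_features(ar_amplitudes(fit$ar, fit$var.pred, basis, fs))
      }
      values[i, col0 + 1L] <- bands[["mu"]]
      values[i, col0 + 2L] <- bands[["beta"]]
      values[i, col0 + 3L] <- bands[["gamma"]]
      values[i, col0 + 4L] <- mean(win)
    }
  }
  labels <- data.frame(
    channel = rep(channel_ids, each = 4L),
    band = rep(c("mu", "beta", "gamma", "lmp"), nch),
    stringsAsFactors = FALSE
  )
  feature_series(values, step_end_times(n_steps, fs), labels)
}

#' Normalize spectral features to a rest condition
#'
#' Divides each spectral (mu/beta/gamma) feature by its mean over the given
#' rest steps, so a value of 1 means no task-related modulation and a value
#' of 2 means the band amplitude doubled relative to rest. The LMP is a
#' signed time-domain average with no meaningful ratio scale and is left
#' unscaled. Intended for visualization/diagnostics; the classifiers consume
#' un-normalized features.
#'
#' @param features a [feature_series()].
#' @param rest_steps integer step indices of the rest condition (e.g. the
#'   inter-trial interval).
#' @return a [feature_series()] with normalized spectral columns.
#' @export
normalize_to_rest <- function(features, rest_steps) {
  stopifnot(inherits(features, "feature_series"))
  if (length(rest_steps) == 0) stop("rest step set is empty")
  spectral <- which(features$labels$band != "lmp")
  rest_mean <- colMeans(features$values[rest_steps, spectral, drop = FALSE])
  if (any(rest_mean == 0)) {
    stop("zero rest-condition mean for feature(s) ",
         paste(spectral[rest_mean == 0], collapse = ", "))
  }
  values <- features$values
  values[, spectral] <- sweep(values[, spectral, drop = FALSE], 2,
                              rest_mean, "/")
  feature_series(values, features$step_times, features$labels)
}

#' Greedy forward feature selection by cross-validated accuracy
#'
#' Starting from the empty set, repeatedly adds the feature whose inclusion
#' maximizes the mean 5-fold cross-validated accuracy of the downstream
#' classifier (a class-weighted RBF SVM by default). Folds are assigned
#' trial-wise when a `groups` vector is given, so overlapping windows from
#' one trial never straddle a fold boundary. Ties are broken toward the
#' lowest feature index, making the selection order reproducible for a fixed
#' seed.
#'
#' @param features a [feature_series()] or a plain numeric matrix (rows =
#'   observations).
#' @param labels class label per row.
#' @param k number of features to select (default 20).
#' @param groups optional grouping vector (e.g. trial id) for fold
#'   assignment.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param score_fn optional function(x_train, y_train, x_test, y_test) ->
#'   scalar score; defaults to weighted-SVM accuracy.
#' @return integer vector of `k` feature indices in selection order.
#' @export
forward_feature_selection <- function(features, labels, k = 20,
                                      groups = NULL, n_folds = 5, seed = 1,
                                      score_fn = NULL) {
  x <- if (inherits(features, "feature_series")) features$values else
    as.matrix(features)
  m <- ncol(x)
  if (k > m) stop("k = ", k, " exceeds number of features (", m, ")")
  if (k == 0) return(integer(0))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes for feature selection")
  if (is.null(groups)) groups <- seq_along(y)
  folds <- assign_folds(groups, n_folds, seed)
  if (is.null(score_fn)) score_fn <- svm_accuracy_score
  selected <- integer(0)
  for (step in seq_len(k)) {
    candidates <- setdiff(seq_len(m), selected)
    scores <- vapply(candidates, function(j) {
      cols <- c(selected, j)
      mean(vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
        score_fn(x[tr, cols, drop = FALSE], y[tr],
                 x[!tr, cols, drop = FALSE], y[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    selected <- c(selected, candidates[which.max(scores)])
  }
  selected
}

# trial-wise fold assignment: whole groups go to one fold
assign_folds <- function(groups, n_folds, seed) {
  ug <- unique(groups)
  fold_of <- with_seed(seed, {
    sample(rep_len(seq_len(n_folds), length(ug)))
  })
  fold_of[match(groups, ug)]
}

#' Stratified trial-wise fold assignment
#'
#' Spreads each stratum's members (e.g. each direction's trials) round-robin
#' over the folds after shuffling, so every training fold keeps a balanced
#' representation of every stratum.
#'
#' @param strata stratum label per observation.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold assignment per observation.
#' @export
assign_folds_stratified <- function(strata, n_folds, seed) {
  folds <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      folds[idx] <- rep_len(sample(seq_len(n_folds)), length(idx))
    }
  })
  folds
}

# balanced accuracy (mean per-class recall) of a class-weighted RBF SVM;
# plain accuracy saturates at the majority-class rate on the heavily
# imbalanced onset labels and cannot rank features
svm_accuracy_score <- function(x_train, y_train, x_test, y_test) {
  w <- rev(as.vector(table(y_train))) / length(y_train)
  names(w) <- levels(y_train)
  fit <- e1071::svm(x_train, y_train, kernel = "radial", class.weights = w,
                    scale = apply(x_train, 2, stats::sd) > 0)
  pred <- predict(fit, x_test)
  recalls <- vapply(levels(y_test), function(cl) {
    n <- sum(y_test == cl)
    if (n == 0) NA_real_ else sum(pred == cl & y_test == cl) / n
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
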