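#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end decoding pipeline with defaults
#' at the study's stated values: 300 ms analysis windows advanced every
#' 100 ms, AR order 25 with 1 Hz bins 0--200 Hz, mu 8--12 / beta 18--26 /
#' gamma 70--170 Hz band averages, a 10-step (1 s) FIFO buffer with onset
#' probability threshold 0.3 and inverse-class-size SVM penalties, 20
#' forward-selected features, direction windows of T = 10 steps with the
#' penalty chosen by cross-validation, and a repositioning grid alpha = 0 to
#' 1 in steps of 0.05.
#'
#' @param sim a [sim_config()] describing the synthetic session (or `NULL`
#'   when `session` is supplied to [run_pipeline()] directly).
#' @param n_selected number of forward-selected features (`NULL` = use all
#'   features and skip selection).
#' @param exclude_channels channel indices dropped before CAR (e.g.
#'   occipital electrodes).
#' @param onset_threshold probability threshold for flagging onsets.
#' @param buffer_len FIFO buffer length in steps.
#' @param ar_order AR model order.
#' @param cost_grid,gamma_grid SVM hyperparameter grids.
#' @param direction_T direction window length in steps.
#' @param lambda direction penalty; `NULL` selects it by cross-validation
#'   over `lambda_grid`.
#' @param lambda_grid candidate penalties for [select_lambda()].
#' @param direction_features `"selected"` to reuse the forward-selected
#'   features for direction classification, `"all"` to use every feature.
#' @param alpha_grid repositioning fractions to evaluate.
#' @param n_folds trial-wise cross-validation folds.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_selected = 20,
                            exclude_channels = integer(0),
                            onset_threshold = 0.3, buffer_len = 10,
                            ar_order = 25, cost_grid = 1, gamma_grid = NULL,
                            direction_T = 10, lambda = NULL,
                            lambda_grid = 10^seq(-3, 1, length.out = 9),
                            direction_features = c("selected", "all"),
                            alpha_grid = seq(0, 1, by = 0.05),
                            n_folds = 5, seed = 1) {
  structure(list(sim = sim, n_selected = n_selected,
                 exclude_channels = exclude_channels,
                 window_s = WINDOW_S, step_s = STEP_S,
                 bands = BAND_BINS, ar_order = ar_order,
                 onset_threshold = onset_threshold,
                 buffer_len = buffer_len, cost_grid = cost_grid,
                 gamma_grid = gamma_grid, direction_T = direction_T,
                 lambda = lambda, lambda_grid = lambda_grid,
                 direction_features = match.arg(direction_features),
                 alpha_grid = alpha_grid, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full decoding pipeline
#'
#' Generates (or takes) a session, extracts features, labels onsets from the
#' joystick, optionally forward-selects features, cross-validates the onset
#' detector, cross-validates the per-direction networks on the 1 s
#' pre-onset windows, and simulates the brain-assisted targeting task with
#' an optimized repositioning fraction. Deterministic given the
#' configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param session optional `ecog_session` to analyse instead of generating
#'   one from `config$sim`.
#' @return list of class `ecog_report` with elements `onset`, `direction`,
#'   `targeting`, `hyperparameters`, `n_trials`.
#' @export
run_pipeline <- function(config, session = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(session)) {
    if (is.null(config$sim)) stop("pipeline stage [session]: no input")
    session <- generate_session(config$sim)
  }
  features <- tryCatch(
    extract_features(session, config$exclude_channels, config$ar_order),
    error = function(e) stop("pipeline stage [features]: ",
                             conditionMessage(e)))
  radial <- downsample_joystick(session$joystick, session$fs)
  labels <- label_onset(radial, session$trials,
                        session$max_radial_extension, session$fs)

  selected <- NULL
  if (!is.null(config$n_selected) &&
        config$n_selected < ncol(features$values)) {
    ds <- onset_dataset(features, labels, buffer_len = 1)
    selected <- forward_feature_selection(
      ds$x, ds$y, k = config$n_selected, groups = ds$trial,
      n_folds = config$n_folds, seed = config$seed)
  }

  onset <- tryCatch(
    evaluate_onset_cv(features, labels, selected,
                      buffer_len = config$buffer_len,
                      threshold = config$onset_threshold,
                      cost_grid = config$cost_grid,
                      gamma_grid = config$gamma_grid,
                      n_folds = config$n_folds, seed = config$seed),
    error = function(e) stop("pipeline stage [onset]: ",
                             conditionMessage(e)))

  dir_sel <- if (config$direction_features == "selected") selected else NULL
  win <- extract_preonset_windows(features, ifelse(labels$valid,
                                                  labels$onset_step, NA),
                                  config$direction_T, dir_sel)
  directions <- session$trials$target_index[win$trial]
  nd <- session$n_directions
  lambda <- config$lambda
  if (is.null(lambda)) {
    lambda <- select_lambda(win$windows, directions, config$lambda_grid,
                            nd, config$n_folds, config$seed)$lambda
  }
  folds <- assign_folds_stratified(directions, config$n_folds, config$seed)
  pred <- rep(NA_integer_, length(directions))
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    if (!any(!tr)) next
    fit <- tryCatch(
      fit_direction_models(win$windows[tr, , , drop = FALSE],
                           directions[tr], lambda, nd),
      error = function(e) stop("pipeline stage [direction]: ",
                               conditionMessage(e)))
    for (i in which(!tr)) {
      pred[i] <- classify_direction(fit, win$windows[i, , ])
    }
  }
  ang <- angular_error(pred, directions, nd)
  direction <- list(predicted = pred, true = directions,
                    accuracy = mean(pred == directions),
                    mean_angular_error = mean(ang),
                    sd_angular_error = stats::sd(ang),
                    chance = chance_angular_stats(nd), lambda = lambda)

  layout <- target_layout(nd, session$max_radial_extension)
  trials_used <- session$trials[win$trial, ]
  speed <- average_speed(trials_used, layout$radius)
  opt <- optimize_alpha(data.frame(true = directions, predicted = pred),
                        layout, speed, config$alpha_grid)
  baseline <- trials_used$hit_time - trials_used$onset_time
  assisted <- vapply(seq_along(pred), function(i) movement_time(
    reposition_cursor(pred[i], opt$alpha, layout),
    target_position(directions[i], layout), speed), numeric(1))
  targeting <- c(list(alpha = opt$alpha, mean_time = opt$mean_time,
                      alpha_grid = opt$alpha_grid, speed = speed),
                 compare_with_without(baseline, assisted))

  structure(list(
    onset = list(f1 = onset$f1, counts = onset$counts),
    direction = direction, targeting = targeting,
    hyperparameters = list(selected_features = selected, lambda = lambda,
                           svm_cost = config$cost_grid,
                           alpha = opt$alpha, seed = config$seed),
    n_trials = nrow(session$trials)), class = "ecog_report")
}

#' @export
print.ecog_report <- function(x, ...) {
  cat("== decoding report ==\n")
  cat(sprintf("trials: %d\n", x$n_trials))
  cat(sprintf("onset:  F1 = %.3f  (TP %d, FP %d, FN %d)\n", x$onset$f1,
              x$onset$counts$TP, x$onset$counts$FP, x$onset$counts$FN))
  cat(sprintf(paste0("direction: accuracy = %.1f%% (chance 12.5%%), ",
                     "angular error %.1f +- %.1f deg ",
                     "(chance %.1f +- %.1f), lambda = %g\n"),
              100 * x$direction$accuracy, x$direction$mean_angular_error,
              x$direction$sd_angular_error, x$direction$chance[["mean"]],
              x$direction$chance[["sd"]], x$direction$lambda))
  cat(sprintf(paste0("targeting: alpha* = %.2f, baseline %.0f ms -> ",
                     "assisted %.0f ms, %.0f%% improved (p = %.2g)\n"),
              x$targeting$alpha, 1000 * x$targeting$mean_baseline,
              1000 * x$targeting$mean_assisted, x$targeting$pct_improved,
              x$targeting$p_value))
  invisible(x)
}
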