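test_that("joystick downsampling matches the windowed-mean oracle", {
  xy <- rbind(rep(3, 1200), rep(4, 1200))
  expect_equal(downsample_joystick(xy), rep(5, 8))
  expect_equal(downsample_joystick(rbind(rep(0, 720), rep(0, 720))),
               rep(0, 4))
  # linear ramp: windowed mean computed directly
  n <- 1200
  x <- seq(0, 1, length.out = n)
  xy2 <- rbind(x, -2 * x)
  got <- downsample_joystick(xy2)
  for (i in seq_along(got)) {
    idx <- ((i - 1) * 120 + 1):((i - 1) * 120 + 360)
    expect_equal(got[i], sqrt(mean(x[idx])^2 + (2 * mean(x[idx]))^2))
  }
  expect_error(downsample_joystick(rbind(1:10, 1:10)), "shorter")
})

test_that("onset labeling uses a strict threshold crossing", {
  expect_equal(first_crossing(c(0, 0.5, 1.2, 3), 8), 3L)
  expect_true(is.na(first_crossing(c(0, 0.5, 0.9, 1), 8)))
  expect_equal(first_crossing(c(1.0, 1.0001), 8), 2L)  # strict ">"
  s <- small_session()
  lab <- small_labels()
  expect_s3_class(lab, "onset_labels")
  expect_true(all(lab$valid))
  expect_true(all(lab$onset_step > lab$start_step))
  # a trial whose joystick never crosses is excluded
  frozen <- s
  rng <- seq(1, s$trials$hit_time[1] * s$fs + s$fs)
  frozen$joystick[, rng] <- 0
  lab2 <- label_onset(downsample_joystick(frozen$joystick, s$fs),
                      frozen$trials, s$max_radial_extension, s$fs)
  expect_false(lab2$valid[1])
  expect_true(all(lab2$valid[-1]))
})

test_that("F1 identities and the confusion arithmetic hold", {
  expect_equal(f1_score(list(TP = 5, FP = 0, FN = 0)), 1.0)
  expect_equal(f1_score(list(TP = 0, FP = 3, FN = 4)), 0.0)
  expect_equal(f1_score(list(TP = 231, FP = 239, FN = 85)),
               2 * 231 / (2 * 231 + 239 + 85))
  expect_warning(z <- f1_score(list(TP = 0, FP = 0, FN = 0)), "undefined")
  expect_equal(z, 0)
  # TN never enters
  expect_equal(f1_score(list(TP = 4, FP = 2, FN = 1, TN = 10)),
               f1_score(list(TP = 4, FP = 2, FN = 1, TN = 1e6)))
})

test_that("thresholding flags exactly the steps above threshold", {
  expect_equal(threshold_onsets(c(0.1, 0.35, 0.2), 0.3), 2L)
  expect_equal(threshold_onsets(c(0.1, 0.2), 0.3), integer(0))
  expect_equal(threshold_onsets(c(0.1, 0.2, 0.3), 0), 1:3)
  # monotonicity: lowering the threshold never loses predictions
  set.seed(2)
  p <- runif(50)
  for (th in c(0.8, 0.5, 0.2)) {
    expect_true(all(threshold_onsets(p, 0.8) %in% threshold_onsets(p, th)))
  }
})

test_that("per-step scoring separates hits, misses and far false alarms", {
  det <- data.frame(trial = rep(1:2, each = 5), step = c(1:5, 11:15),
                    p = 0, is_onset = c(rep(FALSE, 4), TRUE,
                                        rep(FALSE, 4), TRUE))
  perfect <- evaluate_onsets(c(5, 15), det)
  expect_equal(perfect[c("TP", "FP", "FN")], list(TP = 2, FP = 0, FN = 0))
  expect_equal(f1_score(perfect), 1)
  nothing <- evaluate_onsets(integer(0), det)
  expect_equal(nothing$TP, 0)
  expect_equal(nothing$FN, 2)
  # FP at step 2 is > 200 ms from the onset at step 5; FP at step 4 is not
  near_far <- evaluate_onsets(c(2, 4, 5, 15), det)
  expect_equal(near_far$FP, 2)
  expect_equal(near_far$FP_far, 1)
  expect_lte(near_far$FP_far, near_far$FP)
})

test_that("random predictions produce the expected false-positive rate", {
  set.seed(44)
  n <- 4000
  det <- data.frame(trial = rep(1:200, each = 20), step = 1:n, p = 0,
                    is_onset = rep(c(rep(FALSE, 19), TRUE), 200))
  q <- 0.15
  pred <- which(runif(n) < q)
  counts <- evaluate_onsets(pred, det)
  fp_rate <- counts$FP / sum(!det$is_onset)
  expect_equal(fp_rate, q, tolerance = 0.15)
})

test_that("the trained detector rejects partial buffers and bounds outputs", {
  f <- small_features()
  lab <- small_labels()
  model <- train_onset(f, lab, selected = 1:8, cost_grid = 1, seed = 3)
  expect_s3_class(model, "onset_model")
  full <- f$values[1:10, 1:8]
  p <- predict_onset_probability(model, full)
  expect_true(p >= 0 && p <= 1)
  expect_true(is.na(predict_onset_probability(model, full[1:9, ])))
  # determinism: retraining with the same seed gives identical decisions
  model2 <- train_onset(f, lab, selected = 1:8, cost_grid = 1, seed = 3)
  expect_equal(predict_onset_probability(model2, full), p)
  # probabilities peak at true onsets relative to rest steps
  det <- detect_onsets(model, f, lab)
  expect_gt(median(det$p[det$is_onset]), median(det$p[!det$is_onset]))
})

test_that("training fails cleanly on single-class data", {
  f <- small_features()
  lab <- small_labels()
  lab$valid[1:nrow(lab)] <- FALSE
  expect_error(train_onset(f, lab), "no usable onset")
})

test_that("held-out F1 beats the permutation null on strong effects only", {
  f <- small_features()
  lab <- small_labels()
  # the informative subset: gamma and LMP of the movement-modulated channels
  sel <- which(f$labels$channel %in% 1:3 & f$labels$band %in%
                 c("gamma", "lmp"))
  cv <- evaluate_onset_cv(f, lab, selected = sel, n_folds = 4, seed = 11)
  null_f1 <- perm_null_f1(cv$detections, threshold = 0.3, n_perm = 200,
                          seed = 12)
  # strong movement-locked effects: observed F1 in the extreme upper tail
  expect_gt(cv$f1, quantile(null_f1, 0.95))

  ns <- null_session()
  fn <- extract_features(ns)
  labn <- label_onset(downsample_joystick(ns$joystick, ns$fs), ns$trials,
                      ns$max_radial_extension, ns$fs)
  seln <- which(fn$labels$channel %in% 1:3 & fn$labels$band %in%
                  c("gamma", "lmp"))
  cvn <- evaluate_onset_cv(fn, labn, selected = seln, n_folds = 4,
                           seed = 11)
  null_n <- perm_null_f1(cvn$detections, threshold = 0.3, n_perm = 200,
                         seed = 12)
  # no task information: observed F1 inside the null distribution
  p_emp <- (1 + sum(null_n >= cvn$f1)) / (length(null_n) + 1)
  expect_gt(p_emp, 0.05)
})

test_that("confidence map localizes onset information to motor gamma/LMP", {
  f <- small_features()
  lab <- small_labels()
  motor_gamma <- which(f$labels$channel %in% 1:3 &
                         f$labels$band == "gamma")
  noise <- feature_series_col(f, 6, "mu")  # non-motor channel
  cm <- feature_confidence_map(f, lab,
                               feature_subset = c(motor_gamma, noise),
                               n_reps = 20, n_folds = 4, seed = 5)
  conf_motor <- max(cm$confidence[seq_along(motor_gamma)])
  conf_noise <- cm$confidence[length(motor_gamma) + 1]
  expect_gt(conf_motor, 3)  # p < 0.05 corresponds to -log(p) > 3
  expect_gt(conf_motor, conf_noise)
  # a duplicated feature column gets an identical confidence index
  best <- motor_gamma[which.max(cm$confidence[seq_along(motor_gamma)])]
  f2 <- f
  f2$values <- cbind(f$values, f$values[, best])
  f2$labels <- rbind(f$labels, data.frame(channel = 99, band = "gamma"))
  cm2 <- feature_confidence_map(f2, lab,
                                feature_subset = c(best, ncol(f2$values)),
                                n_reps = 5, n_folds = 4, seed = 5)
  expect_equal(cm2$confidence[1], cm2$confidence[2])
})
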