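#' @keywords internal
#' @importFrom e1071 svm
#' @importFrom glmnet glmnet
#' @importFrom signal fir1 fftfilt
#' @importFrom data.table fread fwrite
#' @importFrom jsonlite read_json write_json
#' @importFrom stats predict
"_PACKAGE"

# Sliding-window grid shared by spectral feature extraction and joystick
# downsampling: 300 ms windows advanced in 100 ms steps (200 ms overlap).
# Windows are left-aligned and half-open [t, t + 300 ms); the timestamp of a
# step is the END of its window, so every feature is causal (computable online
# from past samples only). At 1200 Hz a window spans 360 samples and the step
# advance is 120 samples; a 1440-sample (1.2 s) recording yields 10 steps.

WINDOW_S <- 0.3
STEP_S <- 0.1

win_len <- function(fs) {
  n <- fs * WINDOW_S
  stopifnot(abs(n - round(n)) < 1e-9)
  as.integer(round(n))
}

step_len <- function(fs) {
  n <- fs * STEP_S
  stopifnot(abs(n - round(n)) < 1e-9)
  as.integer(round(n))
}

#' Number of full analysis windows in a recording
#'
#' @param n_samples recording length in samples.
#' @param fs sampling rate in Hz.
#' @return integer count of complete 300 ms windows on the 100 ms step grid.
#' @keywords internal
n_steps_for <- function(n_samples, fs) {
  w <- win_len(fs)
  s <- step_len(fs)
  if (n_samples < w) return(0L)
  as.integer((n_samples - w) %/% s + 1L)
}

# sample indices covered by step i (1-based)
window_indices <- function(i, fs) {
  s <- step_len(fs)
  w <- win_len(fs)
  ((i - 1L) * s + 1L):((i - 1L) * s + w)
}

# window-end timestamps (seconds) for steps 1..n
step_end_times <- function(n, fs) {
  WINDOW_S + (seq_len(n) - 1) * STEP_S
}

# step whose window ends at time t (t must sit on the 100 ms grid and be
# >= 300 ms); used to align event times with the feature grid
step_at_time <- function(t) {
  i <- (t - WINDOW_S) / STEP_S + 1
  ir <- round(i)
  stopifnot(all(abs(i - ir) < 1e-6), all(ir >= 1))
  as.integer(ir)
}

# first step whose window starts at or after time t
first_step_after <- function(t) {
  as.integer(ceiling(t / STEP_S - 1e-9)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
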