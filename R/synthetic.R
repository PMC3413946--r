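#' Simulation configuration for a synthetic center-out ECoG session
#'
#' Defines the conditions of a simulated 8-target center-out joystick session:
#' channel count, trial count, movement-locked spectral effects on "motor"
#' channels (high-gamma increase, mu/beta decrease, LMP shift), and
#' direction-specific linear-Gaussian coupling among the latent band features
#' in the 1 s planning window before movement onset. The seed fully
#' determines the generated session.
#'
#' @param n_channels number of ECoG channels (>= 2).
#' @param n_trials number of trials.
#' @param sampling_rate sampling rate in Hz (default 1200; must exceed 400 so
#'   0--200 Hz spectra are defined).
#' @param n_directions number of equally spaced targets (default 8, 45 deg
#'   apart).
#' @param target_radius radius R of the target circle in screen units; also
#'   the joystick's maximum radial extension.
#' @param onset_latency_mean,onset_latency_sd mean/sd (s) of the movement
#'   latency after cursor presentation, drawn from a normal truncated at
#'   0.2 s.
#' @param gamma_gain multiplicative high-gamma amplitude increase on motor
#'   channels during movement (1 = amplitude doubles).
#' @param mu_beta_suppression fractional mu/beta amplitude decrease on motor
#'   channels during movement (0.5 = halved).
#' @param lmp_shift additive LMP shift (signal units) on motor channels
#'   during movement.
#' @param direction_coupling_strength scale of the direction-specific
#'   coupling coefficients in the pre-onset window; 0 = no directional
#'   information.
#' @param feature_mod_sd fractional amplitude modulation per unit latent
#'   feature (links the latent linear-Gaussian process to the band
#'   envelopes).
#' @param noise_sd standard deviation of the broadband background noise.
#' @param seed integer RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 8, n_trials = 40, sampling_rate = 1200,
                       n_directions = 8, target_radius = 1,
                       onset_latency_mean = 0.7, onset_latency_sd = 0.25,
                       gamma_gain = 1.0, mu_beta_suppression = 0.5,
                       lmp_shift = 2.0, direction_coupling_strength = 1.0,
                       feature_mod_sd = 0.4, noise_sd = 1.0, seed = 1) {
  cfg <- list(n_channels = n_channels, n_trials = n_trials,
              sampling_rate = sampling_rate, n_directions = n_directions,
              target_radius = target_radius,
              onset_latency_mean = onset_latency_mean,
              onset_latency_sd = onset_latency_sd,
              gamma_gain = gamma_gain,
              mu_beta_suppression = mu_beta_suppression,
              lmp_shift = lmp_shift,
              direction_coupling_strength = direction_coupling_strength,
              feature_mod_sd = feature_mod_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (n_channels < 2 || n_trials < 1 || n_directions < 2) {
    stop("configuration error: counts must be positive (>= 2 channels)")
  }
  if (sampling_rate <= 400) {
    stop("configuration error: sampling_rate must exceed 2 x 200 Hz")
  }
  if (noise_sd < 0 || target_radius <= 0) {
    stop("configuration error: noise_sd must be >= 0 and target_radius > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

# indices of the designated "motor" channels (movement-modulated); grids in
# this task sit over sensorimotor cortex, so about half the contacts carry
# movement information
motor_channels_for <- function(n_channels) {
  seq_len(max(2L, ceiling(n_channels / 2)))
}

# feature index of (channel, band); bands ordered mu, beta, gamma, lmp
feature_index <- function(channel, band) {
  (channel - 1L) * 4L + match(band, c("mu", "beta", "gamma", "lmp"))
}

# Draw one direction-specific coefficient set: a temporal matrix A (row m =
# coefficients on all features at t-1) and a spatial matrix S (row m =
# coefficients on other features at t) that is acyclic by construction
# (strictly lower-triangular in a random node order). Coupling is confined
# to the features of the motor channels.
draw_direction_coefs <- function(M, active, coupling) {
  A <- matrix(0, M, M)
  S <- matrix(0, M, M)
  order <- sample(active)
  rank <- integer(M)
  rank[order] <- seq_along(order)
  for (m in active) {
    tp <- sample(active, 1)
    A[m, tp] <- 0.8 * sample(c(-1, 1), 1)
    earlier <- active[rank[active] < rank[m]]
    if (length(earlier) && stats::runif(1) < 0.5) {
      sp <- if (length(earlier) == 1) earlier else sample(earlier, 1)
      S[m, sp] <- 0.5 * sample(c(-1, 1), 1)
    }
  }
  # stabilize: the effective one-step transition (I - S)^-1 A is rescaled to
  # operator 2-norm 0.95, bounding the amplification per step (the spectral
  # radius alone is useless here: sparse sign patterns are often nilpotent)
  G <- solve(diag(M) - S, A)
  s2n <- norm(G, "2")
  if (s2n > 0) A <- A * (0.95 / s2n)
  list(A = coupling * A, S = coupling * S, order = order)
}

# truncated-normal latency (lower truncation at 0.2 s) by rejection
draw_latency <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= 0.2) break
    }
    out[i] <- v
  }
  out
}

# 50 ms moving-average smoothing (softens piecewise-constant envelopes)
smooth_env <- function(x, fs) {
  k <- max(1L, as.integer(round(fs * 0.05)))
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = TRUE))
}

# unit-variance band-limited noise carrier; FIR design (stable at narrow
# low-frequency bands where IIR band-passes are not)
band_carrier <- function(n, band_hz, fs) {
  ord <- min(480L, 2L * (n %/% 6L))
  bf <- signal::fir1(ord, band_hz / (fs / 2), type = "pass")
  x <- signal::fftfilt(bf, stats::rnorm(n + ord))[(ord + 1):(n + ord)]
  x / stats::sd(x)
}

#' Generate a synthetic center-out ECoG session
#'
#' Builds a full session with known ground truth: a joystick trace whose
#' radial extension crosses 1/8 of its maximum at each trial's latent onset
#' and then extends fully toward the trial's target; latent band features
#' that follow a direction-specific linear-Gaussian transition/coupling model
#' over the 10 steps (1 s) before onset; and a raw multichannel signal in
#' which those band features are realized as amplitude-modulated band-passed
#' noise carriers on top of broadband background noise. Motor channels
#' additionally show a movement-locked high-gamma increase, mu/beta decrease
#' and LMP shift.
#'
#' @param config a [sim_config()].
#' @return an object of class `ecog_session` with elements `signal`
#'   (channels x samples), `joystick` (2 x samples), `fs`, `trials`
#'   (data.frame with `trial`, `target_index`, `target_time`, `cursor_time`,
#'   `onset_time`, `hit_time`), `max_radial_extension`, `n_directions`,
#'   `truth` (latent ground-truth metadata) and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_session_impl(config))
}

generate_session_impl <- function(cfg) {
  fs <- cfg$sampling_rate
  nch <- cfg$n_channels
  nd <- cfg$n_directions
  R <- cfg$target_radius
  M <- 4L * nch
  motor <- motor_channels_for(nch)
  # direction-specific coupling lives on the high-SNR planning features:
  # high-gamma and LMP of the motor channels
  active <- sort(as.vector(vapply(motor, function(ch)
    feature_index(ch, c("gamma", "lmp")), integer(2))))

  coefs <- lapply(seq_len(nd), function(d)
    draw_direction_coefs(M, active, cfg$direction_coupling_strength))

  # balanced, shuffled direction sequence (0-based target indices)
  directions <- sample(rep_len(0:(nd - 1), cfg$n_trials))

  snap <- function(t) round(t * 10) / 10
  ramp_s <- 0.4; hold_s <- 0.2; ret_s <- 0.3; iti_s <- 1.0
  t_target <- numeric(cfg$n_trials); t_cursor <- numeric(cfg$n_trials)
  t_move <- numeric(cfg$n_trials); t_hit <- numeric(cfg$n_trials)
  t <- 1.2  # lead-in so the first pre-onset window fits on the step grid
  lat <- draw_latency(cfg$n_trials, cfg$onset_latency_mean,
                      cfg$onset_latency_sd)
  for (i in seq_len(cfg$n_trials)) {
    t_target[i] <- snap(t)
    t_cursor[i] <- snap(t_target[i] + 1.0)
    t_move[i] <- max(snap(t_cursor[i] + lat[i]), t_cursor[i] + 0.2)
    t_hit[i] <- snap(t_move[i] + ramp_s)
    t <- t_hit[i] + hold_s + ret_s + iti_s
  }
  duration <- t_hit[cfg$n_trials] + 1.5
  n_samples <- as.integer(round(duration * fs))
  ts <- (seq_len(n_samples) - 1) / fs

  # joystick: rest -> linear ramp to full extension toward the target ->
  # hold -> return to rest
  angle <- 2 * pi * directions / nd
  jx <- numeric(n_samples); jy <- numeric(n_samples)
  radial <- numeric(n_samples)
  for (i in seq_len(cfg$n_trials)) {
    seg <- stats::approx(
      x = c(t_move[i], t_hit[i], t_hit[i] + hold_s,
            t_hit[i] + hold_s + ret_s),
      y = c(0, R, R, 0), xout = ts, yleft = NA, yright = NA)$y
    idx <- which(!is.na(seg))
    radial[idx] <- seg[idx]
    jx[idx] <- seg[idx] * cos(angle[i])
    jy[idx] <- seg[idx] * sin(angle[i])
  }

  # labeled onset = first step whose moving-averaged radial extension
  # exceeds 1/8 of the maximum (the same rule label_onset() applies)
  rad10 <- downsample_joystick(rbind(jx, jy), fs = fs)
  n_steps <- length(rad10)
  stimes <- step_end_times(n_steps, fs)
  onset_step <- integer(cfg$n_trials)
  for (i in seq_len(cfg$n_trials)) {
    win <- which(stimes > t_cursor[i] & stimes <= t_hit[i] + ret_s)
    cross <- win[rad10[win] > R / 8]
    stopifnot(length(cross) > 0)
    onset_step[i] <- cross[1]
  }
  onset_time <- stimes[onset_step]

  # latent band features on the step grid: iid standard normal at rest,
  # direction-specific linear-Gaussian coupling in the 10 pre-onset steps
  Z <- matrix(stats::rnorm(n_steps * M), n_steps, M)
  window_steps <- lapply(onset_step, function(s) (s - 10L):(s - 1L))
  solvers <- lapply(coefs, function(k) solve(diag(M) - k$S))
  for (i in seq_len(cfg$n_trials)) {
    d <- directions[i] + 1L
    w <- window_steps[[i]]
    stopifnot(w[1] >= 1)
    Z[w[1], ] <- solvers[[d]] %*% stats::rnorm(M)
    for (k in 2:10) {
      Z[w[k], ] <- solvers[[d]] %*%
        (coefs[[d]]$A %*% Z[w[k - 1], ] + stats::rnorm(M))
    }
  }

  # movement envelope (per-sample): ramps up around movement start, decays
  # after the hit
  mov <- numeric(n_samples)
  for (i in seq_len(cfg$n_trials)) {
    seg <- stats::approx(
      x = c(t_move[i] - 0.1, t_move[i] + 0.1, t_hit[i], t_hit[i] + 0.3),
      y = c(0, 1, 1, 0), xout = ts, yleft = NA, yright = NA)$y
    idx <- which(!is.na(seg))
    mov[idx] <- pmax(mov[idx], seg[idx])
  }

  # map step-grid latent values onto samples: the value of step k occupies
  # the 100 ms segment two segments after k, so that the (300 ms, trailing)
  # analysis window of step i averages latent steps i-2..i — causal
  seg_len <- step_len(fs)
  seg_of_sample <- pmin(pmax((seq_len(n_samples) - 1L) %/% seg_len - 1L, 1L),
                        n_steps)
  z_at <- function(f) Z[seg_of_sample, f]

  base_amp <- c(mu = 6, beta = 4, gamma = 2)
  sig <- matrix(0, nch, n_samples)
  a <- cfg$feature_mod_sd
  for (ch in seq_len(nch)) {
    is_motor <- ch %in% motor
    x <- numeric(n_samples)
    for (b in c("mu", "beta", "gamma")) {
      env <- base_amp[[b]] * pmax(1 + a * z_at(feature_index(ch, b)), 0.05)
      if (is_motor) {
        env <- env * if (b == "gamma") 1 + cfg$gamma_gain * mov else
          pmax(1 - cfg$mu_beta_suppression * mov, 0.05)
      }
      x <- x + smooth_env(env, fs) * band_carrier(n_samples, BAND_BINS[[b]][
        c(1, length(BAND_BINS[[b]]))], fs)
    }
    lmp_env <- 3 * a * z_at(feature_index(ch, "lmp"))
    if (is_motor) lmp_env <- lmp_env + cfg$lmp_shift * mov
    pink <- as.numeric(stats::filter(stats::rnorm(n_samples), 0.9,
                                     method = "recursive"))
    pink <- pink / stats::sd(pink)
    sig[ch, ] <- x + smooth_env(lmp_env, fs) + cfg$noise_sd * pink
  }

  trials <- data.frame(trial = seq_len(cfg$n_trials),
                       target_index = directions,
                       target_time = t_target, cursor_time = t_cursor,
                       onset_time = onset_time, hit_time = t_hit)
  structure(list(
    signal = sig, joystick = rbind(x = jx, y = jy), fs = fs,
    trials = trials, max_radial_extension = R, n_directions = nd,
    truth = list(directions = directions, onset_step = onset_step,
                 onset_time = onset_time, move_time = t_move,
                 latent = Z, window_steps = window_steps,
                 motor_channels = motor, active_features = active,
                 coefs = coefs, feature_mod_sd = a),
    config = cfg), class = "ecog_session")
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf(paste0("<ecog_session> %d channels x %d samples @ %g Hz, ",
                     "%d trials, %d directions\n"),
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$trials),
              x$n_directions))
  invisible(x)
}

#' Ground-truth labels of a generated session
#'
#' @param session an `ecog_session` produced by [generate_session()].
#' @return data.frame with one row per trial: `trial`, `onset_time` (s),
#'   `onset_step` (index on the 100 ms feature grid) and `direction`
#'   (0-based target index).
#' @export
latent_truth <- function(session) {
  if (is.null(session$truth)) {
    stop("session carries no ground-truth metadata")
  }
  data.frame(trial = seq_along(session$truth$directions),
             onset_time = session$truth$onset_time,
             onset_step = session$truth$onset_step,
             direction = session$truth$directions)
}

#' Simulate feature windows directly from a known coupling model
#'
#' Draws T x M feature windows from the linear-Gaussian
#' transition/coupling model itself (unit-variance Gaussian innovations):
#' slice 1 has spatial coupling only, slices 2..T have both temporal and
#' spatial coupling. Used for well-posed parameter-recovery checks.
#'
#' @param coefs list with temporal matrix `A` (M x M; row m = coefficients of
#'   node m on all nodes at t-1) and spatial matrix `S` (M x M, acyclic).
#' @param n_windows number of windows to draw.
#' @param T_steps window length in steps.
#' @param seed integer seed.
#' @return numeric array n_windows x T_steps x M.
#' @export
simulate_mtvdbn_windows <- function(coefs, n_windows, T_steps = 10,
                                    seed = 1) {
  M <- nrow(coefs$A)
  inv <- solve(diag(M) - coefs$S)
  with_seed(seed, {
    out <- array(0, dim = c(n_windows, T_steps, M))
    for (n in seq_len(n_windows)) {
      out[n, 1, ] <- inv %*% stats::rnorm(M)
      for (t in 2:T_steps) {
        out[n, t, ] <- inv %*% (coefs$A %*% out[n, t - 1, ] +
                                  stats::rnorm(M))
      }
    }
    out
  })
}
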