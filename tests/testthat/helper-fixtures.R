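# Shared fixtures, built once per test run and memoized. Sessions are small
# on purpose: enough trials per direction to fit every stage, short enough
# that the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

small_session <- function() {
  memo("small_session", function()
    generate_session(sim_config(n_channels = 6, n_trials = 24, seed = 101)))
}

small_features <- function() {
  memo("small_features", function() extract_features(small_session()))
}

small_labels <- function() {
  memo("small_labels", function() {
    s <- small_session()
    label_onset(downsample_joystick(s$joystick, s$fs), s$trials,
                s$max_radial_extension, s$fs)
  })
}

null_session <- function() {
  memo("null_session", function()
    generate_session(sim_config(
      n_channels = 6, n_trials = 24, gamma_gain = 0,
      mu_beta_suppression = 0, lmp_shift = 0,
      direction_coupling_strength = 0, seed = 202)))
}

# Independent coordinate-descent oracle for the l1 objective
#   (1/N) * sum (y - X a)^2 + lambda * ||a||_1
# written from the subgradient equations, sharing no code with the package
# solver (which goes through glmnet).
oracle_lasso <- function(X, y, lambda, iters = 5000, tol = 1e-13) {
  p <- ncol(X); n <- nrow(X)
  a <- rep(0, p)
  for (it in seq_len(iters)) {
    a_old <- a
    for (j in seq_len(p)) {
      r <- y - X[, -j, drop = FALSE] %*% a[-j]
      rho <- sum(X[, j] * r) / n
      zj <- sum(X[, j]^2) / n
      if (zj == 0) { a[j] <- 0; next }
      a[j] <- sign(rho) * max(abs(rho) - lambda / 2, 0) / zj
    }
    if (max(abs(a - a_old)) < tol) break
  }
  a
}

oracle_objective <- function(X, y, a, lambda) {
  mean((y - X %*% a)^2) + lambda * sum(abs(a))
}

# brute-force score of a window under an mtvdbn model, written directly from
# the double-sum definition without reusing package internals
oracle_score <- function(model, window) {
  if (!is.null(model$scaler)) {
    window <- (window - model$scaler$center) / model$scaler$scale
  }
  total <- 0
  for (t in seq_len(model$T)) for (m in seq_len(model$M)) {
    nd <- model$slices[[t]][[m]]
    fit <- 0
    if (t > 1) for (k in seq_along(nd$tpar)) {
      fit <- fit + nd$tcoef[k] * window[t - 1, nd$tpar[k]]
    }
    for (k in seq_along(nd$spar)) {
      fit <- fit + nd$scoef[k] * window[t, nd$spar[k]]
    }
    total <- total + (window[t, m] - fit)^2
  }
  total
}

# exhaustive search over all admissible spatial DAGs on small instances:
# every subset of candidate edges is tested for acyclicity and scored with
# the same penalized node objective the hill climber minimizes
oracle_best_dag <- function(y_mat, x_temporal, temporal_support,
                            spatial_candidates, lambda) {
  M <- ncol(y_mat)
  edges <- do.call(rbind, lapply(seq_len(M), function(m) {
    js <- spatial_candidates[[m]]
    if (length(js)) cbind(child = m, parent = js) else NULL
  }))
  n_e <- NROW(edges)
  acyclic <- function(par) {
    col <- integer(M)  # 0 unvisited, 1 in stack, 2 done
    ok <- TRUE
    visit <- function(v) {
      if (col[v] == 1L) { ok <<- FALSE; return() }
      if (col[v] == 2L) return()
      col[v] <<- 1L
      for (u in par[[v]]) visit(u)
      col[v] <<- 2L
    }
    for (v in seq_len(M)) { visit(v); if (!ok) return(FALSE) }
    TRUE
  }
  node_obj <- function(m, spar) {
    Xt <- if (is.null(x_temporal)) NULL else
      x_temporal[, temporal_support[[m]], drop = FALSE]
    X <- cbind(Xt, y_mat[, spar, drop = FALSE])
    if (ncol(X) == 0) return(mean(y_mat[, m]^2))
    a <- oracle_lasso(X, y_mat[, m], lambda)
    oracle_objective(X, y_mat[, m], a, lambda)
  }
  best <- Inf; best_par <- rep(list(integer(0)), M)
  for (mask in 0:(2^n_e - 1)) {
    par <- rep(list(integer(0)), M)
    if (n_e > 0) for (e in seq_len(n_e)) {
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L))) {
        par[[edges[e, "child"]]] <- c(par[[edges[e, "child"]]],
                                      edges[e, "parent"])
      }
    }
    if (!acyclic(par)) next
    obj <- sum(vapply(seq_len(M), function(m) node_obj(m, par[[m]]),
                      numeric(1)))
    if (obj < best - 1e-12) { best <- obj; best_par <- par }
  }
  list(objective = best, spatial_parents = lapply(best_par, sort))
}

is_dag <- function(parents) {
  M <- length(parents)
  indeg_order_ok <- tryCatch({
    remaining <- seq_len(M)
    par <- parents
    repeat {
      leaves <- remaining[vapply(remaining, function(v)
        length(intersect(par[[v]], remaining)) == 0, logical(1))]
      if (length(leaves) == 0) break
      remaining <- setdiff(remaining, leaves)
    }
    length(remaining) == 0
  }, error = function(e) FALSE)
  indeg_order_ok
}

feature_series_col <- function(f, channel, band) {
  which(f$labels$channel == channel & f$labels$band == band)
}

# permutation null for the onset detector's F1: keep the detector's
# predictions fixed and re-draw which labeled step in each trial is the
# onset, uniformly at random
perm_null_f1 <- function(detections, threshold, n_perm = 200, seed = 1) {
  set.seed(seed)
  pred <- detections$p > threshold
  idx_by_trial <- split(seq_len(nrow(detections)), detections$trial)
  vapply(seq_len(n_perm), function(b) {
    truth <- logical(nrow(detections))
    for (ix in idx_by_trial) truth[ix[sample.int(length(ix), 1)]] <- TRUE
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}
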