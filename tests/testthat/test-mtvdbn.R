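test_that("l1 screening matches its closed forms at the extremes", {
  set.seed(12)
  n <- 40
  xp <- rnorm(n)
  y <- 2 * xp  # exact relation, no noise
  fit <- learn_node_coefficients(y, x_temporal = NULL,
                                 x_spatial = cbind(xp), lambda = 0)
  expect_equal(unname(fit$spatial), 2, tolerance = 1e-10)
  # full shrinkage: lambda >= 2 * max |(1/N) sum x_j y| kills everything
  X <- matrix(rnorm(n * 5), n, 5)
  y2 <- rnorm(n)
  lam_kill <- 2 * max(abs(crossprod(X, y2)) / n) * 1.001
  fit2 <- learn_node_coefficients(y2, X[, 1:2], X[, 3:5], lam_kill)
  expect_true(all(fit2$temporal == 0) && all(fit2$spatial == 0))
  expect_error(learn_node_coefficients(y2, X[, 1:2], X[, 3:5], -1),
               "lambda")
})

test_that("l1 solver agrees with the coordinate-descent oracle", {
  set.seed(77)
  worst <- 0
  for (rep in 1:50) {
    n <- sample(10:30, 1)
    p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta_true <- rnorm(p) * rbinom(p, 1, 0.5)
    y <- as.vector(X %*% beta_true) + rnorm(n, sd = 0.5)
    lambda <- runif(1, 0.01, 1)
    nt <- sample(0:(p - 1), 1)
    fit <- learn_node_coefficients(
      y, if (nt) X[, seq_len(nt), drop = FALSE] else NULL,
      X[, (nt + 1):p, drop = FALSE], lambda)
    a_pkg <- c(fit$temporal, fit$spatial)
    a_orc <- oracle_lasso(X, y, lambda)
    gap <- oracle_objective(X, y, a_pkg, lambda) -
      oracle_objective(X, y, a_orc, lambda)
    worst <- max(worst, abs(gap))
  }
  expect_lt(worst, 1e-6)
})

test_that("orthonormal design solution is soft-thresholded least squares", {
  set.seed(5)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 4), n, 4))) * sqrt(n)  # X'X/n = I
  y <- rnorm(n)
  lambda <- 0.3
  fit <- learn_node_coefficients(y, NULL, X, lambda)
  ols <- as.vector(crossprod(X, y) / n)
  expect_equal(unname(fit$spatial),
               sign(ols) * pmax(abs(ols) - lambda / 2, 0),
               tolerance = 1e-6)
})

test_that("shrinkage is monotone: support never grows with lambda", {
  set.seed(41)
  n <- 30; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(n, sd = 0.3)
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 1, 2), function(l) {
    f <- learn_node_coefficients(y, NULL, X, l)
    sum(f$spatial != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("hill climbing resolves mutual candidates to a single edge", {
  set.seed(6)
  n <- 60
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + rnorm(n, sd = 0.2)
  Y <- cbind(x1, x2)
  res <- build_acyclic_structure(
    Y, x_temporal = NULL,
    temporal_support = list(integer(0), integer(0)),
    spatial_candidates = list(2L, 1L), lambda = 0.05)
  pars <- res$spatial_parents
  n_edges <- length(pars[[1]]) + length(pars[[2]])
  expect_equal(n_edges, 1)
  expect_true(is_dag(pars))
})

test_that("a candidate chain is retained in full", {
  set.seed(8)
  n <- 80
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, sd = 0.3)
  x3 <- 0.8 * x2 + rnorm(n, sd = 0.3)
  Y <- cbind(x1, x2, x3)
  res <- build_acyclic_structure(
    Y, NULL, rep(list(integer(0)), 3),
    spatial_candidates = list(integer(0), 1L, 2L), lambda = 0.02)
  expect_equal(res$spatial_parents, list(integer(0), 1L, 2L))
  # empty candidate sets give the empty graph
  res0 <- build_acyclic_structure(Y, NULL, rep(list(integer(0)), 3),
                                  rep(list(integer(0)), 3), lambda = 0.02)
  expect_true(all(lengths(res0$spatial_parents) == 0))
})

test_that("hill climbing matches exhaustive DAG search on small instances", {
  set.seed(90)
  for (rep in 1:8) {
    M <- sample(3:4, 1)
    n <- 40
    Y <- matrix(rnorm(n * M), n, M)
    # random true spatial structure to give candidates something to find
    for (m in 2:M) {
      if (runif(1) < 0.7) Y[, m] <- Y[, m] + 0.9 * Y[, m - 1]
    }
    Xt <- matrix(rnorm(n * M), n, M)
    tsup <- lapply(seq_len(M), function(m)
      if (runif(1) < 0.5) sample(M, 1) else integer(0))
    scand <- lapply(seq_len(M), function(m)
      sample(setdiff(seq_len(M), m), sample(0:2, 1)))
    lambda <- 0.1
    hc <- build_acyclic_structure(Y, Xt, tsup, scand, lambda)
    ex <- oracle_best_dag(Y, Xt, tsup, scand, lambda)
    expect_true(is_dag(hc$spatial_parents))
    # greedy construction reaches the exhaustive optimum on these sizes
    expect_equal(hc$objective, ex$objective, tolerance = 1e-5)
  }
})

test_that("score_sequence equals the brute-force double sum", {
  set.seed(14)
  M <- 6
  A <- matrix(0, M, M); A[2, 1] <- 0.7; A[5, 3] <- -0.5
  S <- matrix(0, M, M); S[4, 2] <- 0.6
  w <- simulate_mtvdbn_windows(list(A = A, S = S), 30, seed = 2)
  fit <- fit_direction_model(w, lambda = 0.1)
  for (i in c(1, 7, 23)) {
    expect_equal(score_sequence(fit, w[i, , ]), oracle_score(fit, w[i, , ]))
  }
  expect_error(score_sequence(fit, w[1, 1:5, ]), "window must be")
})

test_that("noiseless self-generated windows score zero; empty model scores energy", {
  # a hand-built model with no parents anywhere: score = sum of squares
  M <- 3; T_steps <- 4
  empty_nodes <- lapply(seq_len(M), function(m)
    list(tpar = integer(0), tcoef = numeric(0),
         spar = integer(0), scoef = numeric(0)))
  model <- structure(list(T = T_steps, M = M, lambda = 0.1,
                          slices = rep(list(empty_nodes), T_steps),
                          scaler = NULL, direction = 0L, n_trials = 2L),
                     class = "mtvdbn_model")
  set.seed(3)
  w <- matrix(rnorm(T_steps * M), T_steps, M)
  expect_equal(score_sequence(model, w), sum(w^2))
  # deterministic chain x2 = 2 x1 within each slice scores exactly zero
  chain_nodes <- empty_nodes
  chain_nodes[[2]] <- list(tpar = integer(0), tcoef = numeric(0),
                           spar = 1L, scoef = 2)
  model2 <- structure(list(T = T_steps, M = M, lambda = 0,
                           slices = rep(list(chain_nodes), T_steps),
                           scaler = NULL, direction = 0L, n_trials = 2L),
                      class = "mtvdbn_model")
  w2 <- w; w2[, 2] <- 2 * w2[, 1]; w2[, 3] <- 0
  w2[, 1] <- 0  # only node 2 residual is structural; zero the rest
  w2[, 2] <- 2 * w2[, 1]
  expect_equal(score_sequence(model2, w2), 0)
})

test_that("constant feature columns yield empty parent sets", {
  set.seed(19)
  w <- simulate_mtvdbn_windows(list(A = matrix(0, 3, 3),
                                    S = matrix(0, 3, 3)), 20, seed = 6)
  w[, , 2] <- 5  # constant node
  fit <- fit_direction_model(w, lambda = 0.1)
  for (t in 1:10) {
    expect_length(fit$slices[[t]][[2]]$tpar, 0)
    expect_length(fit$slices[[t]][[2]]$spar, 0)
  }
})

test_that("every fitted spatial slice is acyclic", {
  set.seed(23)
  M <- 8
  A <- matrix(rnorm(M * M) * rbinom(M * M, 1, 0.15) * 0.4, M, M)
  S <- matrix(0, M, M)
  S[lower.tri(S)] <- rnorm(sum(lower.tri(S))) * rbinom(M * (M - 1) / 2,
                                                       1, 0.3) * 0.4
  w <- simulate_mtvdbn_windows(list(A = A, S = S), 40, seed = 7)
  fit <- fit_direction_model(w, lambda = 0.05)
  for (t in seq_len(fit$T)) {
    expect_true(is_dag(lapply(fit$slices[[t]], `[[`, "spar")))
  }
})

test_that("support of a known sparse model is recovered as N grows", {
  set.seed(71)
  M <- 8
  A <- matrix(0, M, M); S <- matrix(0, M, M)
  A[1, 2] <- 0.7; A[3, 1] <- -0.7; A[5, 5] <- 0.7; A[7, 4] <- 0.7
  S[2, 1] <- 0.6; S[6, 3] <- -0.6
  # lambda sized so its soft threshold (lambda / 2) sits well above the
  # sampling noise of a null coefficient (~1/sqrt(N)) and below the true
  # magnitudes
  jacc <- vapply(c(50, 200), function(N) {
    w <- simulate_mtvdbn_windows(list(A = A, S = S), N, seed = N)
    fit <- fit_direction_model(w, lambda = 0.45, scaler = FALSE)
    support_jaccard(fit, A, S)
  }, numeric(1))
  expect_gt(jacc[2], 0.8)
  expect_gte(jacc[2] + 0.05, jacc[1])  # consistency: not worse with more data
})

test_that("classification recovers the generating direction and ties break low", {
  set.seed(83)
  M <- 6
  mk <- function(seed) {
    A <- matrix(0, M, M); S <- matrix(0, M, M)
    set.seed(seed)
    for (m in 1:M) A[m, sample(M, 1)] <- 0.7 * sample(c(-1, 1), 1)
    list(A = A, S = S)
  }
  coef_sets <- lapply(1:4, mk)
  train <- lapply(1:4, function(d)
    simulate_mtvdbn_windows(coef_sets[[d]], 40, seed = 100 + d))
  windows <- do.call(abind_windows, train)
  dirs <- rep(0:3, each = 40)
  fit <- fit_direction_models(windows, dirs, lambda = 0.15,
                              n_directions = 4)
  test <- lapply(1:4, function(d)
    simulate_mtvdbn_windows(coef_sets[[d]], 25, seed = 200 + d))
  pred <- unlist(lapply(1:4, function(d)
    vapply(seq_len(25), function(i)
      classify_direction(fit, test[[d]][i, , ]), integer(1))))
  acc <- mean(pred == rep(0:3, each = 25))
  expect_gt(acc, 0.5)  # well above the 25% chance level
  # all-zero window under identical empty models -> direction 0 by tie-break
  empty <- fit_direction_models(
    simulate_mtvdbn_windows(list(A = matrix(0, M, M),
                                 S = matrix(0, M, M)), 8, seed = 1),
    rep(0:3, each = 2), lambda = 100, n_directions = 4)
  expect_equal(classify_direction(empty, matrix(0, 10, M)), 0L)
  broken <- fit
  broken$models[[2]] <- NULL
  broken$models[[4]] <- NULL  # shrink then pad to simulate missing model
  broken$models <- c(broken$models, list(NULL, NULL))
  expect_error(classify_direction(broken, test[[1]][1, , ]), "untrained")
})

test_that("lambda selection behaves at the extremes", {
  set.seed(99)
  expect_equal(select_lambda(array(rnorm(80), c(4, 10, 2)),
                             c(0, 0, 1, 1), lambda_grid = 0.5,
                             n_directions = 2)$lambda, 0.5)
  M <- 4
  A <- matrix(0, M, M); A[1, 2] <- 0.8; A[2, 1] <- -0.8
  B <- matrix(0, M, M); B[3, 4] <- 0.8; B[4, 3] <- -0.8
  w <- abind_windows(simulate_mtvdbn_windows(list(A = A, S = 0 * A), 24,
                                             seed = 1),
                     simulate_mtvdbn_windows(list(A = B, S = 0 * B), 24,
                                             seed = 2))
  dirs <- rep(0:1, each = 24)
  sel <- select_lambda(w, dirs, lambda_grid = c(0.05, 0.3, 20),
                       n_directions = 2, n_folds = 3, seed = 4)
  # structured data: an informative lambda beats the empty-model extreme
  best_acc <- max(sel$accuracy[1:2])
  expect_gt(best_acc, sel$accuracy[3] - 1e-9)
  expect_lt(sel$lambda, 20)
})

test_that("model round-trips through JSON serialization", {
  set.seed(27)
  M <- 4
  A <- matrix(0, M, M); A[2, 1] <- 0.6
  w1 <- simulate_mtvdbn_windows(list(A = A, S = 0 * A), 10, seed = 1)
  w2 <- simulate_mtvdbn_windows(list(A = -A, S = 0 * A), 10, seed = 2)
  fit <- fit_direction_models(abind_windows(w1, w2), rep(0:1, each = 10),
                              lambda = 0.2, n_directions = 2)
  path <- tempfile(fileext = ".json")
  write_direction_models(fit, path)
  back <- read_direction_models(path)
  expect_equal(back$n_directions, 2)
  test_w <- w1[3, , ]
  expect_equal(score_sequence(back$models[[1]], test_w),
               score_sequence(fit$models[[1]], test_w))
  expect_equal(classify_direction(back, test_w),
               classify_direction(fit, test_w))
})
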