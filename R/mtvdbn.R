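# Per-direction modified time-varying dynamic Bayesian networks: each of the
# 8 directions gets its own linear-Gaussian network over the T = 10 feature
# steps preceding movement onset, with time-varying temporal parents (edges
# from slice t-1) and within-slice spatial parents (edges inside slice t,
# constrained to a DAG). Parents are screened per node by l1-penalized least
# squares, repaired to an acyclic within-slice graph by greedy hill climbing,
# and refit unpenalized on the final parent sets. Classification picks the
# direction whose network gives the smallest summed squared residual
# (largest Gaussian log-likelihood) for a test window.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# penalized objective: mean squared residual + lambda * ||beta||_1
l1_objective <- function(X, y, beta, lambda) {
  mean((y - as.vector(X %*% beta))^2) + lambda * sum(abs(beta))
}

ols_coef <- function(X, y) {
  b <- stats::lm.fit(X, y)$coefficients
  b[is.na(b)] <- 0
  unname(b)
}

# coordinate descent on the l1 objective; used for the small restricted
# refits inside hill climbing (design widths of a handful of columns)
lasso_cd <- function(X, y, lambda, max_iter = 200, tol = 1e-7) {
  p <- ncol(X)
  if (p == 0) return(numeric(0))
  N <- nrow(X)
  XtX <- crossprod(X) / N
  Xty <- as.vector(crossprod(X, y)) / N
  diagx <- diag(XtX)
  beta <- numeric(p)
  g <- lambda / 2
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (diagx[j] <= 0) next
      r <- Xty[j] - sum(XtX[, j] * beta) + diagx[j] * beta[j]
      az <- abs(r) - g
      bj <- if (az > 0) sign(r) * az / diagx[j] else 0
      d <- abs(bj - beta[j])
      if (d > delta) delta <- d
      beta[j] <- bj
    }
    if (delta < tol) break
  }
  beta
}

# l1 solve of the parent-selection objective (1/N)*RSS + lambda*||a||_1.
# glmnet (coordinate descent over a lambda path) does the work; its
# gaussian objective is (1/(2N))*RSS + lambda_g*||a||_1, so lambda_g =
# lambda / 2.
solve_l1 <- function(X, y, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  p <- ncol(X)
  N <- nrow(X)
  if (p == 0) return(numeric(0))
  if (lambda == 0) return(ols_coef(X, y))
  lam_glm <- lambda / 2
  lam_max <- max(abs(crossprod(X, y)) / N)
  if (lam_glm >= lam_max || lam_max == 0) return(rep(0, p))
  if (p == 1) {
    return(soft_threshold(sum(X * y) / N, lam_glm) / (sum(X * X) / N))
  }
  path <- exp(seq(log(lam_max), log(lam_glm), length.out = 30))
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        intercept = FALSE, standardize = FALSE,
                        lambda = path, thresh = 1e-12)
  as.numeric(fit$beta[, ncol(fit$beta)])
}

#' Sparse parent coefficients for one node at one time slice
#'
#' Solves the l1-penalized least-squares screening problem for node `m` at
#' slice `t`: minimize `(1/N) sum_n (X_m - a_temporal X_{t-1} -
#' a_spatial X_t)^2 + lambda (||a_temporal||_1 + ||a_spatial||_1)` over the
#' candidate temporal parents (all features at t-1) and spatial parents (all
#' other features at t). Zero coefficients encode absent edges.
#'
#' @param y numeric response vector (node m's values at slice t over the N
#'   training windows).
#' @param x_temporal N x M matrix of candidate temporal parents (slice t-1),
#'   or `NULL` for the boundary slice t = 1.
#' @param x_spatial N x (M-1) matrix of candidate spatial parents (slice t,
#'   node m excluded).
#' @param lambda penalty coefficient (>= 0) controlling sparsity.
#' @return list with numeric vectors `temporal` and `spatial` of
#'   coefficients aligned with the candidate columns.
#' @export
learn_node_coefficients <- function(y, x_temporal, x_spatial, lambda) {
  if (length(y) < 2) stop("need at least 2 training windows")
  nt <- if (is.null(x_temporal)) 0L else ncol(x_temporal)
  X <- cbind(x_temporal, x_spatial)
  beta <- solve_l1(X, y, lambda)
  list(temporal = if (nt) beta[seq_len(nt)] else numeric(0),
       spatial = beta[seq_len(ncol(x_spatial)) + nt])
}

# does adding edge from -> to close a directed cycle? (i.e. can `to`
# already reach `from`)
creates_cycle <- function(parents_of, from, to) {
  # edges point parent -> child; parents_of[[m]] lists m's parents
  stack <- from
  seen <- logical(length(parents_of))
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, parents_of[[v]])
  }
  FALSE
}

#' Greedy acyclic repair of the within-slice spatial structure
#'
#' The per-node l1 screening can propose spatial parent sets whose union
#' contains directed cycles. Starting from the empty spatial graph, this
#' hill-climbing pass repeatedly adds the single candidate edge giving the
#' largest decrease in the total penalized residual (each node's restricted
#' l1 refit with its temporal support fixed), rejecting edges that would
#' close a directed cycle, until no admissible edge improves the score. Ties
#' are broken toward the lower child index, then the lower parent index.
#'
#' @param y_mat N x M matrix of node values at the slice.
#' @param x_temporal N x M matrix of slice t-1 values, or `NULL` at t = 1.
#' @param temporal_support list (length M) of each node's temporal parent
#'   indices (fixed during the repair).
#' @param spatial_candidates list (length M) of each node's candidate
#'   spatial parent indices from the screening step.
#' @param lambda penalty coefficient used in the node objectives.
#' @return list with `spatial_parents` (list of parent index vectors, a DAG)
#'   and `objective` (total penalized residual after repair).
#' @export
build_acyclic_structure <- function(y_mat, x_temporal, temporal_support,
                                    spatial_candidates, lambda) {
  M <- ncol(y_mat)
  node_obj <- function(m, spar) {
    Xt <- if (is.null(x_temporal)) NULL else
      x_temporal[, temporal_support[[m]], drop = FALSE]
    X <- cbind(Xt, y_mat[, spar, drop = FALSE])
    if (ncol(X) == 0) return(mean(y_mat[, m]^2))
    beta <- lasso_cd(X, y_mat[, m], lambda)
    l1_objective(X, y_mat[, m], beta, lambda)
  }
  parents <- rep(list(integer(0)), M)
  obj <- vapply(seq_len(M), function(m) node_obj(m, integer(0)), numeric(1))
  # candidate edges ordered by (child, parent) for deterministic tie-breaks
  cand <- do.call(rbind, lapply(seq_len(M), function(m) {
    js <- sort(spatial_candidates[[m]])
    if (length(js)) cbind(child = m, parent = js) else NULL
  }))
  used <- logical(NROW(cand))
  # candidate objectives are cached: adding an edge only changes its child's
  # node objective, so other children's gains stay valid across iterations
  cand_obj <- rep(NA_real_, NROW(cand))
  repeat {
    best_gain <- 0; best_i <- 0
    for (i in seq_len(NROW(cand))) {
      if (used[i]) next
      m <- cand[i, "child"]; j <- cand[i, "parent"]
      if (creates_cycle(parents, j, m)) next
      if (is.na(cand_obj[i])) {
        cand_obj[i] <- node_obj(m, c(parents[[m]], j))
      }
      gain <- obj[m] - cand_obj[i]
      if (gain > best_gain + 1e-12) {
        best_gain <- gain; best_i <- i
      }
    }
    if (best_i == 0) break
    m <- unname(cand[best_i, "child"])
    j <- unname(cand[best_i, "parent"])
    parents[[m]] <- c(parents[[m]], j)
    obj[m] <- cand_obj[best_i]
    used[best_i] <- TRUE
    cand_obj[cand[, "child"] == m] <- NA_real_
  }
  list(spatial_parents = lapply(parents, sort), objective = sum(obj))
}

#' Fit one direction's time-varying network
#'
#' Fits the linear-Gaussian network of one movement direction from the 1 s
#' (T = 10 step) pre-onset feature windows of that direction's trials: per
#' node and slice, candidate parents are screened by
#' [learn_node_coefficients()], the within-slice spatial structure is
#' repaired to a DAG by [build_acyclic_structure()], and the coefficients
#' are refit unpenalized (ordinary least squares) on the final parent sets.
#' Slice 1 has no temporal parents (there is no slice 0 in the window).
#'
#' @param windows numeric array n_trials x T x M of feature windows (or a
#'   list of T x M matrices).
#' @param lambda penalty coefficient.
#' @param scaler optional list with `center` and `scale` (T x M matrices)
#'   used to standardize the windows; `NULL` computes one from these
#'   windows; `FALSE` disables standardization.
#' @param direction optional 0-based direction index stored in the model.
#' @return object of class `mtvdbn_model` with per-slice, per-node parent
#'   sets and coefficients.
#' @export
fit_direction_model <- function(windows, lambda, scaler = NULL,
                                direction = NA_integer_) {
  windows <- as_window_array(windows)
  n <- dim(windows)[1]; T_steps <- dim(windows)[2]; M <- dim(windows)[3]
  if (n < 2) stop("need at least 2 trials to fit a direction model")
  if (is.null(scaler)) scaler <- window_scaler(windows)
  if (!identical(scaler, FALSE)) windows <- scale_windows(windows, scaler)
  slices <- vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    Y <- windows[, t, , drop = TRUE]
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
    Xt <- if (t > 1) {
      xm <- windows[, t - 1, , drop = TRUE]
      if (is.null(dim(xm))) matrix(xm, nrow = n) else xm
    } else NULL
    tsup <- vector("list", M); scand <- vector("list", M)
    for (m in seq_len(M)) {
      fit <- learn_node_coefficients(
        Y[, m], Xt, Y[, -m, drop = FALSE], lambda)
      tsup[[m]] <- which(fit$temporal != 0)
      scand[[m]] <- setdiff(seq_len(M), m)[fit$spatial != 0]
    }
    dag <- build_acyclic_structure(Y, Xt, tsup, scand, lambda)
    nodes <- vector("list", M)
    for (m in seq_len(M)) {
      tp <- tsup[[m]]; sp <- dag$spatial_parents[[m]]
      X <- cbind(if (!is.null(Xt)) Xt[, tp, drop = FALSE],
                 Y[, sp, drop = FALSE])
      beta <- if (ncol(X)) ols_coef(X, Y[, m]) else numeric(0)
      nodes[[m]] <- list(tpar = tp,
                         tcoef = if (length(tp)) beta[seq_along(tp)] else
                           numeric(0),
                         spar = sp,
                         scoef = if (length(sp))
                           beta[length(tp) + seq_along(sp)] else numeric(0))
    }
    slices[[t]] <- nodes
  }
  structure(list(T = T_steps, M = M, lambda = lambda, slices = slices,
                 scaler = if (identical(scaler, FALSE)) NULL else scaler,
                 direction = direction, n_trials = n),
            class = "mtvdbn_model")
}

as_window_array <- function(windows) {
  if (is.list(windows)) {
    T_steps <- nrow(windows[[1]]); M <- ncol(windows[[1]])
    arr <- array(0, dim = c(length(windows), T_steps, M))
    for (i in seq_along(windows)) arr[i, , ] <- windows[[i]]
    arr
  } else {
    stopifnot(length(dim(windows)) == 3)
    windows
  }
}

# per (slice, node) mean/sd over windows
window_scaler <- function(windows) {
  list(center = apply(windows, c(2, 3), mean),
       scale = {
         s <- apply(windows, c(2, 3), stats::sd)
         s[s == 0] <- 1
         s
       })
}

scale_windows <- function(windows, scaler) {
  out <- windows
  for (i in seq_len(dim(windows)[1])) {
    out[i, , ] <- (windows[i, , ] - scaler$center) / scaler$scale
  }
  out
}

#' @export
print.mtvdbn_model <- function(x, ...) {
  n_edges <- sum(vapply(x$slices, function(sl)
    sum(vapply(sl, function(nd) length(nd$tpar) + length(nd$spar),
               numeric(1))), numeric(1)))
  cat(sprintf(paste0("<mtvdbn_model> direction %s: T = %d, M = %d, ",
                     "lambda = %g, %d edges (fit on %d trials)\n"),
              x$direction, x$T, x$M, x$lambda, n_edges, x$n_trials))
  invisible(x)
}

#' Negative log-likelihood score of a window under one direction model
#'
#' Computes `sum_t sum_m (X_m^t - a_temporal X_{parents}^{t-1} -
#' a_spatial X_{parents}^t)^2`, the summed squared residual of the window
#' under the model's linear-Gaussian networks (equal to the negative
#' log-likelihood up to an additive constant, since the noise has unit
#' variance after standardization). The window is standardized with the
#' model's training scaler. Slice 1 contributes no temporal term.
#'
#' @param model an `mtvdbn_model`.
#' @param window T x M numeric matrix.
#' @return scalar score (smaller = more likely under the model).
#' @export
score_sequence <- function(model, window) {
  window <- as.matrix(window)
  if (nrow(window) != model$T || ncol(window) != model$M) {
    stop(sprintf("window must be %d x %d; got %d x %d", model$T, model$M,
                 nrow(window), ncol(window)))
  }
  if (!is.null(model$scaler)) {
    window <- (window - model$scaler$center) / model$scaler$scale
  }
  total <- 0
  for (t in seq_len(model$T)) {
    for (m in seq_len(model$M)) {
      nd <- model$slices[[t]][[m]]
      pred <- 0
      if (t > 1 && length(nd$tpar)) {
        pred <- pred + sum(nd$tcoef * window[t - 1, nd$tpar])
      }
      if (length(nd$spar)) {
        pred <- pred + sum(nd$scoef * window[t, nd$spar])
      }
      total <- total + (window[t, m] - pred)^2
    }
  }
  total
}

#' Fit the full set of per-direction models
#'
#' One network per direction, trained only on that direction's trials. All
#' models share a single scaler computed jointly over every training window,
#' so the directions are distinguished by their coupling dynamics rather
#' than by per-direction feature means.
#'
#' @param windows array n x T x M (or list of T x M matrices) of pre-onset
#'   windows for all training trials.
#' @param directions 0-based direction label per window.
#' @param lambda penalty coefficient (scalar).
#' @param n_directions number of directions (default 8).
#' @return object of class `direction_model_set`.
#' @export
fit_direction_models <- function(windows, directions, lambda,
                                 n_directions = 8) {
  windows <- as_window_array(windows)
  stopifnot(dim(windows)[1] == length(directions))
  scaler <- window_scaler(windows)
  models <- vector("list", n_directions)
  for (d in 0:(n_directions - 1)) {
    idx <- which(directions == d)
    if (length(idx) < 2) {
      stop("direction ", d, " has fewer than 2 training trials")
    }
    models[[d + 1]] <- fit_direction_model(
      windows[idx, , , drop = FALSE], lambda, scaler = scaler,
      direction = d)
  }
  structure(list(models = models, lambda = lambda, scaler = scaler,
                 n_directions = n_directions),
            class = "direction_model_set")
}

#' @export
print.direction_model_set <- function(x, ...) {
  cat(sprintf("<direction_model_set> %d directions, lambda = %g\n",
              x$n_directions, x$lambda))
  invisible(x)
}

#' Classify the direction of a pre-onset window
#'
#' Scores the window under each direction's network and returns the
#' direction with the smallest negative log-likelihood (Eq. 5's argmin);
#' ties break toward the lowest direction index.
#'
#' @param models a `direction_model_set`.
#' @param window T x M numeric matrix.
#' @return 0-based predicted direction index.
#' @export
classify_direction <- function(models, window) {
  stopifnot(inherits(models, "direction_model_set"))
  if (any(vapply(models$models, is.null, logical(1)))) {
    stop("direction model set contains untrained models")
  }
  scores <- vapply(models$models, score_sequence, numeric(1),
                   window = window)
  which.min(scores) - 1L
}

#' Choose the penalty coefficient by cross-validation
#'
#' Trial-wise k-fold cross-validation of held-out classification accuracy
#' over a lambda grid. Among grid values whose mean accuracy is within one
#' standard error of the best, the largest (sparsest) lambda is returned.
#'
#' @param windows array n x T x M of training windows.
#' @param directions 0-based direction label per window.
#' @param lambda_grid candidate penalties (default logarithmic over
#'   `[1e-3, 10]`).
#' @param n_directions number of directions.
#' @param n_folds cross-validation folds.
#' @param seed seed for fold assignment.
#' @return list with `lambda` (the selection), `grid`, `accuracy` (mean per
#'   grid value) and `se`.
#' @export
select_lambda <- function(windows, directions,
                          lambda_grid = 10^seq(-3, 1, length.out = 9),
                          n_directions = 8, n_folds = 5, seed = 1) {
  stopifnot(length(lambda_grid) >= 1)
  windows <- as_window_array(windows)
  if (length(lambda_grid) == 1) {
    return(list(lambda = lambda_grid, grid = lambda_grid,
                accuracy = NA_real_, se = NA_real_))
  }
  n <- dim(windows)[1]
  folds <- assign_folds(seq_len(n), n_folds, seed)
  acc <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (min(table(directions[tr])) < 2 || !any(!tr)) next
    for (li in seq_along(lambda_grid)) {
      fit <- fit_direction_models(windows[tr, , , drop = FALSE],
                                  directions[tr], lambda_grid[li],
                                  n_directions)
      pred <- vapply(which(!tr), function(i)
        classify_direction(fit, windows[i, , ]), integer(1))
      acc[f, li] <- mean(pred == directions[!tr])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  se <- apply(acc, 2, function(a)
    stats::sd(a, na.rm = TRUE) / sqrt(sum(!is.na(a))))
  best <- which.max(mean_acc)
  ok <- which(mean_acc >= mean_acc[best] - se[best])
  list(lambda = max(lambda_grid[ok]), grid = lambda_grid,
       accuracy = mean_acc, se = se)
}

#' Absolute angular error between two target indices
#'
#' @param predicted,true 0-based target indices on a circle of equally
#'   spaced targets.
#' @param n_targets number of targets (default 8, i.e. 45 degree spacing).
#' @return absolute angular error in degrees, in `[0, 180]`.
#' @export
angular_error <- function(predicted, true, n_targets = 8) {
  step <- 360 / n_targets
  d <- abs(predicted - true) %% n_targets
  step * pmin(d, n_targets - d)
}

#' Extract the 1 s pre-onset feature windows
#'
#' @param features a [feature_series()].
#' @param onset_steps integer onset step per trial (e.g. from
#'   [label_onset()] or [latent_truth()]).
#' @param T_steps window length in steps (default 10 = 1 s).
#' @param selected optional feature column subset.
#' @return list with `windows` (array n x T x M over the usable trials) and
#'   `trial` (indices of the trials whose window fit inside the series).
#' @export
extract_preonset_windows <- function(features, onset_steps, T_steps = 10,
                                     selected = NULL) {
  vals <- features$values
  if (!is.null(selected)) vals <- vals[, selected, drop = FALSE]
  ok <- which(!is.na(onset_steps) & onset_steps - T_steps >= 1 &
                onset_steps <= nrow(vals) + 1)
  arr <- array(0, dim = c(length(ok), T_steps, ncol(vals)))
  for (i in seq_along(ok)) {
    s <- onset_steps[ok[i]]
    arr[i, , ] <- vals[(s - T_steps):(s - 1), , drop = FALSE]
  }
  list(windows = arr, trial = ok)
}

#' Jaccard overlap between fitted and true edge supports
#'
#' Compares the parent sets of a fitted model with the nonzero pattern of a
#' known generating coefficient pair, pooled over all slices. Temporal
#' edges are compared as directed edges (time orients them). Spatial
#' (within-slice) edges are compared as unordered pairs — the skeleton —
#' because the orientation of a contemporaneous linear-Gaussian dependency
#' with equal noise variances is only weakly identifiable, and greedy
#' acyclic construction may legitimately return either direction.
#'
#' @param model an `mtvdbn_model`.
#' @param A,S true M x M temporal and spatial coefficient matrices (row m =
#'   parents of node m).
#' @return Jaccard index in `[0, 1]` (1 when both supports are empty).
#' @export
support_jaccard <- function(model, A, S) {
  inter <- 0; uni <- 0
  pair_key <- function(m, js) {
    if (!length(js)) return(character(0))
    paste(pmin(m, js), pmax(m, js))
  }
  for (t in seq_len(model$T)) {
    true_pairs <- character(0); est_pairs <- character(0)
    for (m in seq_len(model$M)) {
      nd <- model$slices[[t]][[m]]
      true_t <- if (t > 1) which(A[m, ] != 0) else integer(0)
      inter <- inter + length(intersect(true_t, nd$tpar))
      uni <- uni + length(union(true_t, nd$tpar))
      true_pairs <- c(true_pairs, pair_key(m, which(S[m, ] != 0)))
      est_pairs <- c(est_pairs, pair_key(m, nd$spar))
    }
    true_pairs <- unique(true_pairs); est_pairs <- unique(est_pairs)
    inter <- inter + length(intersect(true_pairs, est_pairs))
    uni <- uni + length(union(true_pairs, est_pairs))
  }
  if (uni == 0) return(1)
  inter / uni
}

#' Concatenate window arrays along the trial dimension
#'
#' @param ... arrays n_i x T x M with matching T and M.
#' @return a single array with `sum(n_i)` windows.
#' @export
abind_windows <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0
  for (p in parts) {
    n <- dim(p)[1]
    out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}
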