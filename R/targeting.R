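# Brain-assisted targeting simulation: at each predicted movement onset the
# cursor is pre-positioned at a fraction alpha of the target radius toward
# the predicted direction, and the remaining movement is simulated as a
# straight line at the subject's average speed. The geometry of the target
# circle fixes the improvement region: a repositioned cursor is closer to
# the target than the center was whenever alpha < 2 cos(angular error), so
# an error under 60 degrees improves every choice of alpha in (0, 1].

#' Target layout of the center-out task
#'
#' @param n_targets number of equally spaced targets (default 8).
#' @param radius circle radius R in screen units.
#' @return object of class `target_layout` with `angles_deg` (target k at
#'   `k * 360 / n_targets` degrees, 0 = rightward, counterclockwise) and
#'   `radius`.
#' @export
target_layout <- function(n_targets = 8, radius = 1) {
  stopifnot(n_targets >= 2, radius > 0)
  structure(list(n_targets = n_targets,
                 angles_deg = (0:(n_targets - 1)) * 360 / n_targets,
                 radius = radius),
            class = "target_layout")
}

target_position <- function(index, layout) {
  th <- layout$angles_deg[index + 1] * pi / 180
  layout$radius * c(cos(th), sin(th))
}

#' Reposition the cursor toward a predicted direction
#'
#' Places the cursor at distance `alpha * R` from the center along the
#' predicted target's direction. `alpha = 0` leaves the cursor at the
#' center (the prediction has no effect); `alpha = 1` with a correct
#' prediction places it on the target.
#'
#' @param predicted 0-based predicted target index.
#' @param alpha repositioning fraction in `[0, 1]`.
#' @param layout a [target_layout()].
#' @return numeric 2-vector (x, y).
#' @export
reposition_cursor <- function(predicted, alpha, layout) {
  if (alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]; got ", alpha)
  }
  alpha * target_position(predicted, layout)
}

#' Straight-line movement time between two points
#'
#' @param start,target numeric 2-vectors.
#' @param speed cursor speed in screen units per second (> 0).
#' @return time in seconds (Euclidean distance / speed).
#' @export
movement_time <- function(start, target, speed) {
  if (speed <= 0) stop("speed must be positive")
  sqrt(sum((target - start)^2)) / speed
}

#' Average movement speed over completed trials
#'
#' The mean over trials of `R / (hit_time - onset_time)`.
#'
#' @param trials data.frame with `onset_time` and `hit_time` (seconds).
#' @param radius target radius R.
#' @return speed in screen units per second.
#' @export
average_speed <- function(trials, radius) {
  ok <- !is.na(trials$onset_time) & !is.na(trials$hit_time) &
    trials$hit_time > trials$onset_time
  if (!any(ok)) stop("no completed trials to estimate speed from")
  mean(radius / (trials$hit_time[ok] - trials$onset_time[ok]))
}

#' Optimize the repositioning fraction alpha
#'
#' Simulates the assisted movement time of every trial for each alpha on the
#' grid (cursor pre-positioned toward the predicted target, then moved in a
#' straight line to the true target at the given speed) and returns the grid
#' arg-min of the mean time, ties broken toward the smaller alpha. At
#' `alpha = 0` the curve equals the baseline mean time `R / speed` exactly.
#'
#' @param predictions data.frame with 0-based `true` and `predicted` target
#'   indices, one row per trial.
#' @param layout a [target_layout()].
#' @param speed cursor speed in screen units per second.
#' @param alpha_grid candidate alphas in `[0, 1]` (default 0 to 1 by 0.05).
#' @return list with `alpha` (the optimum), `alpha_grid`, `mean_time`
#'   (seconds per grid value) and `baseline_time`.
#' @export
optimize_alpha <- function(predictions, layout, speed,
                           alpha_grid = seq(0, 1, by = 0.05)) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0 & alpha_grid <= 1))
  mean_time <- vapply(alpha_grid, function(a) {
    mean(vapply(seq_len(nrow(predictions)), function(i) {
      movement_time(
        reposition_cursor(predictions$predicted[i], a, layout),
        target_position(predictions$true[i], layout), speed)
    }, numeric(1)))
  }, numeric(1))
  best <- which.min(mean_time)  # first minimum = smallest alpha on ties
  list(alpha = alpha_grid[best], alpha_grid = alpha_grid,
       mean_time = mean_time, baseline_time = layout$radius / speed)
}

#' Fraction of the target circle closer to a target on its rim
#'
#' Two circles of radius R whose centers are `center_distance` apart (the
#' solid center circle and the locus of points at distance R from a target
#' on its rim) intersect in a lens. With the standard configuration
#' (`center_distance = R`) the lens covers `(2 pi / 3 - sqrt(3) / 2) / pi`,
#' about 39%, of the solid circle: a randomly repositioned cursor has a 61%
#' chance of ending up farther from the target than the center was.
#'
#' @param layout a [target_layout()].
#' @param center_distance distance between the circle centers (default R).
#' @return fraction in `[0, 1]`.
#' @export
lens_area_fraction <- function(layout, center_distance = layout$radius) {
  R <- layout$radius
  d <- center_distance
  if (d >= 2 * R) return(0)
  lens <- 2 * R^2 * acos(d / (2 * R)) - (d / 2) * sqrt(4 * R^2 - d^2)
  lens / (pi * R^2)
}

#' Angular error margin of the assisted targeting geometry
#'
#' The angle at the center between the ray through the true target and the
#' ray through an intersection point of the two circles. In the standard
#' configuration the centers and an intersection point form an equilateral
#' triangle, giving a margin of exactly 60 degrees: a directional prediction
#' within +-60 degrees lands the fully repositioned cursor closer to the
#' target.
#'
#' @inheritParams lens_area_fraction
#' @return margin in degrees.
#' @export
error_margin <- function(layout, center_distance = layout$radius) {
  acos(center_distance / (2 * layout$radius)) * 180 / pi
}

#' Chance-level angular error statistics
#'
#' Exact mean and standard deviation of the absolute angular error when the
#' predicted target is uniform over the layout and independent of the truth,
#' computed over the discrete outcome distribution (for 8 targets: errors
#' {0, 45, 90, 135, 180} degrees with weights {1, 2, 2, 2, 1}/8).
#'
#' @param n_targets number of equally spaced targets.
#' @return named numeric vector `c(mean =, sd =)` in degrees.
#' @export
chance_angular_stats <- function(n_targets = 8) {
  errs <- angular_error(0:(n_targets - 1), 0, n_targets)
  m <- mean(errs)
  c(mean = m, sd = sqrt(mean(errs^2) - m^2))
}

#' Compare assisted and unassisted movement times
#'
#' Paired per-trial comparison of baseline and assisted movement times:
#' mean times, percentage of trials improved (assisted strictly faster) and
#' degraded (ties counted as degraded), and a paired one-sided t-test of
#' improvement.
#'
#' @param baseline_times,assisted_times numeric vectors of per-trial
#'   movement times in seconds (same length, paired).
#' @return list with `mean_baseline`, `mean_assisted`, `pct_improved`,
#'   `pct_degraded`, `p_value` and `n`.
#' @export
compare_with_without <- function(baseline_times, assisted_times) {
  stopifnot(length(baseline_times) == length(assisted_times),
            length(baseline_times) >= 1)
  improved <- assisted_times < baseline_times
  diffs <- baseline_times - assisted_times
  # (near-)constant differences break the t-test; the one-sided conclusion
  # is determined by the sign alone in that case
  p <- if (length(diffs) < 2 ||
             stats::sd(diffs) <= 1e-10 * max(1, abs(mean(diffs)))) {
    if (mean(diffs) > 0) 0 else 1
  } else {
    stats::t.test(diffs, mu = 0, alternative = "greater")$p.value
  }
  list(mean_baseline = mean(baseline_times),
       mean_assisted = mean(assisted_times),
       pct_improved = 100 * mean(improved),
       pct_degraded = 100 * mean(!improved),
       p_value = p, n = length(baseline_times))
}
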