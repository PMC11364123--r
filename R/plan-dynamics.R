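# Leaf kinematics: the time / speed / acceleration substrate of the
# MLC-dynamics complexity metrics.
#
# With the dose rate fixed during delivery, MU is proportional to beam-on
# time, so interval durations follow directly from the cumulative meterset
# fraction: dt_n = dcmf_n * meterset / dose_rate (converted to seconds).

# Leaf-interval speeds below this (cm/s) count as parked, so closed or
# stationary leaves do not dilute the moving-leaf statistics.
MOVING_SPEED_TOL <- 1e-4

#' Derive per-leaf time, speed and acceleration series from a beam
#'
#' Interval durations come from the fixed-dose-rate proportionality between
#' MU and time. Speeds are `|dx|/dt` per bank leaf (cm/s); accelerations are
#' centred differences of consecutive interval speeds over the midpoint time
#' step, so a beam with `n` control points has `n-1` speed values and `n-2`
#' acceleration values per leaf. Both banks are stacked along the leaf axis
#' (bank A rows first).
#'
#' @param beam An [rt_beam()]. Zero-MU intervals are degenerate (no elapsed
#'   time) and have already been rejected by the beam validator.
#' @return An object of class `leaf_kinematics`: list with `beam_id`,
#'   `times` (s, at control points), `dt` (s, per interval), `speeds`
#'   (cm/s, `[2*n_pairs x n_int]`), `accelerations` (cm/s^2,
#'   `[2*n_pairs x n_int-1]`), `travel` (cm per leaf), `interval_mu` (MU).
#' @export
derive_kinematics <- function(beam) {
  dcmf <- diff(beam$cmf)
  dt <- dcmf * beam$meterset / beam$dose_rate * 60  # s
  times <- c(0, cumsum(dt))
  # [leaf x interval] displacement in mm; banks stacked A then B
  dx <- rbind(t(abs(diff(beam$bank_a))), t(abs(diff(beam$bank_b))))
  if (length(beam$cmf) == 2L) dx <- matrix(dx, ncol = 1L)
  speeds <- sweep(dx / 10, 2, dt, "/")  # cm/s
  n_int <- length(dt)
  if (n_int >= 2L) {
    mid_dt <- (dt[-n_int] + dt[-1]) / 2
    accel <- sweep(speeds[, -1, drop = FALSE] -
                     speeds[, -n_int, drop = FALSE], 2, mid_dt, "/")
  } else {
    accel <- matrix(numeric(0), nrow = nrow(speeds), ncol = 0)
  }
  structure(
    list(beam_id = beam$id, times = times, dt = dt, speeds = speeds,
         accelerations = accel, travel = rowSums(dx) / 10,
         interval_mu = dcmf * beam$meterset,
         meterset = beam$meterset, dose_rate = beam$dose_rate),
    class = "leaf_kinematics")
}

#' Summarise leaf kinematics for the dynamics metric family
#'
#' @param k A [derive_kinematics()] result.
#' @param moving_threshold Speed (cm/s) above which a leaf-interval counts
#'   as moving; prevents parked/closed leaves diluting the mean speed.
#' @param max_speed Physical maximum leaf speed (cm/s) used for the
#'   at-limit fraction.
#' @return A list: `LS_mean`, `LS_sd` (cm/s over moving leaf-intervals; 0 and
#'   flagged via `all_static` when nothing moves), `LS_max`, `frac_at_max`
#'   (fraction of moving intervals at/above `max_speed`), `LT_mean` (cm,
#'   mean total travel over leaves that move at least once), `LT_sum` (cm,
#'   summed over leaves), `LT_per_mu` (cm/MU from `LT_mean`),
#'   `moving_fraction`, `all_static`.
#' @export
kinematic_summaries <- function(k, moving_threshold = MOVING_SPEED_TOL,
                                max_speed = 2.5) {
  moving <- k$speeds > moving_threshold
  sp <- k$speeds[moving]
  all_static <- !length(sp)
  moving_leaves <- k$travel > moving_threshold * sum(k$dt)
  lt_mean <- if (any(moving_leaves)) mean(k$travel[moving_leaves]) else 0
  list(
    LS_mean = if (all_static) 0 else mean(sp),
    LS_sd = if (all_static) 0 else if (length(sp) > 1) sd(sp) else 0,
    LS_max = if (all_static) 0 else max(sp),
    frac_at_max = if (all_static) 0 else mean(sp >= max_speed),
    LT_mean = lt_mean,
    LT_sum = sum(k$travel),
    LT_per_mu = lt_mean / k$meterset,
    moving_fraction = mean(moving),
    all_static = all_static)
}

#' @export
print.leaf_kinematics <- function(x, ...) {
  cat(sprintf(
    "<leaf_kinematics '%s'> %d leaves x %d intervals, %.1f s beam-on\n",
    x$beam_id, nrow(x$speeds), ncol(x$speeds), max(x$times)))
  invisible(x)
}
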