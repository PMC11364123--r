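# In-memory plan model for sliding-window IMRT.
#
# A beam stores its control-point sequence as matrices (one row per control
# point, one column per leaf pair) rather than a list of per-CP records:
# every downstream computation (kinematics, aperture metrics, fluence) is
# vectorised over control points, and the matrix layout makes that natural.
# `control_point()` exposes the per-CP record view of the same data.

#' Construct a sliding-window IMRT beam
#'
#' @param id Beam label.
#' @param meterset Beam meterset in MU (> 0).
#' @param dose_rate Dose rate in MU/min; the study's delivery is fixed at
#'   400 MU/min, which is the default when a source file omits it.
#' @param leaf_boundaries Numeric vector of leaf-pair edges (mm) along the
#'   direction orthogonal to leaf travel; strictly increasing, length
#'   `n_pairs + 1`.
#' @param cmf Cumulative meterset fraction per control point: non-decreasing,
#'   first 0, last 1, no repeated values (zero-MU intervals are degenerate
#'   for the kinematics stage and rejected here).
#' @param bank_a,bank_b Matrices `[n_cp x n_pairs]` of leaf positions in mm,
#'   IEC beam-limiting-device X coordinates. Bank A is the larger-coordinate
#'   side; `bank_b <= bank_a` (a closed pair has gap 0; gaps more negative
#'   than the closed-pair tolerance are invalid).
#' @param jaw_x,jaw_y Jaw openings in mm, either a length-2 vector (static
#'   jaws) or an `[n_cp x 2]` matrix.
#' @return An object of class `rt_beam`.
#' @export
rt_beam <- function(id, meterset, dose_rate = 400, leaf_boundaries,
                    cmf, bank_a, bank_b, jaw_x, jaw_y) {
  bank_a <- unname(as.matrix(bank_a))
  bank_b <- unname(as.matrix(bank_b))
  n_cp <- length(cmf)
  expand_jaw <- function(j) {
    if (is.null(dim(j))) matrix(rep(as.numeric(j), each = n_cp), ncol = 2)
    else unname(as.matrix(j))
  }
  beam <- structure(
    list(id = as.character(id), meterset = as.numeric(meterset),
         dose_rate = as.numeric(dose_rate),
         leaf_boundaries = as.numeric(leaf_boundaries),
         cmf = as.numeric(cmf), bank_a = bank_a, bank_b = bank_b,
         jaw_x = expand_jaw(jaw_x), jaw_y = expand_jaw(jaw_y)),
    class = "rt_beam")
  validate_beam(beam)
}

#' Validate an `rt_beam` against the plan-model invariants
#'
#' Checks control-point monotonicity, bank ordering (clamping sub-tolerance
#' negative gaps to closed), leaf-boundary ordering and dimension agreement.
#' Called by [rt_beam()]; exported for use on externally assembled objects.
#'
#' @param beam An `rt_beam`.
#' @return The (possibly gap-clamped) beam, invisibly valid.
#' @export
validate_beam <- function(beam) {
  n_cp <- length(beam$cmf)
  n_pairs <- length(beam$leaf_boundaries) - 1L
  if (n_cp < 2L)
    stop("beam '", beam$id, "': needs at least 2 control points")
  if (!is.finite(beam$meterset) || beam$meterset <= 0)
    stop("beam '", beam$id, "': meterset must be > 0")
  if (!is.finite(beam$dose_rate) || beam$dose_rate <= 0)
    stop("beam '", beam$id, "': dose_rate must be > 0")
  if (n_pairs < 1L || any(diff(beam$leaf_boundaries) <= 0))
    stop("beam '", beam$id, "': leaf_boundaries must be strictly increasing")
  if (!identical(dim(beam$bank_a), dim(beam$bank_b)))
    stop("beam '", beam$id, "': bank matrices must have equal dimensions")
  if (nrow(beam$bank_a) != n_cp || ncol(beam$bank_a) != n_pairs)
    stop("beam '", beam$id, "': bank matrices must be [n_cp x n_pairs]")
  if (abs(beam$cmf[1]) > 1e-12 || abs(beam$cmf[n_cp] - 1) > 1e-9)
    stop("beam '", beam$id,
         "': cumulative meterset fraction must start at 0 and end at 1")
  dcmf <- diff(beam$cmf)
  if (any(dcmf < 0)) {
    bad <- which(dcmf < 0)[1] + 1L
    stop("beam '", beam$id, "': cumulative meterset fraction decreases at ",
         "control point ", bad)
  }
  if (any(dcmf == 0)) {
    bad <- which(dcmf == 0)[1] + 1L
    stop("beam '", beam$id, "': zero-MU interval at control point ", bad,
         " (degenerate for leaf kinematics)")
  }
  gap <- beam$bank_a - beam$bank_b
  if (any(gap < -CLOSED_GAP_TOL)) {
    idx <- which(gap < -CLOSED_GAP_TOL, arr.ind = TRUE)[1, ]
    stop("beam '", beam$id, "': bank B exceeds bank A at control point ",
         idx[1], ", leaf pair ", idx[2])
  }
  # absorb round-off: force tiny negative gaps to exactly closed
  neg <- gap < 0
  if (any(neg)) beam$bank_b[neg] <- beam$bank_a[neg]
  beam
}

#' Construct a treatment plan
#'
#' @param id Plan label.
#' @param site Treatment site, one of `"head_and_neck"`,
#'   `"chest_and_abdomen"`, `"pelvis"`, `"limbs"`.
#' @param prescribed_dose Prescription dose in Gy (> 0).
#' @param beams List of [rt_beam()] objects (at least one).
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(id, site, prescribed_dose, beams) {
  site <- match.arg(site, PLAN_SITES)
  if (!is.finite(prescribed_dose) || prescribed_dose <= 0)
    stop("plan '", id, "': prescribed_dose must be > 0")
  if (!length(beams))
    stop("plan '", id, "': needs at least one beam")
  if (!all(vapply(beams, inherits, logical(1), "rt_beam")))
    stop("plan '", id, "': beams must be rt_beam objects")
  structure(list(id = as.character(id), site = site,
                 prescribed_dose = as.numeric(prescribed_dose),
                 beams = beams),
            class = "rt_plan")
}

#' Extract one control point of a beam as a record
#'
#' @param beam An `rt_beam`.
#' @param i Control-point index (1-based).
#' @return A list with fields `index`, `cmf`, `bank_a`, `bank_b`, `jaw_x`,
#'   `jaw_y`.
#' @export
control_point <- function(beam, i) {
  stopifnot(i >= 1, i <= length(beam$cmf))
  list(index = i, cmf = beam$cmf[i],
       bank_a = beam$bank_a[i, ], bank_b = beam$bank_b[i, ],
       jaw_x = beam$jaw_x[i, ], jaw_y = beam$jaw_y[i, ])
}

#' @export
print.rt_beam <- function(x, ...) {
  cat(sprintf("<rt_beam '%s'> %d CPs, %d leaf pairs, %.1f MU @ %g MU/min\n",
              x$id, length(x$cmf), ncol(x$bank_a), x$meterset, x$dose_rate))
  invisible(x)
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan '%s'> site=%s, %.1f Gy, %d beams, %.0f MU total\n",
              x$id, x$site, x$prescribed_dose, length(x$beams),
              plan_meterset(x)))
  invisible(x)
}

#' Total plan meterset (MU)
#' @param plan An `rt_plan`.
#' @return Sum of beam metersets.
#' @export
plan_meterset <- function(plan) {
  sum(vapply(plan$beams, function(b) b$meterset, numeric(1)))
}

# MU-weighted mean of per-beam values; the standard aggregation from beam to
# plan level used by every plan-level metric.
beam_weighted_mean <- function(plan, values) {
  mu <- vapply(plan$beams, function(b) b$meterset, numeric(1))
  sum(values * mu) / sum(mu)
}

# Trapezoidal per-CP MU weights: w_i = (dcmf_{i-1} + dcmf_i)/2 with half
# intervals at the ends. Symmetric under time reversal and stable (to the
# stated 1e-9) under splitting a CP's weight across identical entries.
cp_mu_weights <- function(cmf) {
  d <- diff(cmf)
  w <- c(d / 2, 0) + c(0, d / 2)
  w
}

# Weighted mean that renormalises over the kept entries; `keep` marks CPs
# that participate (e.g. non-zero-area CPs for aperture metrics).
weighted_mean_kept <- function(values, weights, keep = NULL) {
  if (!is.null(keep)) {
    values <- values[keep]
    weights <- weights[keep]
  }
  tw <- sum(weights)
  if (tw <= 0 || !length(values)) return(NA_real_)
  sum(values * weights) / tw
}

#' Reverse a beam in time
#'
#' Returns the beam delivered back-to-front: control points in reverse order
#' with the cumulative meterset fraction remapped to `1 - rev(cmf)`. Useful
#' for symmetry checks — scalar complexity metrics are invariant under this
#' transformation.
#'
#' @param beam An `rt_beam`.
#' @return The time-reversed `rt_beam`.
#' @export
reverse_beam <- function(beam) {
  n <- length(beam$cmf)
  idx <- n:1
  rt_beam(id = beam$id, meterset = beam$meterset,
          dose_rate = beam$dose_rate,
          leaf_boundaries = beam$leaf_boundaries,
          cmf = 1 - beam$cmf[idx],
          bank_a = beam$bank_a[idx, , drop = FALSE],
          bank_b = beam$bank_b[idx, , drop = FALSE],
          jaw_x = beam$jaw_x[idx, , drop = FALSE],
          jaw_y = beam$jaw_y[idx, , drop = FALSE])
}
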