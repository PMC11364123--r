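# Named complexity-metric operations: modulation complexity score,
# modulation indices for leaf speed/acceleration, small-aperture and
# MU-family metrics. Plan-level values aggregate beam values by MU weight.

#' Configuration of the complexity-metric registry
#'
#' All tunable metric parameters in one place. Defaults: 0.5 mm aperture
#' raster, 5 mm edge margin for the edge-area metric, 5 mm distance scale
#' for the converted-aperture fallback, small-aperture gap thresholds
#' 2/5/10/20 mm, modulation-index integration over f in \[0, 1\] on a
#' 1000-node grid with weight `w(v) = 1 + c*v/sigma` and `c = 1` (a
#' variation around 2.5 sigma then gets roughly double the weight of one
#' around 0.5 sigma), maximum leaf speed 2.5 cm/s.
#'
#' @param raster_res_mm Aperture raster resolution (mm) for EAM/CAM.
#' @param eam_margin_mm Edge-region margin (mm) of the edge-area metric.
#' @param cam_kappa_mm Distance scale (mm) of the converted-aperture
#'   fallback.
#' @param sas_gaps_mm Gap thresholds (mm) of the small-aperture scores.
#' @param f_grid Threshold-multiplier grid for the modulation indices.
#' @param mi_weight_c Weighting slope `c` of the modulation indices
#'   (0 recovers the unweighted fraction).
#' @param moving_threshold_cm_s Speed below which a leaf-interval is parked.
#' @param max_speed_cm_s Physical maximum leaf speed.
#' @param small_field_cm2 Area threshold of the small-field fraction.
#' @param ltmcs_scale_cm Travel scale of the travel-weighted MCS variant.
#' @return A list of class `pcm_config`.
#' @export
pcm_config <- function(raster_res_mm = 0.5, eam_margin_mm = 5,
                       cam_kappa_mm = 5, sas_gaps_mm = c(2, 5, 10, 20),
                       f_grid = seq(0, 1, length.out = 1000),
                       mi_weight_c = 1, moving_threshold_cm_s = MOVING_SPEED_TOL,
                       max_speed_cm_s = 2.5, small_field_cm2 = 10,
                       ltmcs_scale_cm = 100) {
  structure(list(raster_res_mm = raster_res_mm, eam_margin_mm = eam_margin_mm,
                 cam_kappa_mm = cam_kappa_mm, sas_gaps_mm = sas_gaps_mm,
                 f_grid = f_grid, mi_weight_c = mi_weight_c,
                 moving_threshold_cm_s = moving_threshold_cm_s,
                 max_speed_cm_s = max_speed_cm_s,
                 small_field_cm2 = small_field_cm2,
                 ltmcs_scale_cm = ltmcs_scale_cm),
            class = "pcm_config")
}

#' Modulation complexity score of a beam or plan
#'
#' The MU-weighted sum over delivery intervals of the product of the
#' leaf-sequence variability (LSV) and aperture-area variability (AAV),
#' interval values being the mean of the two bounding control points. 1 for
#' a static unmodulated field; decreases with modulation.
#'
#' @param x An [rt_beam()] or [rt_plan()] (plan value: MU-weighted mean over
#'   beams).
#' @param config A [pcm_config()].
#' @return A scalar in (0, 1] (0, with a warning, for a zero-area beam).
#' @export
mcs <- function(x, config = pcm_config()) {
  if (inherits(x, "rt_plan"))
    return(beam_weighted_mean(x, vapply(x$beams, mcs, numeric(1),
                                        config = config)))
  f <- beam_aperture_features(x, config)
  mcs_from_features(f, x$cmf)
}

mcs_from_features <- function(f, cmf) {
  if (all(f$area <= 0)) {
    warning("zero-area beam: MCS set to 0")
    return(0)
  }
  n <- length(cmf)
  d <- diff(cmf)
  v <- (f$aav[-n] + f$aav[-1]) / 2 * (f$lsv[-n] + f$lsv[-1]) / 2
  sum(v * d)
}

# Weighted exceedance integral shared by MI_s / MI_a: values v >= 0,
# sigma their spread; Z(f) = sum(w[v > f*sigma]) / sum(w) with
# w = 1 + c*v/sigma, integrated over f_grid by the trapezoidal rule.
mi_integral <- function(values, sigma, f_grid, weight_c) {
  if (!length(values) || !is.finite(sigma) || sigma <= 0) return(0)
  w <- 1 + weight_c * values / sigma
  tw <- sum(w)
  ord <- order(values)
  v_sorted <- values[ord]
  cw_above <- rev(cumsum(rev(w[ord])))  # weight of values >= v_sorted[i]
  z <- vapply(f_grid, function(f) {
    i <- findInterval(f * sigma, v_sorted)  # v_sorted[i] <= f*sigma
    if (i >= length(v_sorted)) 0 else cw_above[i + 1] / tw
  }, numeric(1))
  sum((z[-1] + z[-length(z)]) / 2 * diff(f_grid))
}

#' Modulation index for MLC speed
#'
#' Measures the jaggedness of the leaf-speed pattern: the per-leaf speed
#' variations between consecutive delivery intervals, `|s_(n+1) - s_n|`,
#' are compared against multiples of `sigma_s`, the standard deviation of
#' all moving leaf-interval speeds. `Z(f)` is the weighted fraction of
#' variations exceeding `f*sigma_s` — larger variations receive larger
#' weight (`w = 1 + c*v/sigma_s`) — and the index integrates `Z` over the
#' configured `f` range. 0 by convention when nothing moves or all speeds
#' are equal (`sigma_s = 0`).
#'
#' @param k A [derive_kinematics()] result.
#' @param config A [pcm_config()] (uses `f_grid` and `mi_weight_c`).
#' @return Non-negative scalar.
#' @export
mi_speed <- function(k, config = pcm_config()) {
  sp <- k$speeds
  if (ncol(sp) < 2) return(0)
  moving <- sp > config$moving_threshold_cm_s
  sigma <- sd(sp[moving])
  # guard against pure float round-off on constant-speed patterns
  if (!is.finite(sigma) || sigma <= 1e-9) return(0)
  adj <- moving[, -ncol(sp), drop = FALSE] | moving[, -1, drop = FALSE]
  v <- abs(sp[, -1, drop = FALSE] - sp[, -ncol(sp), drop = FALSE])[adj]
  if (!length(v)) return(0)
  mi_integral(v, sigma, config$f_grid, config$mi_weight_c)
}

#' Modulation index for MLC acceleration
#'
#' As [mi_speed()], one level up: acceleration variations between
#' consecutive intervals against multiples of `sigma_a`, the standard
#' deviation of the accelerations of leaf-intervals adjacent to motion.
#'
#' @inheritParams mi_speed
#' @return Non-negative scalar.
#' @export
mi_accel <- function(k, config = pcm_config()) {
  ac <- k$accelerations
  if (ncol(ac) < 2) return(0)
  n_int <- ncol(k$speeds)
  moving <- k$speeds > config$moving_threshold_cm_s
  adj <- moving[, -n_int, drop = FALSE] | moving[, -1, drop = FALSE]
  sigma <- sd(ac[adj])
  if (!is.finite(sigma) || sigma <= 1e-9) return(0)
  adj2 <- adj[, -ncol(ac), drop = FALSE] | adj[, -1, drop = FALSE]
  v <- abs(ac[, -1, drop = FALSE] - ac[, -ncol(ac), drop = FALSE])[adj2]
  if (!length(v)) return(0)
  mi_integral(v, sigma, config$f_grid, config$mi_weight_c)
}

#' Small-aperture metrics of a plan
#'
#' MU-weighted over control points (zero-area control points excluded with
#' weight renormalisation): `SAS_x`, the fraction of open leaf pairs with
#' gap below x mm; `MFA`, mean field area (cm^2); `EAM`, the fraction of
#' the open area lying within the edge margin of any aperture edge
#' (raster-based); `CAM`, the converted-aperture fallback — mean over open
#' aperture points of `exp(-d/kappa)` with `d` the distance to the nearest
#' aperture edge (flagged as a fallback definition in the registry).
#'
#' @param plan An [rt_plan()].
#' @param config A [pcm_config()].
#' @return Named list: `SAS_2`, `SAS_5`, `SAS_10`, `SAS_20`, `MFA`, `EAM`,
#'   `CAM` (names follow `sas_gaps_mm`).
#' @export
small_aperture_metrics <- function(plan, config = pcm_config()) {
  per_beam <- lapply(plan$beams, function(b) {
    f <- beam_aperture_features(b, config)
    keep <- f$area > 0
    c(vapply(colnames(f$sas), function(nm)
        weighted_mean_kept(f$sas[, nm], f$weights, keep), numeric(1)),
      MFA = weighted_mean_kept(f$area, f$weights, keep),
      EAM = weighted_mean_kept(f$eam, f$weights, keep & !is.na(f$eam)),
      CAM = weighted_mean_kept(f$cam, f$weights, keep & !is.na(f$cam)))
  })
  m <- do.call(rbind, per_beam)
  as.list(apply(m, 2, function(v) beam_weighted_mean(plan, v)))
}

#' MU-family metrics of a plan
#'
#' `MU` (total meterset), `MU_per_Gy` (meterset per prescribed Gy), `BI`
#' (beam irregularity: MU-weighted `perimeter^2 / (4 pi area)`, 1 for a
#' circular field) and `PM` (plan modulation:
#' `1 - sum_cp MU_cp * A_cp / (MU_beam * A_union)` per beam, MU-weighted
#' over beams; 0 for a single-aperture beam).
#'
#' @param plan An [rt_plan()].
#' @param config A [pcm_config()].
#' @return Named list with `MU`, `MU_per_Gy`, `BI`, `PM`.
#' @export
mu_metrics <- function(plan, config = pcm_config()) {
  per_beam <- lapply(plan$beams, function(b) {
    f <- beam_aperture_features(b, config)
    keep <- f$area > 0
    bi <- weighted_mean_kept(f$perimeter^2 / (4 * pi * f$area), f$weights,
                             keep)
    pm <- if (f$union_area > 0)
      1 - sum(f$weights * f$area) / f$union_area
    else NA_real_
    c(BI = bi, PM = pm)
  })
  m <- do.call(rbind, per_beam)
  list(MU = plan_meterset(plan),
       MU_per_Gy = plan_meterset(plan) / plan$prescribed_dose,
       BI = beam_weighted_mean(plan, m[, "BI"]),
       PM = beam_weighted_mean(plan, m[, "PM"]))
}
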