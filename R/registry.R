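# The 53-slot complexity-metric registry. Every metric is a named plugin
# (shared plan features -> scalar) carrying its family, its orientation
# (declared sign of its association with plan complexity: +1 higher = more
# complex, -1 lower = more complex, 0 structural/no declared direction) and
# whether its definition is a documented fallback rather than a canonical
# published form.

# Shared per-plan features computed once and consumed by all plugins.
plan_features <- function(plan, config = pcm_config()) {
  beams <- lapply(plan$beams, function(b) {
    ap <- beam_aperture_features(b, config)
    k <- derive_kinematics(b)
    summ <- kinematic_summaries(k, config$moving_threshold_cm_s,
                                config$max_speed_cm_s)
    # gap-change speed per pair (cm/s): |d gap| / dt
    gap <- b$bank_a - b$bank_b
    dgap <- t(abs(diff(gap))) / 10
    gap_speed <- sweep(dgap, 2, diff(b$cmf) * b$meterset / b$dose_rate * 60,
                       "/")
    list(meterset = b$meterset, ap = ap, kin = k, summ = summ,
         gap_speed = gap_speed, n_cp = length(b$cmf), mcs_beam =
           suppressWarnings(mcs_from_features(ap, b$cmf)))
  })
  mu <- vapply(beams, function(x) x$meterset, numeric(1))
  list(plan = plan, beams = beams, beam_mu = mu, config = config)
}

# MU-weighted plan aggregate of a per-beam function.
agg_beam <- function(ft, fn) {
  v <- vapply(ft$beams, fn, numeric(1))
  sum(v * ft$beam_mu) / sum(ft$beam_mu)
}

# MU-weighted CP aggregate within beams, then MU-weighted over beams.
# `value_fn(bf)` returns per-CP values; CPs with zero aperture are dropped
# with weight renormalisation.
agg_cp <- function(ft, value_fn, keep_fn = function(bf) bf$ap$area > 0) {
  agg_beam(ft, function(bf) {
    v <- value_fn(bf)
    weighted_mean_kept(v, bf$ap$weights, keep_fn(bf) & !is.na(v))
  })
}

# Moving-leaf speed / acceleration pools across all beams of the plan.
pool_speeds <- function(ft) {
  unlist(lapply(ft$beams, function(bf)
    bf$kin$speeds[bf$kin$speeds > ft$config$moving_threshold_cm_s]))
}
pool_accels <- function(ft) {
  unlist(lapply(ft$beams, function(bf) {
    k <- bf$kin
    if (!ncol(k$accelerations)) return(numeric(0))
    n_int <- ncol(k$speeds)
    moving <- k$speeds > ft$config$moving_threshold_cm_s
    adj <- moving[, -n_int, drop = FALSE] | moving[, -1, drop = FALSE]
    abs(k$accelerations[adj])
  }))
}

registry_entry <- function(name, category, orientation, fn, fallback = FALSE)
  list(name = name, category = category, orientation = orientation,
       fn = fn, fallback = fallback)

#' The default 53-metric registry
#'
#' Covers the aperture/fluence, MU and MLC-dynamics families: the
#' modulation complexity score and its LSV/AAV factors, mean field area,
#' edge-area and converted-aperture metrics, small-aperture scores at
#' 2/5/10/20 mm, gap statistics, irregularity measures, monitor-unit
#' metrics, plan modulation, and the dynamics family built on leaf speed
#' and acceleration (modulation indices, leaf travel in leaf-mean and
#' leaf-sum variants, travel per MU, speed/acceleration statistics).
#' Metrics whose published definition could not be pinned down ship as
#' documented fallbacks and are flagged (`fallback = TRUE`).
#'
#' @return A named list of registry entries (name, category, orientation,
#'   fallback, plugin function).
#' @export
pcm_registry <- function() {
  sd0 <- function(v) if (length(v) > 1) sd(v) else 0
  e <- list(
    # --- aperture / fluence family ---
    registry_entry("MCS", "aperture", -1, function(ft)
      agg_beam(ft, function(bf) bf$mcs_beam)),
    registry_entry("LSV", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) bf$ap$lsv)),
    registry_entry("AAV", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) bf$ap$aav)),
    registry_entry("MFA", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) bf$ap$area)),
    registry_entry("EAM", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$eam)),
    registry_entry("CAM", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$cam), fallback = TRUE),
    registry_entry("MAD", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$mad), fallback = TRUE),
    registry_entry("SAS_2", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$sas[, "SAS_2"])),
    registry_entry("SAS_5", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$sas[, "SAS_5"])),
    registry_entry("SAS_10", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$sas[, "SAS_10"])),
    registry_entry("SAS_20", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$sas[, "SAS_20"])),
    registry_entry("mean_gap", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) rowMeans(bf$ap$gaps, na.rm = TRUE))),
    registry_entry("sd_gap", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) apply(bf$ap$gaps, 1, function(g)
        sd0(g[!is.na(g)])))),
    registry_entry("max_gap", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) suppressWarnings(
        apply(bf$ap$gaps, 1, max, na.rm = TRUE)))),
    registry_entry("min_gap", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) suppressWarnings(
        apply(bf$ap$gaps, 1, min, na.rm = TRUE)))),
    registry_entry("mean_perimeter", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$perimeter)),
    registry_entry("edge_metric", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$end_edges / bf$ap$area)),
    registry_entry("BI", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$perimeter^2 / (4 * pi * bf$ap$area))),
    registry_entry("PA_ratio", "aperture", +1, function(ft)
      agg_cp(ft, function(bf) bf$ap$perimeter / bf$ap$area)),
    registry_entry("EFS", "aperture", -1, function(ft)
      agg_cp(ft, function(bf) 4 * bf$ap$area / bf$ap$perimeter)),
    registry_entry("area_sd", "aperture", 0, function(ft)
      agg_beam(ft, function(bf) sd0(bf$ap$area[bf$ap$area > 0]))),
    registry_entry("small_field_frac", "aperture", +1, function(ft)
      agg_cp(ft, function(bf)
        as.numeric(bf$ap$area < ft$config$small_field_cm2))),
    registry_entry("min_area", "aperture", -1, function(ft)
      agg_beam(ft, function(bf) min(bf$ap$area[bf$ap$area > 0]))),
    registry_entry("union_area", "aperture", 0, function(ft)
      agg_beam(ft, function(bf) bf$ap$union_area)),
    registry_entry("open_pair_fraction", "aperture", 0, function(ft)
      agg_cp(ft, function(bf) bf$ap$n_open / ncol(bf$ap$gaps))),
    registry_entry("y_extent", "aperture", 0, function(ft)
      agg_beam(ft, function(bf) bf$ap$y_extent)),
    registry_entry("x_range", "aperture", 0, function(ft)
      agg_beam(ft, function(bf) bf$ap$x_range)),
    # --- MU family ---
    registry_entry("MU", "mu", +1, function(ft) sum(ft$beam_mu)),
    registry_entry("MU_per_Gy", "mu", +1, function(ft)
      sum(ft$beam_mu) / ft$plan$prescribed_dose),
    registry_entry("PM", "mu", +1, function(ft)
      agg_beam(ft, function(bf)
        if (bf$ap$union_area > 0)
          1 - sum(bf$ap$weights * bf$ap$area) / bf$ap$union_area
        else NA_real_)),
    registry_entry("MU_per_cp", "mu", +1, function(ft)
      agg_beam(ft, function(bf) bf$meterset / bf$n_cp)),
    registry_entry("beam_on_time", "mu", +1, function(ft)
      sum(vapply(ft$beams, function(bf) max(bf$kin$times), numeric(1)))),
    registry_entry("mean_beam_mu", "mu", +1, function(ft)
      mean(ft$beam_mu)),
    registry_entry("n_beams", "mu", 0, function(ft)
      length(ft$beams)),
    registry_entry("n_cp", "mu", 0, function(ft)
      sum(vapply(ft$beams, function(bf) bf$n_cp, numeric(1)))),
    # --- dynamics family ---
    registry_entry("MI_s", "dynamics", +1, function(ft)
      agg_beam(ft, function(bf) mi_speed(bf$kin, ft$config))),
    registry_entry("MI_a", "dynamics", +1, function(ft)
      agg_beam(ft, function(bf) mi_accel(bf$kin, ft$config))),
    registry_entry("LT", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) bf$summ$LT_mean)),
    registry_entry("LT_sum", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) bf$summ$LT_sum)),
    registry_entry("LT_per_MU", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) bf$summ$LT_per_mu)),
    registry_entry("LS_mean", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) bf$summ$LS_mean)),
    registry_entry("LS_sd", "dynamics", +1, function(ft)
      agg_beam(ft, function(bf) bf$summ$LS_sd)),
    registry_entry("LS_max", "dynamics", +1, function(ft)
      agg_beam(ft, function(bf) bf$summ$LS_max)),
    registry_entry("frac_max_speed", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) bf$summ$frac_at_max)),
    registry_entry("LA_mean", "dynamics", 0, function(ft) {
      v <- pool_accels(ft); if (length(v)) mean(v) else 0 }),
    registry_entry("LA_sd", "dynamics", 0, function(ft) {
      v <- pool_accels(ft); sd0(v) }),
    registry_entry("LA_max", "dynamics", 0, function(ft) {
      v <- pool_accels(ft); if (length(v)) max(v) else 0 }),
    registry_entry("gap_speed_mean", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) mean(bf$gap_speed))),
    registry_entry("gap_speed_sd", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) sd0(as.vector(bf$gap_speed)))),
    registry_entry("moving_fraction", "dynamics", 0, function(ft)
      agg_beam(ft, function(bf) bf$summ$moving_fraction)),
    registry_entry("speed_cv", "dynamics", +1, function(ft) {
      v <- pool_speeds(ft); if (length(v) > 1 && mean(v) > 0)
        sd(v) / mean(v) else 0 }),
    registry_entry("accel_cv", "dynamics", 0, function(ft) {
      v <- pool_accels(ft); if (length(v) > 1 && mean(v) > 0)
        sd(v) / mean(v) else 0 }),
    registry_entry("LTMCS", "dynamics", -1, function(ft)
      agg_beam(ft, function(bf)
        bf$mcs_beam * exp(-bf$summ$LT_mean / ft$config$ltmcs_scale_cm)))
  )
  names(e) <- vapply(e, function(x) x$name, character(1))
  e
}

#' Compute the full complexity-metric vector of a plan
#'
#' Evaluates every registered metric on shared per-plan features. A metric
#' that fails is recorded as unavailable with its reason and never aborts
#' the vector; identical plans give bitwise-identical vectors.
#'
#' @param plan An [rt_plan()].
#' @param registry A registry as returned by [pcm_registry()].
#' @param config A [pcm_config()].
#' @return An object of class `pcm_vector`: `plan_id`, `values` (named
#'   numeric), `category`, `orientation`, `fallback` (named per metric) and
#'   `unavailable` (named character of failure reasons, possibly empty).
#' @export
compute_pcm_vector <- function(plan, registry = pcm_registry(),
                               config = pcm_config()) {
  ft <- plan_features(plan, config)
  values <- numeric(length(registry))
  names(values) <- names(registry)
  unavailable <- character(0)
  for (nm in names(registry)) {
    v <- tryCatch(registry[[nm]]$fn(ft), error = function(e)
      structure(NA_real_, reason = conditionMessage(e)))
    if (is.na(v)) {
      reason <- attr(v, "reason")
      unavailable[nm] <- if (is.null(reason)) "value not defined" else reason
      values[nm] <- NA_real_
    } else values[nm] <- as.numeric(v)
  }
  structure(
    list(plan_id = plan$id, values = values,
         category = vapply(registry, function(x) x$category, character(1)),
         orientation = vapply(registry, function(x) x$orientation,
                              numeric(1)),
         fallback = vapply(registry, function(x) x$fallback, logical(1)),
         unavailable = unavailable),
    class = "pcm_vector")
}

#' @export
print.pcm_vector <- function(x, ...) {
  cat(sprintf("<pcm_vector '%s'> %d metrics (%d unavailable)\n",
              x$plan_id, length(x$values), length(x$unavailable)))
  invisible(x)
}
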