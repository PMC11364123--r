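# Synthetic QA study: site-stratified sliding-window plans with a
# controllable complexity dial, a toy planned dose per plan, and two
# surrogate verification channels with deliberately orthogonal error
# mechanisms — a calculation channel whose mismatch grows with
# small-aperture content, and a measurement channel whose delivery jitter
# grows with leaf speed (plus detector noise).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

plan_seed <- function(seed, i) {
  # derive a sub-stream seed; arithmetic in double to stay exact and the
  # result below 2^31 (R integers are 32-bit)
  as.integer((as.numeric(seed) %% 1048573) * 1009 + i * 7919) %%
    2147483647L
}

# Millennium-style 120-leaf bank: 10 outer pairs of 10 mm and 40 central
# pairs of 5 mm per side, spanning -200..200 mm.
millennium_boundaries <- function() {
  c(seq(-200, -100, by = 10), seq(-95, 95, by = 5), seq(100, 200, by = 10))
}

site_profile <- function(site) {
  switch(site,
    head_and_neck = list(n_beams = 7, wx = c(60, 110), wy = c(80, 160),
                         dose = c(60, 70), mu = c(90, 140)),
    chest_and_abdomen = list(n_beams = 5, wx = c(80, 140), wy = c(100, 180),
                             dose = c(45, 60), mu = c(80, 130)),
    pelvis = list(n_beams = 5, wx = c(80, 150), wy = c(100, 180),
                  dose = c(45, 55), mu = c(80, 130)),
    limbs = list(n_beams = 3, wx = c(60, 120), wy = c(80, 200),
                 dose = c(50, 66), mu = c(70, 120)))
}

#' Cohort configuration for the synthetic QA study
#'
#' Defaults mirror the study conditions: per-site plan counts of the two
#' linacs (46/32/65/9 and 122/64/59/7), 400 MU/min delivery, 2.5 mm dose
#' grid, the four gamma criteria with a 10% dose threshold, and the noise
#' coefficients of the two error channels.
#'
#' @param n_per_site_linac1,n_per_site_linac2 Named counts per site.
#' @param complexity_dial_range Range of the per-plan complexity dial.
#' @param seed Integer seed; the same seed gives a bitwise-identical cohort.
#' @param noise Error-channel coefficients. Measurement channel:
#'   `jitter_mm_per_speed_change` (mm of MLC positional sigma per cm/s of
#'   leaf speed change), `output_per_speed_change` (per-beam output sigma
#'   per cm/s of mean speed change), `systematic_offset_mm` (gap-widening
#'   offset), `detector_noise_percent` (i.i.d. relative detector noise).
#'   Calculation channel: `calc_blur_mm_per_small_aperture` (extra
#'   penumbra sigma per unit SAS_5), `calc_output_per_small_aperture`
#'   (fractional output offset per unit SAS_5), `ccc_scale` (multiplier on
#'   the calculation-channel coefficients for the second linac's
#'   collapsed-cone-like system).
#' @param decouple_sd Spread of the independent per-plan jiggle applied to
#'   the aperture and dynamics sub-dials around the common dial; keeps the
#'   two error channels only loosely coupled across the cohort.
#' @param n_cp Control points per beam.
#' @param dose Toy dose-engine settings: `spacing_mm`, `half_extent_mm`,
#'   `penumbra_sigma_mm`, `depth_mu_per_mm`.
#' @param gamma Gamma-engine settings: `threshold_percent`, `step_frac`,
#'   `search_factor`, `cap`.
#' @param criteria Criteria data.frame ([default_criteria()]).
#' @param pcm A [pcm_config()] used for the cohort's metric vectors.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_site_linac1 = c(head_and_neck = 46, chest_and_abdomen = 32,
                          pelvis = 65, limbs = 9),
    n_per_site_linac2 = c(head_and_neck = 122, chest_and_abdomen = 64,
                          pelvis = 59, limbs = 7),
    complexity_dial_range = c(0, 1),
    seed = 20240622,
    noise = list(jitter_mm_per_speed_change = 0.5,
                 output_per_speed_change = 0.15,
                 systematic_offset_mm = 0.05,
                 detector_noise_percent = 0.5,
                 calc_blur_mm_per_small_aperture = 6,
                 calc_output_per_small_aperture = 0.04,
                 ccc_scale = 1.6),
    decouple_sd = 0.35,
    n_cp = 60,
    dose = list(spacing_mm = 2.5, half_extent_mm = 115,
                penumbra_sigma_mm = 3, depth_mu_per_mm = 0.004),
    gamma = list(threshold_percent = 10, step_frac = 0.1,
                 search_factor = 3, cap = 1.1),
    criteria = default_criteria(),
    pcm = pcm_config()) {
  stopifnot(all(n_per_site_linac1 >= 0), all(n_per_site_linac2 >= 0),
            all(unlist(noise) >= 0))
  structure(list(n_per_site_linac1 = n_per_site_linac1,
                 n_per_site_linac2 = n_per_site_linac2,
                 complexity_dial_range = complexity_dial_range,
                 seed = as.integer(seed), noise = noise,
                 decouple_sd = decouple_sd, n_cp = n_cp, dose = dose,
                 gamma = gamma, criteria = criteria, pcm = pcm),
            class = "cohort_config")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate one synthetic sliding-window plan
#'
#' Both banks sweep unidirectionally left to right; the trailing bank's
#' increments carry a smooth per-leaf modulation whose variance grows with
#' the dynamics sub-dial, and the gap follows a smooth per-leaf process
#' whose mean shrinks and whose variance grows with the aperture sub-dial.
#' Leaf speeds are kept under the physical cap by increment clamping; a
#' plan that still validates infeasible is regenerated (up to 5 attempts).
#'
#' @param site One of the four cohort sites.
#' @param m Complexity dial in \[0, 1\].
#' @param seed Integer seed (same arguments, same plan, bitwise).
#' @param n_cp Control points per beam.
#' @param aperture_m,dynamics_m Sub-dials for the aperture and dynamics
#'   channels; both default to `m`.
#' @param max_speed_cm_s Physical maximum leaf speed.
#' @param id Plan label.
#' @return An [rt_plan()].
#' @export
generate_plan <- function(site, m, seed, n_cp = 60,
                          aperture_m = m, dynamics_m = m,
                          max_speed_cm_s = 2.5, id = NULL) {
  stopifnot(m >= 0, m <= 1)
  site <- match.arg(site, PLAN_SITES)
  if (is.null(id)) id <- sprintf("%s_m%03.0f_s%d", site, 100 * m, seed)
  for (attempt in 1:5) {
    plan <- try(with_seed(plan_seed(seed, attempt), generate_plan_once(
      site, id, n_cp, aperture_m, dynamics_m, max_speed_cm_s)),
      silent = TRUE)
    if (!inherits(plan, "try-error")) return(plan)
  }
  stop("generate_plan: could not generate a feasible plan for site '",
       site, "' after 5 attempts: ", attr(plan, "condition")$message)
}

generate_plan_once <- function(site, id, n_cp, aperture_m, dynamics_m,
                               max_speed_cm_s) {
  prof <- site_profile(site)
  n_beams <- max(2L, prof$n_beams + sample(-1:1, 1))
  bd <- millennium_boundaries()
  m_overall <- (aperture_m + dynamics_m) / 2
  dose <- runif(1, prof$dose[1], prof$dose[2])
  beams <- lapply(seq_len(n_beams), function(bi) {
    wx <- runif(1, prof$wx[1], prof$wx[2])
    wy <- runif(1, prof$wy[1], prof$wy[2])
    x0 <- -wx / 2
    mu <- runif(1, prof$mu[1], prof$mu[2]) * (1 + 0.6 * m_overall)
    cmf <- seq(0, 1, length.out = n_cp)
    dt <- (mu / 400 * 60) / (n_cp - 1)           # s per interval
    step_cap <- max_speed_cm_s * 10 * dt         # mm per interval at cap
    active <- which(bd[-length(bd)] < wy / 2 & bd[-1] > -wy / 2)
    np <- length(bd) - 1L
    bank_a <- matrix(x0, n_cp, np)
    bank_b <- matrix(x0, n_cp, np)
    g_mean <- 36 - aperture_m * 32                # mm: 36 down to 4
    for (p in active) {
      # trailing bank: normalised positive increments with speed-capped
      # modulation growing with the dynamics dial
      eta <- as.vector(stats::filter(rnorm(n_cp - 1), 0.5, "recursive"))
      db <- pmax(0, (wx / (n_cp - 1)) * (1 + 2.2 * dynamics_m * eta))
      # normalise the sweep to the field width, then re-clip so that the
      # trailing-bank and gap increments together stay under the speed cap
      db <- pmin(db * wx / sum(db), 0.55 * step_cap)
      b <- x0 + cumsum(db)
      # smooth strictly-positive gap process (log-normal modulation): the
      # mean shrinks and the spread grows with the aperture dial, without
      # hard clamps that would inject spurious speed variation
      xi <- as.vector(stats::filter(rnorm(n_cp), 0.7, "recursive")) * 0.7
      g <- 1.5 + (g_mean - 1.5) * exp(0.6 * aperture_m * (xi - 0.3))
      dg <- pmin(pmax(diff(g), -0.4 * step_cap), 0.4 * step_cap)
      g <- pmax(cumsum(c(g[1], dg)), 0)  # rate-limited; floor is rare
      b_full <- c(x0, b)
      a_full <- cummax(b_full + g)  # leading bank: monotone, never below b
      bank_b[, p] <- b_full
      bank_a[, p] <- a_full
    }
    jaw_x <- c(x0 - 10, wx / 2 + 10)
    ylo <- bd[min(active)]; yhi <- bd[max(active) + 1L]
    beam <- rt_beam(id = sprintf("B%d", bi), meterset = mu,
                    dose_rate = 400, leaf_boundaries = bd, cmf = cmf,
                    bank_a = bank_a, bank_b = bank_b,
                    jaw_x = jaw_x, jaw_y = c(ylo, yhi))
    k <- derive_kinematics(beam)
    if (max(k$speeds) > max_speed_cm_s)
      stop("leaf speed above the physical cap")
    beam
  })
  rt_plan(id = id, site = site, prescribed_dose = dose, beams = beams)
}

# --- toy dose engine ---------------------------------------------------

gaussian_blur_matrix <- function(coords, sigma) {
  if (sigma <= 0) return(diag(length(coords)))
  k <- outer(coords, coords, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  sweep(k, 1, rowSums(k), "/")
}

# Interval-resolved (midpoint) bank/jaw matrices of a beam; the fluence of
# an interval uses the mean of its bounding control points.
interval_banks <- function(beam) {
  n <- length(beam$cmf)
  mid <- function(m) (m[-n, , drop = FALSE] + m[-1, , drop = FALSE]) / 2
  list(bank_a = mid(beam$bank_a), bank_b = mid(beam$bank_b),
       jaw_x = mid(beam$jaw_x), jaw_y = mid(beam$jaw_y),
       interval_mu = diff(beam$cmf) * beam$meterset)
}

#' Toy planned dose of a plan
#'
#' Accumulates per-interval aperture fluence (open-aperture indicator times
#' interval MU) on the grid, convolves with an isotropic Gaussian penumbra
#' kernel in the beam's-eye plane, applies a gentle exponential depth
#' profile along the beam axis (z), stacks beams with equal weight and
#' scales the result to the prescribed dose at the grid centre.
#' Deterministic given the plan.
#'
#' @param plan An [rt_plan()].
#' @param spacing_mm Grid spacing (2.5 mm default).
#' @param half_extent_mm Half side length of the cubic grid.
#' @param penumbra_sigma_mm Gaussian penumbra sigma.
#' @param depth_mu_per_mm Linear attenuation of the depth profile.
#' @param perturb Optional function applied to each beam's
#'   interval-resolved banks before rasterisation (used by the measurement
#'   surrogate to inject delivery errors).
#' @return A [dose_grid()].
#' @export
toy_dose <- function(plan, spacing_mm = 2.5, half_extent_mm = 115,
                     penumbra_sigma_mm = 3, depth_mu_per_mm = 0.004,
                     perturb = NULL) {
  ax <- seq(-half_extent_mm, half_extent_mm, by = spacing_mm)
  n <- length(ax)
  flu <- matrix(0, n, n)
  for (beam in plan$beams) {
    ib <- interval_banks(beam)
    if (!is.null(perturb)) ib <- perturb(beam, ib)
    flu <- flu + fluence_accumulate(
      ib$bank_a, ib$bank_b, ib$jaw_x, ib$jaw_y, beam$leaf_boundaries,
      ib$interval_mu, ax[1], spacing_mm, n, ax[1], spacing_mm, n,
      CLOSED_GAP_TOL)
  }
  bm <- gaussian_blur_matrix(ax, penumbra_sigma_mm)
  flu <- bm %*% flu %*% t(bm)
  depth <- exp(-depth_mu_per_mm * (ax + half_extent_mm))
  vals <- array(0, dim = c(n, n, n))
  for (iz in seq_len(n)) vals[, , iz] <- flu * depth[iz]
  centre <- (n + 1) / 2
  ref <- vals[ceiling(centre), ceiling(centre), ceiling(centre)]
  if (ref <= 0) ref <- max(vals)
  if (ref <= 0) ref <- 1
  dose_grid(origin = rep(ax[1], 3), spacing = rep(spacing_mm, 3),
            values = vals * plan$prescribed_dose / ref)
}

#' Calculation-based QA surrogate dose
#'
#' Re-renders the planned dose through an algorithm-mismatch channel: the
#' planned grid is blurred in the beam's-eye plane by an extra Gaussian
#' width proportional to the plan's small-aperture fraction (SAS_5) and
#' scaled by a gap-dependent output offset. A plan with no small-aperture
#' content is returned unchanged. Deterministic.
#'
#' @param plan An [rt_plan()].
#' @param planned Its [toy_dose()] grid.
#' @param blur_mm_per_sas Extra sigma (mm) per unit SAS_5.
#' @param output_per_sas Fractional output offset per unit SAS_5.
#' @param sas5 The plan's SAS_5; computed from the plan when omitted.
#' @param pcm A [pcm_config()] for the SAS_5 computation.
#' @return A [dose_grid()].
#' @export
cqa_surrogate <- function(plan, planned, blur_mm_per_sas = 6,
                          output_per_sas = 0.04, sas5 = NULL,
                          pcm = pcm_config()) {
  if (is.null(sas5)) sas5 <- small_aperture_metrics(plan, pcm)$SAS_5
  if (is.na(sas5)) sas5 <- 0
  sigma <- blur_mm_per_sas * sas5
  scale <- 1 - output_per_sas * sas5
  if (sigma <= 0 && scale == 1) return(planned)
  v <- planned$values
  if (sigma > 0) {
    bm <- gaussian_blur_matrix(grid_axis(planned, 1), sigma)
    for (iz in seq_len(dim(v)[3])) v[, , iz] <- bm %*% v[, , iz] %*% t(bm)
  }
  dose_grid(planned$origin, planned$spacing, v * scale)
}

#' Measurement-based QA surrogate readings
#'
#' Re-renders the dose through a delivery-error channel driven by leaf
#' speed variation — the mechanism by which abrupt speed changes between
#' control points stress both the MLC servo and the output servo:
#'
#' * leaf positions are perturbed per delivery interval by a systematic
#'   gap-widening offset plus zero-mean noise whose sigma is proportional
#'   to the leaf's speed change into that interval;
#' * each beam's output wanders by a zero-mean factor whose sigma is
#'   proportional to the beam's MU-weighted mean absolute speed change
#'   (fast-varying leaf patterns give the dose servo less time to settle).
#'
#' The perturbed delivery is sampled at the detector layout and i.i.d.
#' relative detector noise is added. Stochastic, seeded.
#'
#' @param plan An [rt_plan()].
#' @param layout A [build_layout()] result (or list of layouts; readings
#'   are then returned per layout from the one perturbed delivery).
#' @param seed Integer seed.
#' @param jitter_mm_per_speed_change Positional sigma (mm) per cm/s of
#'   interval-to-interval leaf speed change.
#' @param output_per_speed_change Per-beam output sigma (fraction) per
#'   cm/s of MU-weighted mean absolute speed change.
#' @param systematic_offset_mm Gap-widening systematic offset (mm).
#' @param detector_noise_percent Relative detector noise (percent).
#' @param dose Toy dose-engine settings (must match the planned grid's).
#' @return Numeric vector of readings (Gy), or a list of such vectors when
#'   `layout` is a list.
#' @export
mqa_surrogate <- function(plan, layout, seed,
                          jitter_mm_per_speed_change = 0.5,
                          output_per_speed_change = 0.15,
                          systematic_offset_mm = 0.05,
                          detector_noise_percent = 0.5,
                          dose = list(spacing_mm = 2.5,
                                      half_extent_mm = 115,
                                      penumbra_sigma_mm = 3,
                                      depth_mu_per_mm = 0.004)) {
  layouts <- if (inherits(layout, "detector_layout")) list(layout) else layout
  with_seed(seed, {
    perturb <- function(beam, ib) {
      n_int <- nrow(ib$bank_a)
      dt <- diff(beam$cmf) * beam$meterset / beam$dose_rate * 60
      speed_change <- function(bank) {  # cm/s per interval, first = 0
        s <- abs(rbind(bank[1, ], diff(bank))) / 10 / dt
        s[1, ] <- 0
        abs(rbind(s[1, ], diff(s)))
      }
      dva <- speed_change(ib$bank_a)
      dvb <- speed_change(ib$bank_b)
      a <- ib$bank_a + systematic_offset_mm / 2 +
        matrix(rnorm(length(dva), sd = jitter_mm_per_speed_change * dva),
               n_int, ncol(dva))
      b <- ib$bank_b - systematic_offset_mm / 2 +
        matrix(rnorm(length(dvb), sd = jitter_mm_per_speed_change * dvb),
               n_int, ncol(dvb))
      swap <- b > a
      if (any(swap)) { m <- (a[swap] + b[swap]) / 2; a[swap] <- m; b[swap] <- m }
      ib$bank_a <- a; ib$bank_b <- b
      # per-beam output wander scaled by the beam's speed-variation level
      k <- derive_kinematics(beam)
      mv <- k$speeds > MOVING_SPEED_TOL
      n_i <- ncol(k$speeds)
      adj <- mv[, -n_i, drop = FALSE] | mv[, -1, drop = FALSE]
      dsp <- abs(k$speeds[, -1, drop = FALSE] -
                   k$speeds[, -n_i, drop = FALSE])
      V <- if (any(adj)) mean(dsp[adj]) else 0
      ib$interval_mu <- ib$interval_mu *
        max(0, 1 + rnorm(1, sd = output_per_speed_change * V))
      ib
    }
    delivered <- toy_dose(plan, dose$spacing_mm, dose$half_extent_mm,
                          dose$penumbra_sigma_mm, dose$depth_mu_per_mm,
                          perturb = perturb)
    out <- lapply(layouts, function(ly) {
      r <- sample_dose(delivered, ly)
      r * (1 + rnorm(length(r), sd = detector_noise_percent / 100))
    })
    if (inherits(layout, "detector_layout")) out[[1]] else out
  })
}

# --- full study --------------------------------------------------------

#' Simulate the full synthetic QA study
#'
#' Generates the site-stratified cohort on two linacs, computes every
#' plan's complexity-metric vector, renders planned doses, runs both
#' surrogate QA channels and the gamma analysis at all criteria, and
#' returns the long-format GPR table plus the metric table. Linac #1 plans
#' are evaluated by four systems (the calculation surrogate on the helical
#' and cross phantom geometries, and the two measurement arrays); linac #2
#' plans by two (the collapsed-cone-like calculation surrogate and the
#' oblique cross array).
#'
#' @param cfg A [cohort_config()].
#' @param progress Print a line every 50 plans.
#' @return An object of class `qa_cohort`: `gpr` (long table), `pcm` (wide
#'   metric table with `plan_id`, `site`, `linac`), `systems` (system
#'   metadata), `registry` (metric metadata), `config`.
#' @export
simulate_study <- function(cfg = cohort_config(), progress = FALSE) {
  registry <- pcm_registry()
  layouts <- list(helical = build_layout("helical"),
                  cross = build_layout("cross"),
                  oblique_cross = build_layout("oblique_cross"))
  meta <- cohort_plan_meta(cfg)
  results <- list()
  pcm_rows <- list()
  for (i in seq_len(nrow(meta))) {
    pm <- meta[i, ]
    plan <- generate_plan(pm$site, pm$m, seed = plan_seed(cfg$seed, i),
                          n_cp = cfg$n_cp, aperture_m = pm$aperture_m,
                          dynamics_m = pm$dynamics_m, id = pm$plan_id)
    vec <- compute_pcm_vector(plan, registry, cfg$pcm)
    pcm_rows[[i]] <- vec$values
    planned <- toy_dose(plan, cfg$dose$spacing_mm, cfg$dose$half_extent_mm,
                        cfg$dose$penumbra_sigma_mm, cfg$dose$depth_mu_per_mm)
    sas5 <- vec$values[["SAS_5"]]
    ccc <- pm$linac == 2
    calc <- cqa_surrogate(
      plan, planned,
      blur_mm_per_sas = cfg$noise$calc_blur_mm_per_small_aperture *
        (if (ccc) cfg$noise$ccc_scale else 1),
      output_per_sas = cfg$noise$calc_output_per_small_aperture *
        (if (ccc) cfg$noise$ccc_scale else 1),
      sas5 = sas5)
    mqa_layouts <- if (ccc) layouts["oblique_cross"] else
      layouts[c("helical", "cross")]
    readings <- mqa_surrogate(
      plan, mqa_layouts, seed = plan_seed(cfg$seed + 1L, i),
      jitter_mm_per_speed_change = cfg$noise$jitter_mm_per_speed_change,
      output_per_speed_change = cfg$noise$output_per_speed_change,
      systematic_offset_mm = cfg$noise$systematic_offset_mm,
      detector_noise_percent = cfg$noise$detector_noise_percent,
      dose = cfg$dose)
    ga <- function(ref_pos, ref_dose, ev) gamma_analysis(
      ref_pos, ref_dose, ev, criteria = cfg$criteria,
      threshold_percent = cfg$gamma$threshold_percent,
      search_factor = cfg$gamma$search_factor,
      step_frac = cfg$gamma$step_frac, gamma_cap = cfg$gamma$cap)
    sys <- list()
    if (!ccc) {
      p_hel <- sample_dose(planned, layouts$helical)
      p_cro <- sample_dose(planned, layouts$cross)
      sys[["MC_helical"]] <- ga(layouts$helical$points, p_hel, calc)
      sys[["MC_cross"]] <- ga(layouts$cross$points, p_cro, calc)
      sys[["helical"]] <- ga(layouts$helical$points, readings$helical,
                             planned)
      sys[["cross"]] <- ga(layouts$cross$points, readings$cross, planned)
    } else {
      p_obl <- sample_dose(planned, layouts$oblique_cross)
      sys[["CCC"]] <- ga(layouts$oblique_cross$points, p_obl, calc)
      sys[["oblique_cross"]] <- ga(layouts$oblique_cross$points,
                                   readings$oblique_cross, planned)
    }
    results[[pm$plan_id]] <- sys
    if (progress && i %% 50 == 0)
      message(sprintf("simulate_study: %d/%d plans", i, nrow(meta)))
  }
  gpr <- gpr_table(results, meta, cfg$criteria)
  pcm <- cbind(meta[, c("plan_id", "site", "linac")],
               as.data.frame(do.call(rbind, pcm_rows)))
  structure(list(
    gpr = gpr, pcm = pcm,
    systems = data.frame(
      system = c("MC_helical", "MC_cross", "helical", "cross", "CCC",
                 "oblique_cross"),
      type = c("CQA", "CQA", "MQA", "MQA", "CQA", "MQA"),
      linac = c(1, 1, 1, 1, 2, 2), stringsAsFactors = FALSE),
    registry = data.frame(
      metric = names(registry),
      category = vapply(registry, function(x) x$category, character(1)),
      orientation = vapply(registry, function(x) x$orientation, numeric(1)),
      fallback = vapply(registry, function(x) x$fallback, logical(1)),
      stringsAsFactors = FALSE, row.names = NULL),
    config = cfg), class = "qa_cohort")
}

# Per-plan metadata of the cohort: ids, sites, linacs and the complexity
# dials (common dial plus loosely coupled aperture/dynamics sub-dials).
cohort_plan_meta <- function(cfg) {
  counts <- rbind(
    data.frame(site = names(cfg$n_per_site_linac1),
               n = as.integer(cfg$n_per_site_linac1), linac = 1),
    data.frame(site = names(cfg$n_per_site_linac2),
               n = as.integer(cfg$n_per_site_linac2), linac = 2))
  site <- rep(counts$site, counts$n)
  linac <- rep(counts$linac, counts$n)
  n <- length(site)
  with_seed(cfg$seed, {
    m <- runif(n, cfg$complexity_dial_range[1], cfg$complexity_dial_range[2])
    data.frame(
      plan_id = sprintf("P%04d", seq_len(n)), site = site, linac = linac,
      m = m,
      aperture_m = clip01(m + rnorm(n, sd = cfg$decouple_sd)),
      dynamics_m = clip01(m + rnorm(n, sd = cfg$decouple_sd)),
      stringsAsFactors = FALSE)
  })
}

#' @export
print.qa_cohort <- function(x, ...) {
  cat(sprintf("<qa_cohort> %d plans, %d GPR records, %d metrics\n",
              nrow(x$pcm), nrow(x$gpr), nrow(x$registry)))
  invisible(x)
}
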