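test_that("MCS is 1 for a static open field and matches hand computation", {
  expect_equal(mcs(static_open_plan()), 1, tolerance = 1e-12)

  # two equal-MU control points, full aperture then half-width aperture
  # with zero leaf-position spread: LSV = 1 at both; AAV = 1 and 0.5;
  # MCS = mean(AAV) * mean(LSV) = 0.75
  n_pairs <- 10
  bd <- seq(-25, 25, by = 5)
  bank_a <- rbind(rep(25, n_pairs), rep(12.5, n_pairs))
  bank_b <- rbind(rep(-25, n_pairs), rep(-12.5, n_pairs))
  beam <- rt_beam("b", 100, 400, bd, c(0, 1), bank_a, bank_b,
                  jaw_x = c(-30, 30), jaw_y = c(-25, 25))
  expect_equal(mcs(beam), 0.75, tolerance = 1e-12)
})

test_that("MCS lies in (0, 1] on generated plans", {
  for (seed in c(2, 9)) {
    p <- generate_plan("pelvis", runif(1), seed = seed, n_cp = 25)
    v <- mcs(p)
    expect_gt(v, 0)
    expect_lte(v, 1)
  }
})

test_that("modulation indices vanish for static and constant-speed beams", {
  cfg <- pcm_config()
  expect_equal(mi_speed(derive_kinematics(static_open_plan()$beams[[1]]),
                        cfg), 0)
  # constant speed: all variations zero
  k <- derive_kinematics(single_leaf_beam(travel_mm = 30, n_cp = 6))
  expect_equal(mi_speed(k, cfg), 0)
  expect_equal(mi_accel(k, cfg), 0)
})

test_that("MI equals a direct-count oracle on a bimodal variation pattern", {
  # one leaf alternating speeds so that speed changes are 0.1 and 0.5 cm/s
  n_cp <- 13
  mu <- 100; dt <- (mu / 400 * 60) / (n_cp - 1)
  speeds <- rep(c(0.3, 0.4, 0.3, 0.8), length.out = n_cp - 1)  # cm/s
  pos <- cumsum(c(0, speeds * 10 * dt))
  beam <- rt_beam("b", mu, 400, c(-5, 5),
                  cmf = seq(0, 1, length.out = n_cp),
                  bank_a = cbind(pos), bank_b = cbind(pos - 60),
                  jaw_x = c(-80, 160), jaw_y = c(-5, 5))
  k <- derive_kinematics(beam)
  cfg <- pcm_config(f_grid = seq(0, 1, length.out = 501), mi_weight_c = 1)
  got <- mi_speed(k, cfg)

  # oracle: explicit counting at every f node (both leaves of the pair)
  moving <- k$speeds > 1e-4
  sigma <- sd(k$speeds[moving])
  adj <- moving[, -ncol(k$speeds)] | moving[, -1]
  v <- abs(k$speeds[, -1] - k$speeds[, -ncol(k$speeds)])[adj]
  w <- 1 + v / sigma
  z <- vapply(cfg$f_grid, function(f) sum(w[v > f * sigma]) / sum(w),
              numeric(1))
  oracle <- sum((z[-1] + z[-length(z)]) / 2 * diff(cfg$f_grid))
  expect_gt(got, 0)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("unweighted MI_a is invariant under acceleration scaling", {
  p <- generate_plan("pelvis", 0.7, seed = 12, n_cp = 30)
  k <- derive_kinematics(p$beams[[1]])
  cfg <- pcm_config(mi_weight_c = 0)
  base <- mi_accel(k, cfg)
  # scaling all accelerations by c > 0: halve the dose rate (speeds halve,
  # dt doubles -> accelerations scale by 1/4; sigma scales identically)
  b2 <- p$beams[[1]]; b2$dose_rate <- b2$dose_rate / 2
  expect_equal(mi_accel(derive_kinematics(b2), cfg), base,
               tolerance = 1e-9)
})

test_that("small-aperture metrics match closed forms", {
  # 100 x 100 mm open field, 5 mm margin: EAM = 1 - 90^2/100^2 = 0.19
  p <- static_open_plan(width_mm = 100, n_pairs = 10, pair_mm = 10)
  sam <- small_aperture_metrics(p)
  expect_equal(sam$EAM, 0.19, tolerance = 1e-9)
  expect_equal(sam$MFA, 100)
  expect_equal(sam$SAS_5, 0)
  expect_equal(sam$SAS_20, 0)

  # all gaps 3 mm -> SAS_5 = 1
  bd <- seq(-25, 25, by = 5)
  beam <- rt_beam("b", 100, 400, bd, c(0, 1),
                  bank_a = matrix(3, 2, 10), bank_b = matrix(0, 2, 10),
                  jaw_x = c(-10, 10), jaw_y = c(-25, 25))
  p2 <- rt_plan("p", "pelvis", 50, list(beam))
  expect_equal(small_aperture_metrics(p2)$SAS_5, 1)
})

test_that("EAM on a random staircase matches a fine-raster oracle", {
  set.seed(14)
  bd <- seq(0, 30, by = 5)  # 6 pairs
  b <- runif(6, -10, 0); a <- b + runif(6, 6, 25)
  beam <- rt_beam("b", 100, 400, bd, c(0, 1),
                  bank_a = rbind(a, a), bank_b = rbind(b, b),
                  jaw_x = c(-15, 30), jaw_y = c(0, 30))
  p <- rt_plan("p", "pelvis", 50, list(beam))
  got <- small_aperture_metrics(p, pcm_config(raster_res_mm = 0.5))$EAM

  # oracle at 0.25 mm: direct minimum distance from open cells to closed
  res <- 0.25; margin <- 5
  xs <- seq(min(b) - 2, max(a) + 2, by = res)
  ys <- seq(-2, 32, by = res)
  cx <- rep(xs, times = length(ys)); cy <- rep(ys, each = length(xs))
  pair <- findInterval(cy, bd)
  open <- pair >= 1 & pair <= 6 & cy > 0 & cy < 30
  open[open] <- cx[open] > b[pair[open]] & cx[open] < a[pair[open]]
  op <- cbind(cx[open], cy[open]); cl <- cbind(cx[!open], cy[!open])
  near <- vapply(seq_len(nrow(op)), function(i)
    sqrt(min((cl[, 1] - op[i, 1])^2 + (cl[, 2] - op[i, 2])^2)) - res / 2,
    numeric(1))
  oracle <- mean(near < margin)
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("MU metrics match their stated formulas", {
  p <- static_open_plan(mu = 600, dose = 2)
  m <- mu_metrics(p)
  expect_equal(m$MU, 600)
  expect_equal(m$MU_per_Gy, 300)
  expect_equal(m$PM, 0)           # single aperture: A_cp = A_union
  # square field: BI = P^2/(4 pi A) = 4/pi
  expect_equal(m$BI, 4 / pi, tolerance = 1e-12)

  # MLC-rasterised disc: the staircase perimeter of a disc tends to the
  # Manhattan length 8r, so BI tends to (8r)^2/(4 pi * pi r^2) = 16/pi^2
  # (axis-aligned apertures cannot reach the smooth isoperimetric limit 1)
  bd <- seq(-50, 50, by = 2)
  r <- 40
  yc <- (bd[-1] + bd[-51]) / 2
  half <- ifelse(abs(yc) < r, sqrt(pmax(r^2 - yc^2, 0)), 0)
  beam <- rt_beam("b", 100, 400, bd, c(0, 1),
                  bank_a = rbind(half, half), bank_b = rbind(-half, -half),
                  jaw_x = c(-60, 60), jaw_y = c(-50, 50))
  disc <- rt_plan("p", "pelvis", 50, list(beam))
  bi <- mu_metrics(disc)$BI
  expect_lt(abs(bi - 16 / pi^2), 0.05)
  expect_gt(bi, 1)  # isoperimetric bound
})

test_that("the PCM vector covers the registry and is deterministic", {
  reg <- pcm_registry()
  expect_length(reg, 53)
  expect_setequal(unique(vapply(reg, function(e) e$category, character(1))),
                  c("aperture", "mu", "dynamics"))

  p <- generate_plan("chest_and_abdomen", 0.4, seed = 77, n_cp = 25)
  v1 <- compute_pcm_vector(p)
  v2 <- compute_pcm_vector(p)
  expect_length(v1$values, 53)
  expect_identical(v1$values, v2$values)   # bitwise
  expect_length(v1$unavailable, 0)

  # simplest plan: closed forms across families
  vs <- compute_pcm_vector(static_open_plan())
  expect_equal(unname(vs$values["MCS"]), 1)
  expect_equal(unname(vs$values["LT"]), 0)
  expect_equal(unname(vs$values["MI_s"]), 0)
  expect_equal(unname(vs$values["SAS_5"]), 0)
  expect_equal(unname(vs$values["PM"]), 0)
})

test_that("MU-weighted aggregation is stable under weight splitting", {
  # splitting one entry's weight across two identical values must not
  # change any weighted aggregate
  set.seed(10)
  v <- runif(20); w <- runif(20)
  base <- complexiqa:::weighted_mean_kept(v, w)
  v2 <- c(v, v[7]); w2 <- w; w2[7] <- w[7] / 2; w2 <- c(w2, w[7] / 2)
  expect_equal(complexiqa:::weighted_mean_kept(v2, w2), base,
               tolerance = 1e-9)
})

test_that("metrics respond monotonically to constructed plan changes", {
  p <- generate_plan("pelvis", 0.5, seed = 19, n_cp = 25)
  v <- compute_pcm_vector(p)$values
  # shrink every gap by half (leading bank pulled toward the trailing)
  p2 <- p
  p2$beams <- lapply(p$beams, function(b) {
    b$bank_a <- b$bank_b + (b$bank_a - b$bank_b) / 2
    b
  })
  v2 <- compute_pcm_vector(p2)$values
  expect_gt(v2[["SAS_5"]], v[["SAS_5"]])
  expect_gt(v2[["EAM"]], v[["EAM"]])
  expect_gt(v2[["CAM"]], v[["CAM"]])
  expect_lt(v2[["MFA"]], v[["MFA"]])

  # time reversal leaves every metric unchanged
  pr <- p
  pr$beams <- lapply(p$beams, reverse_beam)
  vr <- compute_pcm_vector(pr)$values
  # the reversed cmf axis is only float-identical to ~1e-7 in the
  # modulation-index integrals
  expect_equal(vr, v, tolerance = 1e-6)
})

test_that("declared orientations match a synthetic complexity gradient", {
  n <- 60
  m <- seq(0.02, 0.98, length.out = n)
  vals <- vapply(seq_len(n), function(i)
    compute_pcm_vector(generate_plan("pelvis", m[i], seed = 5000 + i,
                                     n_cp = 25))$values,
    numeric(53))
  reg <- pcm_registry()
  checked <- 0
  for (e in reg) {
    if (e$orientation == 0) next
    v <- vals[e$name, ]
    if (sd(v) == 0) next
    rho <- cor(m, v, method = "spearman")
    if (abs(rho) > 0.15) {
      expect_equal(sign(rho), e$orientation,
                   info = paste("metric", e$name, "rho", round(rho, 2)))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 25)
})
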