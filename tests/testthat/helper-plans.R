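# Plan builders and independent oracles used across the suite.

# A static fully open rectangular field delivered over n_cp identical
# control points: width_mm across leaf travel, n_pairs pairs of
# pair_mm height.
static_open_plan <- function(width_mm = 100, n_pairs = 10, pair_mm = 10,
                             mu = 600, dose = 2, n_cp = 2) {
  bd <- (0:n_pairs - n_pairs / 2) * pair_mm
  beam <- rt_beam(
    id = "open", meterset = mu, dose_rate = 400, leaf_boundaries = bd,
    cmf = seq(0, 1, length.out = n_cp),
    bank_a = matrix(width_mm / 2, n_cp, n_pairs),
    bank_b = matrix(-width_mm / 2, n_cp, n_pairs),
    jaw_x = c(-width_mm / 2 - 5, width_mm / 2 + 5),
    jaw_y = c(min(bd), max(bd)))
  rt_plan("static_open", "pelvis", dose, list(beam))
}

# Single-leaf sweep: 2 control points, one leaf pair moving `travel_mm`.
single_leaf_beam <- function(travel_mm = 30, mu = 100, dose_rate = 400,
                             n_cp = 2) {
  n_pairs <- 3
  bd <- c(-15, -5, 5, 15)
  bank_a <- matrix(10, n_cp, n_pairs)
  bank_b <- matrix(-10, n_cp, n_pairs)
  # pair 2 leading edge sweeps
  bank_a[, 2] <- seq(0, travel_mm, length.out = n_cp)
  bank_b[, 2] <- bank_a[, 2] - 10
  rt_beam(id = "sweep", meterset = mu, dose_rate = dose_rate,
          leaf_boundaries = bd, cmf = seq(0, 1, length.out = n_cp),
          bank_a = bank_a, bank_b = bank_b,
          jaw_x = c(-60, 60), jaw_y = c(-15, 15))
}

# Small random but valid plan (for round-trip and property tests);
# independent of the cohort generator.
random_tiny_plan <- function(seed) {
  set.seed(seed)
  n_beams <- sample(1:3, 1)
  beams <- lapply(seq_len(n_beams), function(bi) {
    n_pairs <- sample(4:8, 1)
    n_cp <- sample(4:10, 1)
    bd <- cumsum(c(-20, runif(n_pairs, 3, 8)))
    cmf <- sort(runif(n_cp - 2))
    cmf <- c(0, cmf[!duplicated(cmf)], 1)
    b <- matrix(runif(length(cmf) * n_pairs, -40, 20), length(cmf), n_pairs)
    a <- b + matrix(runif(length(cmf) * n_pairs, 0, 30), length(cmf),
                    n_pairs)
    rt_beam(id = sprintf("B%d", bi), meterset = runif(1, 40, 200),
            dose_rate = sample(c(300, 400, 600), 1),
            leaf_boundaries = bd, cmf = cmf, bank_a = a, bank_b = b,
            jaw_x = c(-45, 30), jaw_y = range(bd))
  })
  rt_plan(sprintf("tiny_%d", seed),
          sample(c("head_and_neck", "chest_and_abdomen", "pelvis",
                   "limbs"), 1),
          runif(1, 20, 70), beams)
}

# Boolean plan comparison for high-volume property loops (one testthat
# expectation per loop, not per field).
plans_equal <- function(p1, p2, tol = 1e-9) {
  near <- function(a, b) max(abs(a - b)) <= tol
  if (!identical(p1$id, p2$id) || !identical(p1$site, p2$site)) return(FALSE)
  if (!near(p1$prescribed_dose, p2$prescribed_dose)) return(FALSE)
  if (length(p1$beams) != length(p2$beams)) return(FALSE)
  for (i in seq_along(p1$beams)) {
    b1 <- p1$beams[[i]]; b2 <- p2$beams[[i]]
    if (!identical(b1$id, b2$id)) return(FALSE)
    for (f in c("meterset", "dose_rate", "leaf_boundaries", "cmf",
                "bank_a", "bank_b", "jaw_x", "jaw_y"))
      if (!near(b1[[f]], b2[[f]])) return(FALSE)
  }
  TRUE
}

expect_plan_equal <- function(p1, p2, tol = 1e-9) {
  expect_identical(p1$id, p2$id)
  expect_identical(p1$site, p2$site)
  expect_equal(p1$prescribed_dose, p2$prescribed_dose, tolerance = tol)
  expect_equal(length(p1$beams), length(p2$beams))
  for (i in seq_along(p1$beams)) {
    b1 <- p1$beams[[i]]; b2 <- p2$beams[[i]]
    expect_identical(b1$id, b2$id)
    expect_equal(b1$meterset, b2$meterset, tolerance = tol)
    expect_equal(b1$dose_rate, b2$dose_rate, tolerance = tol)
    expect_equal(b1$leaf_boundaries, b2$leaf_boundaries, tolerance = tol)
    expect_equal(b1$cmf, b2$cmf, tolerance = tol)
    expect_equal(b1$bank_a, b2$bank_a, tolerance = tol)
    expect_equal(b1$bank_b, b2$bank_b, tolerance = tol)
    expect_equal(b1$jaw_x, b2$jaw_x, tolerance = tol)
    expect_equal(b1$jaw_y, b2$jaw_y, tolerance = tol)
  }
}

# Independent trilinear interpolation (explicit corner-weight arithmetic
# in R, vectorised over points).
trilinear_oracle <- function(grid, pts) {
  d <- dim(grid$values)
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  fz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  i0 <- pmin(pmax(floor(fx), 0), max(d[1] - 2, 0))
  j0 <- pmin(pmax(floor(fy), 0), max(d[2] - 2, 0))
  k0 <- pmin(pmax(floor(fz), 0), max(d[3] - 2, 0))
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(i0 + dx, d[1] - 1)
    iy <- pmin(j0 + dy, d[2] - 1)
    iz <- pmin(k0 + dz, d[3] - 1)
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    out <- out + w * grid$values[cbind(ix + 1, iy + 1, iz + 1)]
  }
  out
}

# Exhaustive dense-search gamma oracle for one reference point. Searches
# every offset on a step lattice out to `radius`; any candidate beyond
# radius (gamma_engine + margin) * DTA cannot undercut the engine value by
# more than the margin, so the truncation is exact for the comparison.
gamma_point_oracle <- function(pos, dose_ref, grid, dd_abs, dta,
                               radius, step, cap = 2) {
  d <- dim(grid$values)
  lo <- grid$origin
  hi <- grid$origin + (d - 1) * grid$spacing
  stage <- function(centre, r, st) {
    s <- seq(-r, r, by = st)
    offs <- as.matrix(expand.grid(x = s, y = s, z = s))
    offs <- sweep(offs, 2, centre, "+")
    dist <- sqrt(rowSums(offs^2))
    keep <- dist <= radius
    offs <- offs[keep, , drop = FALSE]
    dist <- dist[keep]
    pts <- sweep(offs, 2, pos, "+")
    inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    pts <- pts[inside, , drop = FALSE]
    offs <- offs[inside, , drop = FALSE]
    dist <- dist[inside]
    de <- trilinear_oracle(grid, pts)
    g <- sqrt((dist / dta)^2 + ((de - dose_ref) / dd_abs)^2)
    list(g = min(g), at = offs[which.min(g), ])
  }
  s1 <- stage(c(0, 0, 0), radius, step)
  s2 <- stage(s1$at, step, step / 10)  # dense pass around the argmin
  min(cap, min(s1$g, s2$g))
}

# Smooth random dose grid for gamma tests.
random_dose_grid <- function(seed, n = c(14, 14, 8), spacing = 2) {
  set.seed(seed)
  v <- array(runif(prod(n)), dim = n)
  k <- function(m) {
    x <- seq_len(m)
    w <- exp(-outer(x, x, "-")^2 / 8)
    sweep(w, 1, rowSums(w), "/")
  }
  for (iz in seq_len(n[3])) v[, , iz] <- k(n[1]) %*% v[, , iz] %*% t(k(n[2]))
  for (ix in seq_len(n[1])) v[ix, , ] <- v[ix, , ] %*% t(k(n[3]))
  v <- 1 + 9 * (v - min(v)) / (max(v) - min(v))
  dose_grid(origin = -(n - 1) / 2 * spacing, spacing = rep(spacing, 3),
            values = v)
}
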