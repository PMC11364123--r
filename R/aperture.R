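# Aperture geometry: per-control-point open segments, exact staircase area
# and perimeter, and vectorised per-beam aperture features feeding the
# complexity-metric registry.

#' Aperture shape at one control point
#'
#' Intersects each leaf pair's open interval with the jaw limits, zeroing
#' pairs outside the Y jaws, and computes the exact area and staircase
#' perimeter of the resulting union of row rectangles. Pairs whose clipped
#' gap falls below the closed-pair tolerance are treated as closed.
#'
#' @param cp A control-point record ([control_point()]), or any list with
#'   `bank_a`, `bank_b`, `jaw_x`, `jaw_y`.
#' @param boundaries Leaf-pair boundaries (mm), length `n_pairs + 1`.
#' @return An object of class `aperture_shape`: `open_segments` data.frame
#'   (`pair`, `lo`, `hi`, `ylo`, `yhi`, `open`), `area` (cm^2),
#'   `perimeter` (cm).
#' @export
aperture_from_cp <- function(cp, boundaries) {
  np <- length(boundaries) - 1L
  lo <- pmax(cp$bank_b, cp$jaw_x[1])
  hi <- pmin(cp$bank_a, cp$jaw_x[2])
  ylo <- pmax(boundaries[-(np + 1L)], cp$jaw_y[1])
  yhi <- pmin(boundaries[-1L], cp$jaw_y[2])
  open <- (hi - lo > CLOSED_GAP_TOL) & (yhi - ylo > CLOSED_GAP_TOL)
  w <- ifelse(open, hi - lo, 0)
  h <- ifelse(open, yhi - ylo, 0)
  structure(
    list(open_segments = data.frame(pair = seq_len(np), lo = lo, hi = hi,
                                    ylo = ylo, yhi = yhi, open = open),
         area = sum(w * h) / 100,
         perimeter = staircase_perimeter(lo, hi, h, open) / 10),
    class = "aperture_shape")
}

# Exact perimeter (mm) of a union of per-row rectangles. Horizontal
# exposure between adjacent rows is |dlo| + |dhi| when both are open and
# their intervals overlap, and the sum of the two widths otherwise (which
# also covers open-vs-closed boundaries and the field top/bottom).
staircase_perimeter <- function(lo, hi, h, open, parts = FALSE) {
  w <- ifelse(open, hi - lo, 0)
  side <- sum(2 * h[open])  # leaf-side edges, parallel to leaf motion
  lo_p <- c(NA, lo); hi_p <- c(NA, hi); w_p <- c(0, w); open_p <- c(FALSE, open)
  lo_n <- c(lo, NA); hi_n <- c(hi, NA); w_n <- c(w, 0); open_n <- c(open, FALSE)
  both <- open_p & open_n
  overlap <- both & (hi_p > lo_n) & (hi_n > lo_p)
  exposure <- ifelse(overlap, abs(lo_p - lo_n) + abs(hi_p - hi_n),
                     w_p + w_n)
  ends <- sum(exposure)  # leaf-end (staircase) edges
  if (parts) c(side = side, ends = ends) else side + ends
}

#' @export
print.aperture_shape <- function(x, ...) {
  cat(sprintf("<aperture_shape> %d open pairs, area %.2f cm^2, perimeter %.2f cm\n",
              sum(x$open_segments$open), x$area, x$perimeter))
  invisible(x)
}

# --- vectorised per-beam aperture features ----------------------------

# Jaw-clipped open widths [n_cp x n_pairs]; closed/blocked pairs get NA.
clipped_openings <- function(beam) {
  np <- length(beam$leaf_boundaries) - 1L
  n_cp <- length(beam$cmf)
  lo <- pmax(beam$bank_b, beam$jaw_x[, 1])
  hi <- pmin(beam$bank_a, beam$jaw_x[, 2])
  ylo <- pmax(matrix(beam$leaf_boundaries[-(np + 1L)], n_cp, np, byrow = TRUE),
              beam$jaw_y[, 1])
  yhi <- pmin(matrix(beam$leaf_boundaries[-1L], n_cp, np, byrow = TRUE),
              beam$jaw_y[, 2])
  open <- (hi - lo > CLOSED_GAP_TOL) & (yhi - ylo > CLOSED_GAP_TOL)
  list(lo = lo, hi = hi, h = ifelse(open, yhi - ylo, 0),
       w = ifelse(open, hi - lo, 0), open = open)
}

# Per-CP aperture quantities for one beam (vectorised over control points).
beam_aperture_features <- function(beam, config = pcm_config()) {
  cl <- clipped_openings(beam)
  n_cp <- length(beam$cmf)
  np <- ncol(cl$w)
  area <- rowSums(cl$w * cl$h) / 100  # cm^2
  pp <- vapply(seq_len(n_cp), function(i)
    staircase_perimeter(cl$lo[i, ], cl$hi[i, ], cl$h[i, ], cl$open[i, ],
                        parts = TRUE) / 10,
    numeric(2))
  perim <- colSums(pp)
  end_edges <- pp["ends", ]
  # gap stats over open pairs
  gaps <- cl$w
  gaps[!cl$open] <- NA
  sas <- vapply(config$sas_gaps_mm, function(x)
    rowMeans(gaps < x, na.rm = TRUE), numeric(n_cp))
  colnames(sas) <- paste0("SAS_", config$sas_gaps_mm)
  sas[is.nan(sas)] <- NA
  # MAD fallback: mean |pair midpoint - aperture x centroid| over open pairs
  mid <- (cl$lo + cl$hi) / 2
  aw <- cl$w * cl$h
  centroid <- rowSums(mid * aw, na.rm = TRUE) / rowSums(aw)
  mad_cp <- rowMeans(abs(mid - centroid) * NA^(!cl$open), na.rm = TRUE) / 10
  mad_cp[is.nan(mad_cp)] <- NA
  # McNiven-style LSV/AAV over pairs open at the CP
  lsv <- vapply(seq_len(n_cp), function(i) {
    op <- cl$open[i, ]
    if (sum(op) < 2L) return(1)
    lsv_bank <- function(pos) {
      pos <- pos[op]
      lam <- max(pos) - min(pos)
      if (lam <= 0) return(1)
      sum(lam - abs(diff(pos))) / ((length(pos) - 1) * lam)
    }
    lsv_bank(beam$bank_a[i, ]) * lsv_bank(beam$bank_b[i, ])
  }, numeric(1))
  ever_open <- apply(cl$open, 2, any)
  max_open <- rep(0, np)
  if (any(ever_open)) {
    hi_max <- apply(ifelse(cl$open, cl$hi, -Inf), 2, max)
    lo_min <- apply(ifelse(cl$open, cl$lo, Inf), 2, min)
    max_open[ever_open] <- (hi_max - lo_min)[ever_open]
  }
  denom <- sum(max_open)
  aav <- if (denom > 0) rowSums(cl$w) / denom else rep(1, n_cp)
  # exact per-row interval union across CPs -> union area (cm^2)
  union_area <- 0
  for (p in which(ever_open)) {
    ii <- which(cl$open[, p])
    iv <- cbind(cl$lo[ii, p], cl$hi[ii, p])
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    tot <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
    if (nrow(iv) > 1) for (r in 2:nrow(iv)) {
      if (iv[r, 1] > cur_hi) { tot <- tot + cur_hi - cur_lo
                               cur_lo <- iv[r, 1]; cur_hi <- iv[r, 2] }
      else cur_hi <- max(cur_hi, iv[r, 2])
    }
    tot <- tot + cur_hi - cur_lo
    union_area <- union_area + tot * max(cl$h[, p]) / 100
  }
  # raster metrics (EAM/CAM) via the C++ kernel
  rs <- beam_raster_stats(beam$bank_a, beam$bank_b, beam$jaw_x, beam$jaw_y,
                          beam$leaf_boundaries, config$raster_res_mm,
                          config$eam_margin_mm, config$cam_kappa_mm,
                          CLOSED_GAP_TOL)
  any_open <- any(cl$open)
  list(area = area, perimeter = perim, end_edges = end_edges,
       gaps = gaps, sas = sas,
       mad = mad_cp, lsv = lsv, aav = aav, union_area = union_area,
       eam = rs[, 1], cam = rs[, 2],
       n_open = rowSums(cl$open), ever_open = ever_open,
       y_extent = if (any_open) diff(range(
         beam$leaf_boundaries[c(which(ever_open),
                                which(ever_open) + 1L)])) / 10 else 0,
       x_range = if (any_open)
         (max(cl$hi[cl$open]) - min(cl$lo[cl$open])) / 10 else 0,
       weights = cp_mu_weights(beam$cmf))
}
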