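# Detector-array geometries. The cylinder axis is the y axis (couch
# direction); beams travel along z in the synthetic study.

#' Build a detector-point layout
#'
#' Three geometries are supported, modelled on the commercial 3-D diode
#' arrays used for measurement-based QA:
#'
#' * `"helical"` — diodes on a cylindrical surface of radius 105 mm and
#'   length 210 mm, 10 mm centre-to-centre spacing along and between rings
#'   (66 diodes per ring, 21 rings; consecutive rings staggered by half a
#'   pitch to follow the helix). With the device dimensions this yields
#'   1386 points.
#' * `"cross"` — two orthogonal 200 x 200 mm planes intersecting along the
#'   cylinder axis, 5 mm detector pitch in the central 60 x 60 mm and
#'   10 mm outside; axis-line duplicates are removed.
#' * `"oblique_cross"` — the cross layout rotated 45 degrees about the
#'   cylinder axis.
#'
#' @param kind One of `"helical"`, `"cross"`, `"oblique_cross"`.
#' @param radius_mm Cylinder radius (helical).
#' @param length_mm Cylinder length (helical).
#' @param pitch_mm Centre-to-centre diode spacing (helical).
#' @param plane_mm Cross-plane side length.
#' @param inner_pitch_mm,outer_pitch_mm Cross pitches inside/outside the
#'   central region.
#' @param inner_mm Side length of the central fine-pitch region.
#' @return An object of class `detector_layout`: `kind`, `points`
#'   (`[n x 3]` mm), `ids`.
#' @export
build_layout <- function(kind = c("helical", "cross", "oblique_cross"),
                         radius_mm = 105, length_mm = 210, pitch_mm = 10,
                         plane_mm = 200, inner_pitch_mm = 5,
                         outer_pitch_mm = 10, inner_mm = 60) {
  kind <- match.arg(kind)
  if (kind == "helical") {
    # ring centres at one pitch spacing across the device length (half a
    # pitch of margin at each end): 21 rings for the default dimensions
    n_rings <- as.integer(round(length_mm / pitch_mm))
    ys <- ((seq_len(n_rings) - 1) - (n_rings - 1) / 2) * pitch_mm
    n_per_ring <- round(2 * pi * radius_mm / pitch_mm)
    pts <- do.call(rbind, lapply(seq_len(n_rings), function(r) {
      # half-pitch azimuthal stagger between consecutive rings (helix-like)
      th <- 2 * pi * (seq_len(n_per_ring) - 1 + (r %% 2) / 2) / n_per_ring
      cbind(radius_mm * sin(th), ys[r], radius_mm * cos(th))
    }))
  } else {
    half <- plane_mm / 2; ih <- inner_mm / 2
    ax <- sort(unique(c(seq(-ih, ih, by = inner_pitch_mm),
                        seq(-half, half, by = outer_pitch_mm))))
    ax <- ax[abs(ax) <= half + 1e-9]
    plane_a <- cbind(rep(ax, each = length(ax)), rep(ax, length(ax)), 0)
    plane_b <- cbind(0, rep(ax, length(ax)), rep(ax, each = length(ax)))
    # drop plane-B points on the shared axis line (x = z = 0)
    plane_b <- plane_b[abs(plane_b[, 3]) > 1e-9, , drop = FALSE]
    pts <- rbind(plane_a, plane_b)
    if (kind == "oblique_cross") {
      c45 <- cos(pi / 4); s45 <- sin(pi / 4)
      pts <- cbind(c45 * pts[, 1] + s45 * pts[, 3], pts[, 2],
                   -s45 * pts[, 1] + c45 * pts[, 3])
    }
  }
  structure(list(kind = kind, points = unname(pts),
                 ids = sprintf("%s_%04d", toupper(substr(kind, 1, 1)),
                               seq_len(nrow(pts)))),
            class = "detector_layout")
}

#' @export
print.detector_layout <- function(x, ...) {
  cat(sprintf("<detector_layout '%s'> %d points\n", x$kind,
              nrow(x$points)))
  invisible(x)
}
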