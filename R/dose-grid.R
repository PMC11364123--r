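# Regular 3-D dose lattices and point sampling.

#' Construct a dose grid
#'
#' @param origin mm coordinates of the centre of the first voxel.
#' @param spacing mm voxel spacing per axis (default 2.5 mm isotropic, the
#'   QA recalculation grid of the study conditions).
#' @param values 3-D array of dose values in Gy, indexed `[x, y, z]`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(origin, spacing = c(2.5, 2.5, 2.5), values) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(origin) == 3, length(spacing) == 3,
            length(dim(values)) == 3)
  if (any(spacing <= 0)) stop("dose_grid: spacing must be > 0")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose_grid: values must be finite and non-negative")
  structure(list(origin = origin, spacing = spacing, values = values),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %dx%dx%d voxels @ %.2gx%.2gx%.2g mm, max %.3f Gy\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    max(x$values)))
  invisible(x)
}

grid_axis <- function(grid, i) {
  grid$origin[i] + grid$spacing[i] * (seq_len(dim(grid$values)[i]) - 1)
}

#' Sample a dose grid at detector points
#'
#' Trilinear interpolation of the calculated grid at the detector
#' positions. Detector readings themselves are never interpolated anywhere
#' in the package — only calculated grids are.
#'
#' @param grid A [dose_grid()].
#' @param layout A [build_layout()] result, or a numeric matrix of `[n x 3]`
#'   mm positions.
#' @return Numeric vector of doses (Gy), one per point.
#' @export
sample_dose <- function(grid, layout) {
  pts <- if (inherits(layout, "detector_layout")) layout$points else
    as.matrix(layout)
  lo <- grid$origin - 1e-9
  hi <- grid$origin + (dim(grid$values) - 1) * grid$spacing + 1e-9
  out_of_bounds <- pts[, 1] < lo[1] | pts[, 1] > hi[1] |
    pts[, 2] < lo[2] | pts[, 2] > hi[2] |
    pts[, 3] < lo[3] | pts[, 3] > hi[3]
  if (any(out_of_bounds)) {
    ids <- if (inherits(layout, "detector_layout"))
      layout$ids[out_of_bounds] else which(out_of_bounds)
    stop("sample_dose: points outside grid bounds: ",
         paste(utils::head(ids, 5), collapse = ", "),
         if (sum(out_of_bounds) > 5) " ...")
  }
  trilinear_cpp(pts, grid$origin, grid$spacing, dim(grid$values),
                as.vector(grid$values))
}

#' Write / read a dose grid as plain CSV
#'
#' Header comment lines record origin, spacing and dimensions; values
#' follow one per line in x-fastest order.
#'
#' @param grid A [dose_grid()].
#' @param path File path.
#' @return `path` (write) or a [dose_grid()] (read).
#' @export
write_dose_csv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(grid$values)
  writeLines(c(
    sprintf("# origin_mm,%s", paste(grid$origin, collapse = ",")),
    sprintf("# spacing_mm,%s", paste(grid$spacing, collapse = ",")),
    sprintf("# dims,%s", paste(d, collapse = ",")),
    "dose_gy"), con)
  writeLines(sprintf("%.9g", as.vector(grid$values)), con)
  invisible(path)
}

#' @rdname write_dose_csv
#' @param path File path.
#' @export
read_dose_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  parse_hdr <- function(line) as.numeric(strsplit(line, ",")[[1]][-1])
  origin <- parse_hdr(hdr[1]); spacing <- parse_hdr(hdr[2])
  d <- as.integer(parse_hdr(hdr[3]))
  v <- scan(path, skip = 4, quiet = TRUE)
  dose_grid(origin, spacing, array(v, dim = d))
}
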