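# JSON plan dialect (schema "1").
#
# {
#   "schema": "1", "id": ..., "site": ..., "prescribed_dose_gy": ...,
#   "beams": [ { "id": ..., "meterset_mu": ..., "dose_rate_mu_min": ...,
#                "leaf_boundaries_mm": [...],
#                "control_points": [ { "cmf": ..., "bank_a_mm": [...],
#                                      "bank_b_mm": [...],
#                                      "jaw_x_mm": [lo, hi],
#                                      "jaw_y_mm": [lo, hi] } ] } ]
# }

json_require <- function(x, field, path) {
  if (is.null(x[[field]]))
    stop("JSON plan: missing field '", paste0(path, field), "'")
  x[[field]]
}

#' Read a plan from the JSON plan dialect
#'
#' Parses and validates a plan written in the package's simple JSON dialect
#' (schema "1", see [write_json_plan()]); every plan-model invariant is
#' enforced and violations report the offending field path.
#'
#' @param path Path to a JSON file.
#' @return An [rt_plan()].
#' @export
read_json_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  plan_from_json_list(doc)
}

plan_from_json_list <- function(doc) {
  schema <- json_require(doc, "schema", "")
  if (!identical(as.character(schema), "1"))
    stop("JSON plan: unsupported schema '", schema, "'")
  id <- json_require(doc, "id", "")
  site <- json_require(doc, "site", "")
  dose <- json_require(doc, "prescribed_dose_gy", "")
  beams_json <- json_require(doc, "beams", "")
  if (!length(beams_json))
    stop("JSON plan: field 'beams' must contain at least one beam")
  beams <- lapply(seq_along(beams_json), function(bi) {
    bj <- beams_json[[bi]]
    bp <- sprintf("beams[%d].", bi)
    cps <- json_require(bj, "control_points", bp)
    if (length(cps) < 2L)
      stop("JSON plan: '", bp, "control_points' needs at least 2 entries")
    cmf <- vapply(seq_along(cps), function(ci)
      as.numeric(json_require(cps[[ci]], "cmf",
                              sprintf("%scontrol_points[%d].", bp, ci))),
      numeric(1))
    get_mat <- function(field) {
      rows <- lapply(seq_along(cps), function(ci)
        as.numeric(unlist(json_require(
          cps[[ci]], field, sprintf("%scontrol_points[%d].", bp, ci)))))
      n <- unique(lengths(rows))
      if (length(n) != 1L)
        stop("JSON plan: '", bp, "control_points' field '", field,
             "' has inconsistent lengths across control points")
      do.call(rbind, rows)
    }
    bank_a <- get_mat("bank_a_mm")
    bank_b <- get_mat("bank_b_mm")
    gap <- bank_a - bank_b
    if (any(gap < -CLOSED_GAP_TOL)) {
      idx <- which(gap < -CLOSED_GAP_TOL, arr.ind = TRUE)[1, ]
      stop("JSON plan: '", bp, sprintf("control_points[%d]", idx[1]),
           "' bank_b_mm exceeds bank_a_mm at leaf pair ", idx[2])
    }
    jaw_x <- get_mat("jaw_x_mm")
    jaw_y <- get_mat("jaw_y_mm")
    dr <- bj[["dose_rate_mu_min"]]
    rt_beam(id = json_require(bj, "id", bp),
            meterset = as.numeric(json_require(bj, "meterset_mu", bp)),
            dose_rate = if (is.null(dr)) 400 else as.numeric(dr),
            leaf_boundaries = as.numeric(unlist(
              json_require(bj, "leaf_boundaries_mm", bp))),
            cmf = cmf, bank_a = bank_a, bank_b = bank_b,
            jaw_x = jaw_x, jaw_y = jaw_y)
  })
  rt_plan(id = id, site = site, prescribed_dose = as.numeric(dose),
          beams = beams)
}

#' Write a plan to the JSON plan dialect
#'
#' The written file round-trips through [read_json_plan()] to the identical
#' plan model (coordinates are serialised at full double precision).
#'
#' @param plan An [rt_plan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_plan <- function(plan, path) {
  doc <- list(
    schema = "1",
    id = plan$id,
    site = plan$site,
    prescribed_dose_gy = plan$prescribed_dose,
    beams = lapply(plan$beams, function(b) {
      list(
        id = b$id,
        meterset_mu = b$meterset,
        dose_rate_mu_min = b$dose_rate,
        leaf_boundaries_mm = b$leaf_boundaries,
        control_points = lapply(seq_along(b$cmf), function(i) {
          list(cmf = b$cmf[i],
               bank_a_mm = unname(b$bank_a[i, ]),
               bank_b_mm = unname(b$bank_b[i, ]),
               jaw_x_mm = unname(b$jaw_x[i, ]),
               jaw_y_mm = unname(b$jaw_y[i, ]))
        }))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
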