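# Global 3-D gamma analysis of reference points against an evaluated dose
# lattice, and assembly of gamma-passing-rate tables.

#' Global gamma analysis at one or more criteria
#'
#' Computes, for every reference point above the dose threshold, the gamma
#' index against the evaluated grid: the minimum over evaluated positions of
#' `sqrt(dist^2/DTA^2 + dose_diff^2/(DD% * D_norm/100)^2)` (global
#' normalisation). The evaluated grid is trilinearly upsampled on a shared
#' candidate lattice with step at most DTA/10 for every criterion; because
#' all criteria share one lattice, passing rates are exactly monotone in
#' criterion leniency on any dose pair. Reference doses (measured or
#' planned) are never interpolated. Gamma values are reported capped at
#' `gamma_cap` (pass/fail at 1 is unaffected).
#'
#' @param reference_pos `[n x 3]` mm positions of reference points.
#' @param reference_dose Gy at the reference points.
#' @param evaluated A [dose_grid()] to compare against.
#' @param criteria Data.frame with `label`, `dd_percent`, `dta_mm`
#'   (default [default_criteria()]).
#' @param threshold_percent Dose threshold: reference points below this
#'   percentage of `d_norm` are excluded from analysis.
#' @param d_norm Global normalisation dose (Gy); default the maximum of the
#'   reference distribution.
#' @param search_factor Search radius in units of DTA.
#' @param step_frac Candidate lattice step as a fraction of the smallest
#'   DTA.
#' @param gamma_cap Cap on reported gamma values; also bounds the search
#'   (the search stops once no candidate can beat the cap), so smaller caps
#'   are faster and leave passing rates unchanged for caps above 1.
#' @param refine Local-refinement subdivision around each criterion's best
#'   candidate (the lattice step is divided by this factor over a
#'   one-step window); 0 disables refinement. Refinement candidates are
#'   shared across criteria, preserving the monotonicity guarantee.
#' @return An object of class `gamma_result`: `criteria`,
#'   `threshold_percent`, `d_norm`, `gamma_values` (`[n x n_criteria]`,
#'   NA for below-threshold points), `gpr` (percent per criterion),
#'   `n_evaluated`.
#' @export
gamma_analysis <- function(reference_pos, reference_dose, evaluated,
                           criteria = default_criteria(),
                           threshold_percent = 10, d_norm = NULL,
                           search_factor = 3, step_frac = 0.1,
                           gamma_cap = 2, refine = 5) {
  reference_pos <- as.matrix(reference_pos)
  stopifnot(ncol(reference_pos) == 3,
            nrow(reference_pos) == length(reference_dose))
  if (is.null(d_norm)) d_norm <- max(reference_dose)
  if (!is.finite(d_norm) || d_norm <= 0)
    stop("gamma_analysis: normalization dose must be > 0")
  keep <- reference_dose >= threshold_percent / 100 * d_norm
  if (!any(keep))
    stop("gamma_analysis: no evaluable points (all below the ",
         threshold_percent, "% dose threshold)")
  dd_abs <- criteria$dd_percent / 100 * d_norm
  stop_radius <- pmin(search_factor, gamma_cap) * criteria$dta_mm
  step <- step_frac * min(criteria$dta_mm)
  g <- gamma_points_cpp(reference_pos[keep, , drop = FALSE],
                        reference_dose[keep],
                        evaluated$origin, evaluated$spacing,
                        dim(evaluated$values), as.vector(evaluated$values),
                        dd_abs, criteria$dta_mm, stop_radius, step,
                        gamma_cap, as.integer(refine))
  gamma_values <- matrix(NA_real_, nrow(reference_pos), nrow(criteria),
                         dimnames = list(NULL, criteria$label))
  gamma_values[keep, ] <- g
  structure(
    list(criteria = criteria, threshold_percent = threshold_percent,
         d_norm = d_norm, gamma_values = gamma_values,
         gpr = stats::setNames(100 * colMeans(g <= 1), criteria$label),
         n_evaluated = sum(keep)),
    class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %d points evaluated (threshold %.0f%%)\n",
              x$n_evaluated, x$threshold_percent))
  for (i in seq_len(nrow(x$criteria)))
    cat(sprintf("  %-4s GPR = %6.2f%%\n", x$criteria$label[i], x$gpr[i]))
  invisible(x)
}

#' Assemble a long-format GPR table from per-pair gamma results
#'
#' @param results Named list: `results[[plan_id]][[system]]` is a
#'   [gamma_analysis()] result (or `NULL`/missing for an unavailable dose
#'   pair, which yields rows with `NA` GPR rather than silently dropping
#'   them).
#' @param plan_meta Data.frame with `plan_id`, `site`, `linac` (one row per
#'   plan).
#' @param criteria Criteria data.frame; defaults to the criteria of the
#'   first available result.
#' @return Data.frame: `plan_id`, `site`, `linac`, `system`, `criterion`,
#'   `gpr`, `n_evaluated`. Duplicate (plan, system) entries are an error.
#' @export
gpr_table <- function(results, plan_meta, criteria = NULL) {
  rows <- list()
  for (plan_id in names(results)) {
    systems <- results[[plan_id]]
    if (anyDuplicated(names(systems)))
      stop("gpr_table: duplicate system '",
           names(systems)[duplicated(names(systems))][1],
           "' for plan '", plan_id, "'")
    meta <- plan_meta[plan_meta$plan_id == plan_id, , drop = FALSE]
    if (nrow(meta) != 1)
      stop("gpr_table: plan '", plan_id, "' missing from plan_meta")
    for (system in names(systems)) {
      res <- systems[[system]]
      if (is.null(res)) {
        crit <- if (is.null(criteria)) default_criteria() else criteria
        rows[[length(rows) + 1L]] <- data.frame(
          plan_id = plan_id, site = meta$site, linac = meta$linac,
          system = system, criterion = crit$label, gpr = NA_real_,
          n_evaluated = NA_integer_, stringsAsFactors = FALSE)
      } else {
        if (is.null(criteria)) criteria <- res$criteria
        rows[[length(rows) + 1L]] <- data.frame(
          plan_id = plan_id, site = meta$site, linac = meta$linac,
          system = system, criterion = res$criteria$label, gpr = res$gpr,
          n_evaluated = res$n_evaluated, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
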