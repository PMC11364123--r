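# Report bundle: CSV + Markdown tables mirroring the study's result
# structure (GPR distribution summaries, calculation-vs-measurement
# median gaps and correlation grid, the metric radar with its >= 0.5
# percentage summaries, and per-stratum PCR determination coefficients).

#' Write the study report for a cohort
#'
#' Deterministic given the cohort: rerunning on the same object regenerates
#' byte-identical files. Site strata with no plans are omitted with a
#' notice in the Markdown summary.
#'
#' @param cohort A [simulate_study()] result.
#' @param out_dir Output directory (created if needed).
#' @param variance_target PCR cumulative explained-variance target.
#' @return Invisibly, a list with every table written: `gpr_summary`,
#'   `median_gaps`, `r_calc_meas`, `radar`, `radar_summary`, `top`, `pcr`.
#' @export
study_report <- function(cohort, out_dir, variance_target = 0.90) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- cohort$gpr
  crits <- unique(g$criterion)

  key <- interaction(g$system, g$criterion, drop = TRUE)
  gpr_summary <- do.call(rbind, lapply(split(g, key), function(d)
    data.frame(system = d$system[1], criterion = d$criterion[1],
               n = sum(is.finite(d$gpr)),
               median = median(d$gpr, na.rm = TRUE),
               q1 = unname(quantile(d$gpr, 0.25, na.rm = TRUE)),
               q3 = unname(quantile(d$gpr, 0.75, na.rm = TRUE)),
               stringsAsFactors = FALSE)))
  rownames(gpr_summary) <- NULL
  gpr_summary <- gpr_summary[order(match(gpr_summary$criterion, crits),
                                   gpr_summary$system), ]

  type_of <- cohort$systems$type[match(g$system, cohort$systems$system)]
  median_gaps <- do.call(rbind, lapply(crits, function(cr) {
    sel <- g$criterion == cr
    data.frame(criterion = cr,
               median_cqa = median(g$gpr[sel & type_of == "CQA"],
                                   na.rm = TRUE),
               median_mqa = median(g$gpr[sel & type_of == "MQA"],
                                   na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  median_gaps$gap <- median_gaps$median_cqa - median_gaps$median_mqa

  rcm <- r_calc_meas_matrix(cohort)
  radar <- r_pcm_qa_radar(cohort)

  metric_cols <- cohort$registry$metric
  pcr <- list()
  for (sys in cohort$systems$system) for (cr in crits) {
    d <- g[g$system == sys & g$criterion == cr & is.finite(g$gpr), ]
    if (nrow(d) < 10) next
    X <- as.matrix(cohort$pcm[match(d$plan_id, cohort$pcm$plan_id),
                              metric_cols])
    fit <- tryCatch(suppressWarnings(
      pcr_predict(X, d$gpr, variance_target)), error = function(e) NULL)
    if (is.null(fit)) next
    pcr[[length(pcr) + 1L]] <- data.frame(
      system = sys, criterion = cr, site = "all", n = fit$n, k = fit$k,
      r_squared = fit$r_squared, p = fit$p_value, stringsAsFactors = FALSE)
    for (st in analysis_sites()) {
      ds <- d[d$site == st, ]
      if (nrow(ds) < 10) next
      Xs <- as.matrix(cohort$pcm[match(ds$plan_id, cohort$pcm$plan_id),
                                 metric_cols])
      fs <- tryCatch(suppressWarnings(
        pcr_predict(Xs, ds$gpr, variance_target)), error = function(e) NULL)
      if (is.null(fs)) next
      pcr[[length(pcr) + 1L]] <- data.frame(
        system = sys, criterion = cr, site = st, n = fs$n, k = fs$k,
        r_squared = fs$r_squared, p = fs$p_value, stringsAsFactors = FALSE)
    }
  }
  pcr <- do.call(rbind, pcr)

  wr <- function(d, name) write.csv(d, file.path(out_dir, name),
                                    row.names = FALSE)
  wr(gpr_summary, "gpr_summary.csv")
  wr(median_gaps, "median_gaps.csv")
  wr(rcm, "r_calc_meas.csv")
  wr(radar$radar, "r_pcm_qa.csv")
  wr(radar$summary, "pcm_pct_ge_0.5.csv")
  wr(radar$top, "top_metrics.csv")
  if (!is.null(pcr)) wr(pcr, "pcr_r_squared.csv")

  md <- c("# Synthetic QA study report", "",
          sprintf("Plans: %d; GPR records: %d; metrics: %d.",
                  nrow(cohort$pcm), nrow(g), nrow(cohort$registry)), "",
          "## Median GPR by criterion (calculation vs measurement)", "",
          "| criterion | median CQA | median MQA | gap |",
          "|---|---|---|---|",
          sprintf("| %s | %.1f | %.1f | %.1f |", median_gaps$criterion,
                  median_gaps$median_cqa, median_gaps$median_mqa,
                  median_gaps$gap), "")
  empty_sites <- setdiff(analysis_sites(), unique(g$site))
  if (length(empty_sites))
    md <- c(md, sprintf(
      "Note: site stratum '%s' has no plans; its sections are omitted.",
      empty_sites), "")
  md <- c(md, "## PCMs% >= 0.5 by system (pooled sites, strictest criterion)",
          "")
  ss <- radar$summary[radar$summary$site == "all" &
                        radar$summary$criterion == crits[length(crits)], ]
  md <- c(md, "| system | n >= 0.5 | % |", "|---|---|---|",
          sprintf("| %s | %d/%d | %.1f |", ss$system, ss$n_ge_0.5,
                  ss$n_metrics, ss$pcm_pct_ge_0.5))
  writeLines(md, file.path(out_dir, "report.md"))

  invisible(list(gpr_summary = gpr_summary, median_gaps = median_gaps,
                 r_calc_meas = rcm, radar = radar$radar,
                 radar_summary = radar$summary, top = radar$top, pcr = pcr))
}
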