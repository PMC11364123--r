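# Correlation and regression stage: tie-corrected Spearman correlation
# with strength grading, the calculation-vs-measurement correlation grid,
# the metric-vs-QA radar bookkeeping, and principal-component regression.

#' Grade a correlation coefficient by absolute value
#'
#' Cut points: `|r| >= 0.7` strong, `[0.5, 0.7)` moderate, `[0.4, 0.5)`
#' weak, below 0.4 none.
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of grades.
#' @export
grade_correlation <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.7, "strong",
         ifelse(a >= 0.5, "moderate",
                ifelse(a >= 0.4, "weak", "none")))
}

#' Spearman rank correlation with significance and strength grade
#'
#' Tie-corrected rank correlation (Pearson correlation of mid-ranks);
#' two-tailed p-value from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired finite numeric vectors, `n >= 5`.
#' @return A list of class `correlation_report`: `r`, `p`, `n`, `grade`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("spearman: x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("spearman: need at least 5 pairs (got ", n, ")")
  if (sd(x) == 0 || sd(y) == 0)
    stop("spearman: correlation undefined for a constant vector")
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, grade = grade_correlation(r)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> r = %.3f (%s), p = %.3g, n = %d\n",
              x$r, x$grade, x$p, x$n))
  invisible(x)
}

spearman_or_na <- function(x, y) {
  tryCatch(spearman(x, y),
           error = function(e) list(r = NA_real_, p = NA_real_,
                                    n = sum(is.finite(x) & is.finite(y)),
                                    grade = NA_character_))
}

# Sites entering stratified statistics (limbs carried in the cohort but
# excluded here: its per-site sample is too small to rank).
analysis_sites <- function() setdiff(PLAN_SITES, "limbs")

# Wide GPR matrix: rows plans, columns criteria, for one system.
system_gpr <- function(cohort, sys) {
  g <- cohort$gpr[cohort$gpr$system == sys, ]
  g
}

#' Calculation-vs-measurement correlation grid
#'
#' Spearman correlation between the GPRs of every calculation-based system
#' and every measurement-based system sharing plans, per criterion and per
#' site stratum (plus pooled `"all"`). Pairs with no overlapping plans (or
#' fewer than 5) appear as explicit empty rows rather than being dropped.
#'
#' @param cohort A [simulate_study()] result (or compatible `qa_cohort`).
#' @return Data.frame: `cqa_system`, `mqa_system`, `criterion`, `site`,
#'   `n`, `r`, `p`, `grade`, `highlight` (`|r| >= 0.4`).
#' @export
r_calc_meas_matrix <- function(cohort) {
  sys <- cohort$systems
  cqa <- sys$system[sys$type == "CQA"]
  mqa <- sys$system[sys$type == "MQA"]
  crits <- unique(cohort$gpr$criterion)
  sites <- c(analysis_sites(), "all")
  out <- list()
  for (cs in cqa) for (ms in mqa) for (cr in crits) for (st in sites) {
    gc <- cohort$gpr[cohort$gpr$system == cs & cohort$gpr$criterion == cr, ]
    gm <- cohort$gpr[cohort$gpr$system == ms & cohort$gpr$criterion == cr, ]
    if (st != "all") {
      gc <- gc[gc$site == st, ]; gm <- gm[gm$site == st, ]
    }
    common <- intersect(gc$plan_id, gm$plan_id)
    if (length(common) >= 5) {
      rep <- spearman_or_na(gc$gpr[match(common, gc$plan_id)],
                            gm$gpr[match(common, gm$plan_id)])
    } else rep <- list(r = NA_real_, p = NA_real_, n = length(common),
                       grade = NA_character_)
    out[[length(out) + 1L]] <- data.frame(
      cqa_system = cs, mqa_system = ms, criterion = cr, site = st,
      n = rep$n, r = rep$r, p = rep$p, grade = rep$grade,
      highlight = !is.na(rep$r) & abs(rep$r) >= 0.4,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Metric-vs-QA correlation radar and its summaries
#'
#' For every registered metric, QA system, criterion and site stratum,
#' the Spearman correlation between the metric and the system's GPRs
#' (absolute value reported alongside the signed value). Summaries: the
#' percentage of metrics with `|r| >= 0.5` per system/criterion/site, and
#' the top-10 metric ranking per system at the strictest criterion.
#'
#' @param cohort A [simulate_study()] result.
#' @param top_n Size of the per-system ranking.
#' @return List: `radar` (long data.frame with `metric`, `system`,
#'   `criterion`, `site`, `n`, `r`, `abs_r`, `p`, `grade`), `summary`
#'   (`system`, `criterion`, `site`, `n_metrics`, `n_ge_0.5`,
#'   `pcm_pct_ge_0.5`), `top` (per system at the strictest criterion).
#' @export
r_pcm_qa_radar <- function(cohort, top_n = 10) {
  metrics <- cohort$registry$metric
  crits <- unique(cohort$gpr$criterion)
  sites <- c(analysis_sites(), "all")
  systems <- cohort$systems$system
  radar <- list()
  for (sys in systems) for (cr in crits) {
    g <- cohort$gpr[cohort$gpr$system == sys & cohort$gpr$criterion == cr, ]
    for (st in sites) {
      gs <- if (st == "all") g else g[g$site == st, ]
      idx <- match(gs$plan_id, cohort$pcm$plan_id)
      for (met in metrics) {
        v <- cohort$pcm[[met]][idx]
        rep <- if (length(v) >= 5) spearman_or_na(v, gs$gpr) else
          list(r = NA_real_, p = NA_real_, n = length(v),
               grade = NA_character_)
        radar[[length(radar) + 1L]] <- list(
          metric = met, system = sys, criterion = cr, site = st,
          n = rep$n, r = rep$r, abs_r = abs(rep$r), p = rep$p,
          grade = rep$grade)
      }
    }
  }
  radar <- do.call(rbind, lapply(radar, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  key <- interaction(radar$system, radar$criterion, radar$site, drop = TRUE)
  summary <- do.call(rbind, lapply(split(radar, key), function(d) {
    data.frame(system = d$system[1], criterion = d$criterion[1],
               site = d$site[1], n_metrics = nrow(d),
               n_ge_0.5 = sum(d$abs_r >= 0.5, na.rm = TRUE),
               pcm_pct_ge_0.5 = 100 * sum(d$abs_r >= 0.5, na.rm = TRUE) /
                 nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  strict <- crits[length(crits)]
  top <- do.call(rbind, lapply(systems, function(sys) {
    d <- radar[radar$system == sys & radar$criterion == strict &
                 radar$site == "all", ]
    d <- d[order(-d$abs_r), ]
    utils::head(cbind(rank = seq_len(nrow(d)), d), top_n)
  }))
  rownames(top) <- NULL
  list(radar = radar, summary = summary, top = top)
}

#' Principal-component regression of GPR on the metric matrix
#'
#' Metrics are z-scored (zero-variance columns dropped with a warning),
#' decomposed by PCA on the correlation structure, and the smallest number
#' of leading components whose cumulative explained variance reaches
#' `variance_target` is used as regressors in an ordinary least-squares fit
#' of the GPR vector; multicollinearity among metrics is absorbed by the
#' rotation.
#'
#' @param pcm_matrix Numeric matrix `[n_plans x n_metrics]`.
#' @param gpr_vector GPR per plan (percent).
#' @param variance_target Cumulative explained-variance target in (0, 1].
#' @return List: `r_squared`, `k` (components kept), `coefficients`,
#'   `p_value` (overall F test), `explained_variance` (per component),
#'   `n`.
#' @export
pcr_predict <- function(pcm_matrix, gpr_vector, variance_target = 0.90) {
  pcm_matrix <- as.matrix(pcm_matrix)
  stopifnot(nrow(pcm_matrix) == length(gpr_vector))
  ok_rows <- stats::complete.cases(pcm_matrix) & is.finite(gpr_vector)
  pcm_matrix <- pcm_matrix[ok_rows, , drop = FALSE]
  gpr_vector <- gpr_vector[ok_rows]
  v <- apply(pcm_matrix, 2, sd)
  if (any(v == 0 | !is.finite(v))) {
    warning("pcr_predict: dropping ", sum(v == 0 | !is.finite(v)),
            " zero-variance metric column(s)")
    pcm_matrix <- pcm_matrix[, v > 0 & is.finite(v), drop = FALSE]
  }
  pc <- prcomp(pcm_matrix, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  if (nrow(pcm_matrix) <= k + 1)
    stop("pcr_predict: need more plans than retained components")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  fit <- lm(gpr_vector ~ scores)
  s <- summary(fit)
  p <- if (is.null(s$fstatistic)) NA_real_ else
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE))
  list(r_squared = s$r.squared, k = k, coefficients = coef(fit),
       p_value = p, explained_variance = ev, n = nrow(pcm_matrix))
}
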