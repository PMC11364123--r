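test_that("spearman handles perfect monotone association and errors", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  r1 <- spearman(x, x^3 + 2)       # strictly monotone transform
  expect_equal(r1$r, 1)
  expect_equal(r1$p, 0)
  expect_equal(r1$grade, "strong")
  r2 <- spearman(x, -x)
  expect_equal(r2$r, -1)
  expect_equal(r2$grade, "strong")

  expect_error(spearman(1:4, 2:5), "at least 5")
  expect_error(spearman(rep(1, 8), 1:8), "constant")
  expect_error(spearman(1:5, 1:4), "paired")
})

test_that("tie-corrected spearman matches the rank-definition oracle", {
  set.seed(2)
  for (rep in 1:10) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE) + 0.5 * x
    if (sd(x) == 0 || sd(y) == 0) next
    rep_got <- spearman(x, y)
    # oracle: mid-ranks by definition, then the explicit product-moment sum
    midrank <- function(v) vapply(v, function(vi)
      mean(which(sort(v) == vi)), numeric(1))
    rx <- midrank(x); ry <- midrank(y)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(rep_got$r, num / den, tolerance = 1e-12)
    # cross-check against the independent implementation in stats
    expect_equal(rep_got$r,
                 suppressWarnings(cor.test(x, y, method = "spearman"))$estimate[[1]],
                 tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  base <- spearman(x, y)$r
  expect_equal(spearman(exp(x), y)$r, base, tolerance = 1e-12)
  expect_equal(spearman(x, qlogis(plogis(y)))$r, base, tolerance = 1e-9)
  expect_equal(spearman(-1 / (x + 10), y)$r, base, tolerance = 1e-12)
})

test_that("grading is a step function with the stated boundaries", {
  expect_equal(grade_correlation(c(0.7, 0.71, -0.9)),
               rep("strong", 3))
  expect_equal(grade_correlation(c(0.5, 0.69, -0.5)),
               rep("moderate", 3))
  expect_equal(grade_correlation(c(0.4, 0.49, -0.4)),
               rep("weak", 3))
  expect_equal(grade_correlation(c(0, 0.39, -0.39)),
               rep("none", 3))
})

test_that("r_calc_meas grid pairs systems and flags missing overlap", {
  coh <- tiny_cohort()
  rcm <- r_calc_meas_matrix(coh)
  # CQA systems of linac 1 never share plans with the linac-2 array
  off <- rcm[rcm$cqa_system == "MC_helical" &
               rcm$mqa_system == "oblique_cross", ]
  expect_true(all(is.na(off$r)))
  expect_true(all(off$n == 0))
  # identical GPR columns give r = 1: feed a duplicated system
  coh2 <- coh
  dup <- coh$gpr[coh$gpr$system == "helical", ]
  dup$system <- "helical_copy"
  coh2$gpr <- rbind(coh2$gpr, dup)
  coh2$systems <- rbind(coh2$systems,
                        data.frame(system = "helical_copy", type = "CQA",
                                   linac = 1))
  rcm2 <- r_calc_meas_matrix(coh2)
  self <- rcm2[rcm2$cqa_system == "helical_copy" &
                 rcm2$mqa_system == "helical" & rcm2$site == "all", ]
  # identical columns correlate perfectly wherever defined (a stratum with
  # a constant GPR column is reported as an explicit empty cell)
  expect_gte(sum(!is.na(self$r)), 1)
  expect_true(all(self$r[!is.na(self$r)] == 1))
  expect_true(all(self$highlight[!is.na(self$r)]))
})

test_that("the radar covers every metric-system-criterion-site cell", {
  coh <- tiny_cohort()
  rad <- r_pcm_qa_radar(coh)
  expect_equal(nrow(rad$radar), 53 * 6 * 4 * 4)  # metrics x systems x crit x strata
  one_site <- rad$radar[rad$radar$site == "pelvis" &
                          rad$radar$criterion == "1/1", ]
  expect_equal(nrow(one_site), 53 * 6)
  expect_true(all(rad$summary$pcm_pct_ge_0.5 >= 0 &
                    rad$summary$pcm_pct_ge_0.5 <= 100))
  expect_true(all(rad$top$rank <= 10))
})

test_that("PCMs%>=0.5 is near zero for independent noise metrics", {
  # synthetic cohort shell with 200 plans: pure-noise metrics cannot reach
  # |r| >= 0.5 against any GPR column
  set.seed(31)
  n <- 200
  metrics <- sprintf("m%02d", 1:53)
  sites <- sample(c("head_and_neck", "chest_and_abdomen", "pelvis"), n,
                  TRUE)
  pcm <- cbind(data.frame(plan_id = sprintf("P%03d", 1:n), site = sites,
                          linac = 1),
               as.data.frame(matrix(rnorm(n * 53), n,
                                    dimnames = list(NULL, metrics))))
  gpr <- do.call(rbind, lapply(c("3/3", "3/2", "2/2", "1/1"), function(cr)
    data.frame(plan_id = pcm$plan_id, site = sites, linac = 1,
               system = "sys1", criterion = cr,
               gpr = pmin(100, 95 + rnorm(n, sd = 3)))))
  shell <- structure(list(
    gpr = gpr, pcm = pcm,
    systems = data.frame(system = "sys1", type = "MQA", linac = 1),
    registry = data.frame(metric = metrics, category = "aperture",
                          orientation = 0, fallback = FALSE)),
    class = "qa_cohort")
  rad <- r_pcm_qa_radar(shell)
  expect_lt(max(rad$summary$pcm_pct_ge_0.5[rad$summary$site == "all"]), 5)
})

test_that("PCR attains R^2 = 1 on component-aligned response", {
  set.seed(8)
  X <- matrix(rnorm(500 * 12), 500)
  X[, 1:6] <- X[, 1:6] + 2 * X[, 12]   # correlated block
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  y <- 80 + 3 * pc$x[, 1]
  fit <- suppressWarnings(pcr_predict(X, y, variance_target = 0.9))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$p_value < 1e-10)
})

test_that("PCR on pure-noise response stays near the chance level", {
  set.seed(9)
  lat <- matrix(rnorm(500 * 5), 500)
  X <- lat[, sample(5, 53, TRUE)] + 0.15 * matrix(rnorm(500 * 53), 500)
  y <- rnorm(500)
  fit <- pcr_predict(X, y, variance_target = 0.9)
  expect_lte(fit$k, 10)
  expect_lt(fit$r_squared, 0.1)
})

test_that("PCR absorbs duplicated metric columns", {
  set.seed(10)
  X <- matrix(rnorm(200 * 8), 200)
  y <- X %*% rnorm(8) + rnorm(200)
  f1 <- pcr_predict(X, y, variance_target = 0.95)
  f2 <- pcr_predict(cbind(X, X), y, variance_target = 0.95)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  expect_warning(pcr_predict(cbind(X, 0), y), "zero-variance")
})

test_that("PCR R^2 is non-decreasing in the number of components", {
  set.seed(11)
  X <- matrix(rnorm(150 * 10), 150)
  X[, 1:5] <- X[, 1:5] + matrix(rnorm(150), 150, 5)
  y <- X %*% runif(10) + rnorm(150, sd = 2)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  r2 <- vapply(sort(unique(c(ev, 1))), function(vt)
    pcr_predict(X, y, variance_target = vt)$r_squared, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  # explained variance is non-increasing across components
  fit <- pcr_predict(X, y)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
})
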