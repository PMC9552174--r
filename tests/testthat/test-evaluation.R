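test_that("fit_cox recovers a known two-group hazard ratio", {
  set.seed(101)
  n <- 2000
  grp <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * ifelse(grp == 1, 2, 1))
  cens <- rexp(n, 0.043)  # ~30% censoring
  time <- pmin(t_ev, cens)
  event <- as.integer(t_ev <= cens)
  res <- fit_cox(time, event, grp, "binary")
  expect_gt(res$hr, 1.85)
  expect_lt(res$hr, 2.16)
  # exponential oracle: ratio of event-count/exposure estimates
  rate1 <- sum(event[grp == 1]) / sum(time[grp == 1])
  rate0 <- sum(event[grp == 0]) / sum(time[grp == 0])
  expect_equal(res$hr, rate1 / rate0, tolerance = 0.05)
})

test_that("fit_cox guards degenerate inputs", {
  expect_error(fit_cox(1:10, rep(1, 10), rep(1, 10)), "unidentifiable")
  expect_error(fit_cox(1:10, rep(0, 10), rep(c(0, 1), 5)), "events")
})

test_that("km_curve matches the product-limit estimate by hand", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1), rep("a", 4))
  expect_equal(km$curves$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(unname(km$medians["a"]), 2)
  # without censoring KM equals the empirical survival fraction
  set.seed(3)
  tm <- rexp(200, 0.2)
  km2 <- km_curve(tm, rep(1, 200), rep("a", 200))
  emp <- vapply(km2$curves$time, function(u) mean(tm > u), numeric(1))
  expect_equal(km2$curves$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km2$curves$surv) <= 0))
  expect_true(all(km2$curves$surv >= 0 & km2$curves$surv <= 1))
})

test_that("km median approaches the exponential closed form", {
  set.seed(8)
  lam <- 0.23
  km <- km_curve(rexp(5000, lam), rep(1, 5000), rep("a", 5000))
  expect_lt(abs(km$medians["a"] - log(2) / lam) / (log(2) / lam), 0.05)
})

test_that("identical groups give log-rank p near 1, empty groups error", {
  set.seed(12)
  tm <- rexp(400, 0.2)
  grp <- rep(c("a", "b"), 200)
  km <- km_curve(tm, rep(1, 400), grp)
  expect_gt(km$logrank_p, 0.05)
  expect_error(km_curve(tm, rep(1, 400), factor(grp, levels = c("a", "b", "c"))),
               "empty")
})

test_that("median not reached is NA, never the last time point", {
  km <- km_curve(c(5, 6, 7, 8), c(1, 0, 0, 0), rep("a", 4))
  expect_true(is.na(km$medians["a"]))
})

test_that("cox direction agrees with the KM curves at the median", {
  fx <- step_cohort(800, threshold = 3, step_hr = 0.4, seed = 41)
  grp <- as.integer(fx$score >= 3)
  cx <- fit_cox(fx$cohort$clinical$pfs_time, fx$cohort$clinical$pfs_event,
                grp, "binary")
  expect_lt(cx$hr, 1)
  expect_gt(unname(cx$medians["1"]), unname(cx$medians["0"]))
})

test_that("ORR arithmetic, NE exclusion, and empty-cell flagging", {
  response <- c(rep("PR", 3), "CR", rep("PD", 6))
  tab <- orr_compare(response, strata = rep(1, 10),
                     arms = rep("treated", 10))
  expect_equal(tab$orr[tab$stratum == "high" & tab$arm == "treated"], 0.4)
  expect_true(isTRUE(attr(tab, "empty_cells")))

  # NE and NA excluded from denominators
  tab2 <- orr_compare(c("PR", "NE", "PD", NA), rep(1, 4), rep("treated", 4))
  expect_equal(tab2$n[tab2$stratum == "high" & tab2$arm == "treated"], 2)

  # absolute difference arithmetic on constructed proportions
  resp <- c(rep("PR", 306), rep("PD", 694), rep("PR", 114), rep("PD", 886))
  tab3 <- orr_compare(resp, strata = rep(1, 2000),
                      arms = rep(c("treated", "control"), c(1000, 1000)))
  expect_equal(unname(attr(tab3, "diffs")["treated_vs_control_high"]),
               0.306 - 0.114, tolerance = 1e-12)
})

test_that("responder AUC equals the exhaustive pair oracle", {
  set.seed(77)
  for (trial in 1:10) {
    n <- sample(20:60, 1)
    marker <- sample(0:8, n, replace = TRUE)  # heavy ties
    label <- rbinom(n, 1, 0.4)
    if (length(unique(label)) < 2) next
    expect_equal(auc_mann_whitney(marker, label), auc_oracle(marker, label),
                 tolerance = 1e-14)
    expect_equal(auc_mann_whitney(marker, label) +
                   auc_mann_whitney(-marker, label), 1)
  }
  expect_equal(auc_mann_whitney(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc_mann_whitney(rep(4, 10), c(rep(0, 5), rep(1, 5))), 0.5)
})

test_that("responder_auc bootstrap is seeded and ordered", {
  set.seed(5)
  marker <- rnorm(80)
  label <- rbinom(80, 1, 0.5)
  a <- responder_auc(marker, label, n_bootstrap = 200, seed = 9)
  b <- responder_auc(marker, label, n_bootstrap = 200, seed = 9)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$auc)
  expect_gte(a$ci_high, a$auc)
})

test_that("spearman_rho: exact cases and the rank-formula oracle", {
  expect_equal(spearman_rho(1:10, 1:10)$rho, 1)
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 5)
  # no-ties oracle: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(a) - rank(b)
  expect_equal(spearman_rho(a, b)$rho, 1 - 6 * sum(d^2) / (5 * 24))
  # pairwise-complete handling
  expect_equal(spearman_rho(c(a, NA), c(b, 3))$n, 5)
})

test_that("build_report reproduces the planted qualitative pattern", {
  co <- simulate_cohort(simulation_config(
    n_patients = 900, n_genes = 60, n_benefit_genes = 12,
    mutation_freq_range = c(0.1, 0.3),
    log_hr_treated_per_mutation = log(0.75),
    log_hr_control_per_mutation = log(1.1),
    response_intercept = qlogis(0.1) , response_score_by_arm_slope = log(1.6),
    seed = 55))
  rep1 <- build_report(co, true_panel(co), score_cutoff = 2,
                       n_bootstrap = 200, seed = 4)
  expect_lt(rep1$contrasts$score_group_pfs_treated$hr, 1)
  expect_gte(rep1$contrasts$score_group_pfs_control$hr, 1)
  expect_lt(rep1$contrasts$score_continuous_pfs_treated$hr, 1)
  # benefit patients respond more on immunotherapy
  d <- attr(rep1$orr$score, "diffs")
  expect_gt(unname(d["high_vs_low_treated"]), 0)
  expect_gt(rep1$auc$score$auc, 0.5)
})

test_that("null cohorts: contrast CIs cover 1 at roughly nominal rate", {
  cover <- integer(0)
  for (r in 1:6) {
    co <- simulate_cohort(simulation_config(
      n_patients = 300, n_genes = 30, n_benefit_genes = 6,
      log_hr_treated_per_mutation = 0, log_hr_control_per_mutation = 0,
      response_score_by_arm_slope = 0, seed = 700 + r))
    rep1 <- build_report(co, true_panel(co), score_cutoff = 1,
                         n_bootstrap = 50, seed = 1)
    for (ct in rep1$contrasts) {
      cover <- c(cover, ct$ci_low <= 1 && ct$ci_high >= 1)
    }
  }
  expect_gte(mean(cover), 0.9)
})

test_that("report serialization round-trips", {
  co <- simulate_cohort(simulation_config(n_patients = 250, n_genes = 30,
                                          n_benefit_genes = 6, seed = 66))
  rep1 <- build_report(co, true_panel(co), n_bootstrap = 100, seed = 2)
  path <- tempfile(fileext = ".json")
  report_to_json(rep1, path)
  back <- report_from_json(path)
  expect_equal(back$contrasts$score_group_pfs_treated$hr,
               rep1$contrasts$score_group_pfs_treated$hr, tolerance = 1e-12)
  expect_equal(back$auc$score$auc, rep1$auc$score$auc, tolerance = 1e-12)
  expect_equal(back$spearman$score_vs_tmb$rho,
               rep1$spearman$score_vs_tmb$rho, tolerance = 1e-12)
})

test_that("missing arm yields a partial report with explicit gaps", {
  co <- simulate_cohort(simulation_config(n_patients = 200, n_genes = 30,
                                          n_benefit_genes = 6, arm_ratio = 1,
                                          seed = 3))
  rep1 <- build_report(co, true_panel(co), n_bootstrap = 50, seed = 1)
  expect_true(any(grepl("missing arm", rep1$flags)))
  expect_false(any(grepl("control", names(rep1$contrasts))))
})
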