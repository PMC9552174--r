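test_that("config validation rejects impossible worlds", {
  expect_error(simulation_config(n_benefit_genes = 50, n_genes = 40),
               "exceeds n_genes")
  expect_error(simulation_config(baseline_hazard_pfs = 0), "positive")
  expect_error(simulation_config(baseline_hazard_os = -1), "positive")
  expect_error(simulation_config(mutation_freq_range = c(0.5, 1.2)))
})

test_that("identical seeds give bit-identical cohorts; seeds matter", {
  cfg <- simulation_config(n_patients = 120, n_genes = 30,
                           n_benefit_genes = 5, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_config(n_patients = 120, n_genes = 30,
                                          n_benefit_genes = 5, seed = 43))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("degenerate frequency range gives an all-zero matrix", {
  co <- simulate_cohort(simulation_config(n_patients = 60, n_genes = 15,
                                          n_benefit_genes = 3,
                                          mutation_freq_range = c(0, 0),
                                          seed = 1))
  expect_true(all(co$mutations == 0L))
  expect_true(all(ici_benefit_score(co, true_panel(co)) == 0L))
})

test_that("null-effect world: Cox HR of score is ~1 in both arms", {
  co <- simulate_cohort(simulation_config(
    n_patients = 4000, n_genes = 40, n_benefit_genes = 10,
    log_hr_treated_per_mutation = 0, log_hr_control_per_mutation = 0,
    log_hr_treatment_main = 0, response_score_by_arm_slope = 0, seed = 7))
  score <- ici_benefit_score(co, true_panel(co))
  for (a in c("treated", "control")) {
    sel <- co$clinical$arm == a
    hr <- fit_cox(co$clinical$pfs_time[sel], co$clinical$pfs_event[sel],
                  score[sel], "continuous")$hr
    expect_gt(hr, 0.93)
    expect_lt(hr, 1.07)
  }
})

test_that("Cox recovers the planted per-mutation hazard ratio", {
  # uncensored exponential world: the partial-likelihood fit is consistent
  # all patients treated so the treated-arm fit sees the full n = 5000
  co <- simulate_cohort(simulation_config(
    n_patients = 5000, n_genes = 40, n_benefit_genes = 10,
    mutation_freq_range = c(0.1, 0.3), arm_ratio = 1,
    log_hr_treated_per_mutation = log(0.8),
    log_hr_control_per_mutation = 0, log_hr_treatment_main = 0,
    censor_time_max = Inf, response_score_by_arm_slope = 0, seed = 11))
  score <- ici_benefit_score(co, true_panel(co))
  sel <- co$clinical$arm == "treated"
  hr <- fit_cox(co$clinical$pfs_time[sel], co$clinical$pfs_event[sel],
                score[sel], "continuous")$hr
  expect_lt(abs(hr - 0.8), 0.04)
})

test_that("per-gene mutation frequencies converge to their rates", {
  co <- simulate_cohort(simulation_config(
    n_patients = 5000, n_genes = 50, n_benefit_genes = 0,
    mutation_freq_range = c(0.05, 0.4), seed = 5))
  phat <- colMeans(co$mutations)
  p <- co$sim_freqs
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(phat - p) <= 3 * se))
})

test_that("log-rank between arms holds its nominal 5% size under the null", {
  cfg0 <- simulation_config(n_patients = 80, n_genes = 4, n_benefit_genes = 0,
                            log_hr_treatment_main = 0,
                            response_score_by_arm_slope = 0)
  rejections <- vapply(seq_len(1000), function(r) {
    cfg <- cfg0
    cfg$seed <- 10000L + r
    co <- simulate_cohort(cfg)
    km <- km_curve(co$clinical$pfs_time, co$clinical$pfs_event,
                   co$clinical$arm)
    km$logrank_p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("event rate rises with the censoring horizon", {
  rates <- vapply(c(5, 15, 40), function(cmax) {
    co <- simulate_cohort(simulation_config(
      n_patients = 1500, n_genes = 5, n_benefit_genes = 0,
      censor_time_max = cmax, seed = 3))
    mean(co$clinical$pfs_event)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("true_panel returns the planted genes and errors without truth", {
  co <- simulate_cohort(simulation_config(n_patients = 50, n_genes = 25,
                                          n_benefit_genes = 20, seed = 2))
  expect_length(true_panel(co), 20)
  expect_identical(true_panel(co),
                   true_panel(simulate_cohort(
                     simulation_config(n_patients = 50, n_genes = 25,
                                       n_benefit_genes = 20, seed = 2))))
  real <- clinical_only_cohort(c(1, 2, 3), c(1, 1, 0))
  expect_error(true_panel(real), "no truth")
})

test_that("dataset invariants are enforced by the constructor", {
  ids <- c("A", "B")
  m <- matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(ids, c("G1", "G2")))
  clin <- data.frame(sample_id = ids, arm = c("treated", "control"),
                     pfs_time = c(1, 2), pfs_event = c(1, 0),
                     os_time = c(2, 3), os_event = c(1, 0))
  expect_s3_class(cohort_dataset(m, clin), "cohort_dataset")
  m2 <- m; m2[1, 1] <- 2L
  expect_error(cohort_dataset(m2, clin), "binary")
  clin2 <- clin; clin2$pfs_event[1] <- 2
  expect_error(cohort_dataset(m, clin2), "0/1")
  clin3 <- clin; clin3$pfs_time[2] <- -1
  expect_error(cohort_dataset(m, clin3), "positive")
})
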