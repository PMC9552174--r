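make_labeled_matrix <- function(n = 160, p = 51, seed = 1,
                                perfect_col = NULL) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, sprintf("G%03d", seq_len(p))))
  y <- rbinom(n, 1, 0.5)
  if (!is.null(perfect_col)) x[, perfect_col] <- y
  list(x = x, y = y)
}

test_that("make_label: responder spec masks NE and maps CR/PR to 1", {
  co <- clinical_only_cohort(c(2, 3, 4), c(1, 1, 0),
                             response = c("PR", "SD", "NE"))
  lab <- make_label(co, "responder")
  expect_identical(lab$label[lab$mask], c(1L, 0L))
  expect_identical(lab$mask, c(TRUE, TRUE, FALSE))
})

test_that("make_label: pfs_ge_m handles the three definition cases", {
  co <- clinical_only_cohort(c(7, 3, 3), c(1, 1, 0))
  lab <- make_label(co, "pfs_ge_m", months = 6)
  expect_identical(lab$label, c(1L, 0L, NA_integer_))
  expect_identical(lab$mask, c(TRUE, TRUE, FALSE))
})

test_that("make_label only sees treated-arm patients and needs response", {
  co <- clinical_only_cohort(c(2, 3, 4, 5), c(1, 1, 1, 1),
                             arm = c("treated", "control", "treated",
                                     "control"),
                             response = c("PR", "PR", "PD", "PD"))
  lab <- make_label(co, "responder")
  expect_length(lab$label, 2)
  expect_identical(lab$label, c(1L, 0L))
  co2 <- clinical_only_cohort(c(2, 3), c(1, 1))
  expect_error(make_label(co2, "responder"), "response")
})

test_that("a perfect single-gene predictor dominates the importance ranking", {
  d <- make_labeled_matrix(perfect_col = 25, seed = 4)
  cfg <- selection_config(top_k = 10, seed = 1)
  rep1 <- run_repetition(d$x, d$y, cfg, repetition_seed = 99)
  expect_equal(unname(rep1$rank["G025"]), 1)
  # oracle: univariate AUC ranking agrees that G025 is the top gene
  uni_auc <- apply(d$x, 2, function(col) abs(auc_mann_whitney(col, d$y) - 0.5))
  expect_equal(names(which.max(uni_auc)), "G025")
})

test_that("constant gene columns get importance exactly 0", {
  d <- make_labeled_matrix(perfect_col = 10, seed = 6)
  d$x[, "G040"] <- 0L
  rep1 <- run_repetition(d$x, d$y, selection_config(top_k = 10, seed = 1), 42)
  expect_identical(unname(rep1$importance["G040"]), 0)
})

test_that("run_repetition is deterministic in its seed", {
  d <- make_labeled_matrix(perfect_col = 3, seed = 8)
  cfg <- selection_config(top_k = 10, seed = 1)
  a <- run_repetition(d$x, d$y, cfg, 1234)
  b <- run_repetition(d$x, d$y, cfg, 1234)
  expect_identical(a, b)
  c2 <- run_repetition(d$x, d$y, cfg, 1235)
  expect_false(identical(a$importance, c2$importance))
})

test_that("run_repetition guards: degenerate labels, tiny classes, top_k", {
  d <- make_labeled_matrix(seed = 2)
  cfg <- selection_config(top_k = 10, seed = 1)
  expect_error(run_repetition(d$x, rep(1, nrow(d$x)), cfg, 1), "degenerate")
  y_rare <- c(rep(1L, 5), rep(0L, nrow(d$x) - 5))
  expect_error(run_repetition(d$x, y_rare, cfg, 1), "fewer than 20")
  expect_error(run_repetition(d$x, d$y, selection_config(top_k = 500), 1),
               "top_k")
})

test_that("n_repetitions = 1 returns exactly that repetition's top-k", {
  co <- simulate_cohort(planted_signal_config(seed = 31, n_patients = 400,
                                              n_genes = 60,
                                              n_benefit_genes = 10))
  cfg <- selection_config(n_repetitions = 1, top_k = 15,
                          stability_window = 1, seed = 77)
  sel <- select_panel(co, cfg)
  expect_equal(nrow(sel$panel), 15)
  lab <- make_label(co, "responder")
  x <- co$mutations[lab$treated_rows[lab$mask], , drop = FALSE]
  set.seed(77)
  seed1 <- sample.int(.Machine$integer.max - 1L, 1)
  rep1 <- run_repetition(x, lab$label[lab$mask], cfg, seed1)
  expect_setequal(sel$panel$gene, names(rep1$rank)[rep1$rank <= 15])
})

test_that("running intersection is non-increasing and selection is deterministic", {
  co <- simulate_cohort(planted_signal_config(seed = 19, n_patients = 500,
                                              n_genes = 80,
                                              n_benefit_genes = 10))
  cfg <- selection_config(n_repetitions = 12, top_k = 20,
                          stability_window = 5, seed = 3)
  a <- select_panel(co, cfg)
  expect_true(all(diff(a$trace$intersection_size) <= 0))
  b <- select_panel(co, cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$trace, b$trace)
  expect_identical(a$rankings, b$rankings)
})

test_that("label-independent data: intersection decays, panel stays small", {
  co <- simulate_cohort(simulation_config(
    n_patients = 400, n_genes = 60, n_benefit_genes = 0,
    mutation_freq_range = c(0.15, 0.35), response_intercept = 0,
    response_score_by_arm_slope = 0, seed = 11))
  sel <- select_panel(co, selection_config(
    n_repetitions = 50, top_k = 12, mode = "intersection",
    stability_window = 10, seed = 5))
  expect_lt(nrow(sel$panel), 12 / 4)
  expect_true(all(diff(sel$trace$intersection_size) <= 0))
})

test_that("chance-overlap: no gene is systematically favoured under the null", {
  # equal per-gene frequencies (exchangeable genes) and independent null
  # cohorts; within one dataset chance gene-label correlations persist
  # across repetitions, so the unit of replication is the cohort
  n_cohorts <- 12
  k <- 12; p <- 60
  incl <- matrix(NA_real_, p, n_cohorts)
  for (d in seq_len(n_cohorts)) {
    co <- simulate_cohort(simulation_config(
      n_patients = 300, n_genes = p, n_benefit_genes = 0,
      mutation_freq_range = c(0.25, 0.25), response_intercept = 0,
      response_score_by_arm_slope = 0, seed = 5000 + d))
    sel <- select_panel(co, selection_config(
      n_repetitions = 4, top_k = k, stability_window = 2,
      seed = 6000 + d))
    incl[, d] <- rowMeans(sel$rankings <= k)
  }
  freq <- rowMeans(incl)
  se <- apply(incl, 1, sd) / sqrt(n_cohorts)
  expect_equal(mean(freq), k / p, tolerance = 1e-12)
  within <- abs(freq - k / p) <= 3 * pmax(se, 1e-6)
  expect_gte(mean(within), 0.9)
})

test_that("restrict_panel maps onto another assay's universe", {
  panel <- structure(data.frame(gene = sprintf("G%02d", 1:10),
                                mean_importance = 10:1 / 10,
                                topk_frequency = rep(1, 10)),
                     class = c("gene_panel", "data.frame"))
  assay <- sprintf("G%02d", c(1, 3, 5, 7, 9))
  r <- suppressMessages(restrict_panel(panel, assay))
  expect_identical(r$gene, assay)
  expect_identical(suppressMessages(restrict_panel(panel$gene, assay)), assay)
  expect_identical(restrict_panel(panel, sprintf("G%02d", 1:20)), panel)
  expect_warning(r0 <- restrict_panel(panel, c("X1", "X2")), "empty")
  expect_equal(nrow(r0), 0)
})
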