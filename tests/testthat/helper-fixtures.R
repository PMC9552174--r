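# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# Minimal cohort wrapper around externally constructed survival data: one
# all-zero dummy gene keeps the matrix contract satisfied when only the
# clinical side matters.
clinical_only_cohort <- function(time, event, arm = "treated",
                                 os_time = time, os_event = event,
                                 response = NULL, sld = NULL, tmb = NULL) {
  n <- length(time)
  ids <- sprintf("S%04d", seq_len(n))
  clin <- data.frame(sample_id = ids,
                     arm = rep_len(arm, n),
                     pfs_time = time, pfs_event = event,
                     os_time = os_time, os_event = os_event,
                     stringsAsFactors = FALSE)
  if (!is.null(response)) clin$response <- response
  if (!is.null(sld)) clin$sld <- sld
  if (!is.null(tmb)) clin$tmb <- tmb
  m <- matrix(0L, n, 1, dimnames = list(ids, "DUMMY"))
  cohort_dataset(m, clin)
}

# Step-effect survival fixture: hazard multiplied by `step_hr` when
# score >= threshold; exponential times, optional uniform censoring.
step_cohort <- function(n, threshold = 3L, step_hr = 0.5, h0 = 0.15,
                        score_size = 10L, score_prob = 0.25,
                        censor_max = Inf, seed = 1L) {
  set.seed(seed)
  score <- rbinom(n, score_size, score_prob)
  rate <- h0 * ifelse(score >= threshold, step_hr, 1)
  t_ev <- rexp(n, rate)
  cens <- if (is.finite(censor_max)) runif(n, 0, censor_max) else rep(Inf, n)
  time <- pmin(t_ev, cens)
  event <- as.integer(t_ev <= cens)
  list(cohort = clinical_only_cohort(pmax(time, 1e-6), event),
       score = score, threshold = threshold)
}

# Planted-signal world used for panel recovery (the spec-scale version lives
# in the acceptance tests; `scale` shrinks it for unit tests).
planted_signal_config <- function(seed, n_patients = 1600L, n_genes = 400L,
                                  n_benefit_genes = 20L) {
  mean_score <- n_benefit_genes * 0.225  # middle of the frequency range
  simulation_config(
    n_patients = n_patients, n_genes = n_genes,
    n_benefit_genes = n_benefit_genes,
    mutation_freq_range = c(0.15, 0.30), arm_ratio = 0.5,
    response_intercept = -mean_score * log(4),
    response_score_by_arm_slope = log(4),
    seed = seed
  )
}

# Brute-force OLS Chow oracle built on lm(): independent of the package's
# closed-form implementation.
chow_oracle <- function(x, y, break_index) {
  i1 <- seq_len(break_index)
  i2 <- (break_index + 1L):length(x)
  rss <- function(idx) sum(resid(lm(y[idx] ~ x[idx]))^2)
  rss_p <- sum(resid(lm(y ~ x))^2)
  rss_1 <- rss(i1)
  rss_2 <- rss(i2)
  n <- length(x)
  f <- ((rss_p - rss_1 - rss_2) / 2) / ((rss_1 + rss_2) / (n - 4))
  list(f = f, p = pf(f, 2, n - 4, lower.tail = FALSE))
}

# Exhaustive pairwise AUC oracle with 0.5 tie credit.
auc_oracle <- function(marker, label) {
  pos <- marker[label == 1]
  neg <- marker[label == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
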