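#' Univariate Cox proportional-hazards contrast
#'
#' @param time,event survival times (positive) and 0/1 event indicators.
#' @param covariate numeric (continuous) or 0/1 (binary) covariate.
#' @param covariate_kind `"binary"` or `"continuous"`; for binary covariates
#'   per-group medians and the log-rank p-value are included.
#' @param label free-text label naming the comparison.
#' @return A `survival_contrast` list: `label`, `hr`, `ci_low`, `ci_high`,
#'   `p` (Wald), `logrank_p` (binary only), `n`, `events`, `medians`
#'   (binary only, NA = not reached).
#' @export
fit_cox <- function(time, event, covariate,
                    covariate_kind = c("binary", "continuous"),
                    label = "") {
  covariate_kind <- match.arg(covariate_kind)
  stopifnot(length(time) == length(event), length(time) == length(covariate))
  if (length(unique(covariate)) < 2L) {
    stop("unidentifiable: covariate is constant", call. = FALSE)
  }
  if (sum(event) < 1) stop("no events observed", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- beta / se
  out <- list(
    label = label,
    hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(z)),
    wald = z^2,
    n = length(time),
    events = sum(event)
  )
  if (covariate_kind == "binary") {
    stopifnot(all(covariate %in% c(0, 1)))
    km <- km_curve(time, event, covariate)
    out$medians <- km$medians
    out$logrank_p <- km$logrank_p
    out$n_by_group <- table(covariate)
  }
  class(out) <- "survival_contrast"
  out
}

#' @export
print.survival_contrast <- function(x, ...) {
  cat(sprintf("%s: HR %.3f (95%% CI %.3f-%.3f), P=%.3g [n=%d, events=%d]\n",
              if (nzchar(x$label)) x$label else "contrast",
              x$hr, x$ci_low, x$ci_high, x$p, x$n, x$events))
  invisible(x)
}

#' Kaplan-Meier curves, medians, and log-rank test
#'
#' Product-limit estimates per group. The median is the first time at which
#' survival drops to 0.5 or below; `NA` means not reached (never reported as
#' the last observed time). The log-rank p-value is two-sided and only
#' computed for >= 2 groups.
#'
#' @param time,event survival data.
#' @param groups group labels (any atomic vector); each group must be
#'   non-empty.
#' @return List: `curves` (data.frame `group`, `time`, `surv`, `n_risk`,
#'   `n_event`), `medians` (named numeric), `logrank_p`.
#' @export
km_curve <- function(time, event, groups) {
  stopifnot(length(time) == length(event), length(time) == length(groups))
  g <- if (is.factor(groups)) groups else factor(groups)
  if (any(table(g) == 0L)) stop("empty group", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  if (nlevels(g) == 1L) {
    curves <- data.frame(group = levels(g), time = sf$time, surv = sf$surv,
                         n_risk = sf$n.risk, n_event = sf$n.event)
    logrank_p <- NA_real_
  } else {
    strata_grp <- sub("^g=", "", rep(names(sf$strata), sf$strata))
    curves <- data.frame(group = strata_grp, time = sf$time, surv = sf$surv,
                         n_risk = sf$n.risk, n_event = sf$n.event)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    logrank_p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1L,
                               lower.tail = FALSE)
  }
  # median = first time the product-limit curve reaches 0.5 or below;
  # NA when it never does (reported as "not reached", never the last time)
  medians <- vapply(levels(g), function(lv) {
    cc <- curves[curves$group == lv, , drop = FALSE]
    hit <- cc$time[cc$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  list(curves = curves, medians = medians, logrank_p = logrank_p)
}

#' Objective response rates per stratum and arm
#'
#' Responder = CR or PR; NE/missing responses are excluded from denominators.
#' Empty (stratum, arm) cells are flagged, never divided by zero.
#'
#' @param response character vector of CR/PR/SD/PD/NE (NA allowed).
#' @param strata 0/1 stratum labels (e.g. benefit group).
#' @param arms `"treated"`/`"control"` per patient.
#' @param stratum_labels length-2 names for strata 0 and 1.
#' @return An `orr_table` data.frame: `stratum`, `arm`, `n`, `responders`,
#'   `orr`; plus attribute `diffs` with within-stratum (treated - control)
#'   and within-arm (high - low stratum) absolute ORR differences.
#' @export
orr_compare <- function(response, strata, arms,
                        stratum_labels = c("low", "high")) {
  stopifnot(length(response) == length(strata),
            length(response) == length(arms))
  evaluable <- !is.na(response) & response %in% c("CR", "PR", "SD", "PD")
  resp <- response %in% c("CR", "PR")
  rows <- list()
  for (s in c(0, 1)) {
    for (a in c("treated", "control")) {
      sel <- evaluable & strata == s & arms == a
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum_labels[s + 1L], arm = a, n = n,
        responders = sum(resp[sel]),
        orr = if (n > 0) sum(resp[sel]) / n else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  orr_of <- function(s, a) out$orr[out$stratum == s & out$arm == a]
  diffs <- c(
    treated_vs_control_high = orr_of(stratum_labels[2], "treated") -
      orr_of(stratum_labels[2], "control"),
    treated_vs_control_low = orr_of(stratum_labels[1], "treated") -
      orr_of(stratum_labels[1], "control"),
    high_vs_low_treated = orr_of(stratum_labels[2], "treated") -
      orr_of(stratum_labels[1], "treated"),
    high_vs_low_control = orr_of(stratum_labels[2], "control") -
      orr_of(stratum_labels[1], "control")
  )
  attr(out, "diffs") <- diffs
  if (any(out$n == 0L)) attr(out, "empty_cells") <- TRUE
  class(out) <- c("orr_table", "data.frame")
  out
}

#' Responder AUC with a percentile-bootstrap confidence interval
#'
#' AUC is the Mann-Whitney probability (0.5 credit for ties) that a responder
#' outscores a non-responder; the CI resamples patients with replacement.
#'
#' @param marker numeric marker values.
#' @param responder 0/1 responder labels (both classes required).
#' @param n_bootstrap bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return List: `auc`, `ci_low`, `ci_high`, `n_bootstrap`.
#' @export
responder_auc <- function(marker, responder, n_bootstrap = 2000L, seed = 1L,
                          conf = 0.95) {
  stopifnot(length(marker) == length(responder))
  auc <- auc_mann_whitney(marker, responder)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n <- length(marker)
  boots <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(responder[idx])) < 2L) return(NA_real_)
    auc_mann_whitney(marker[idx], responder[idx])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(auc = auc, ci_low = qs[1], ci_high = qs[2], n_bootstrap = n_bootstrap)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a two-sided p-value
#' (t-approximation); incomplete pairs are dropped (pairwise-complete).
#'
#' @param a,b numeric vectors of equal length (>= 3 complete pairs).
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_rho <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(a), rank(b))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Head-to-head evaluation report: benefit score vs TMB
#'
#' Assembles, for each arm and each endpoint (PFS, OS): the continuous-score
#' Cox contrast, the benefit-vs-non-benefit contrast, and the same pair for
#' TMB; treated-vs-control contrasts within each stratum of each marker; ORR
#' tables per marker; treated-arm responder AUC per marker; Spearman
#' correlations of score with TMB and SLD; and KM coordinates for the main
#' stratified comparisons. Degenerate strata are flagged in `$flags` rather
#' than silently dropped.
#'
#' @param dataset a [cohort_dataset()] with both arms.
#' @param panel gene panel (data.frame or character vector).
#' @param score_cutoff benefit iff score >= this (default 2).
#' @param tmb_high_cutoff TMB-high cutoff, mutations/Mb (default 10).
#' @param tmb_region_mb megabases for TMB derivation (default 1.1).
#' @param n_bootstrap bootstrap reps for AUC CIs (default 2000).
#' @param seed seed for the bootstrap.
#' @return An `evaluation_report` list: `contrasts` (list of
#'   `survival_contrast`), `orr` (per marker), `auc` (per marker),
#'   `spearman`, `km`, `flags`, `config`.
#' @export
build_report <- function(dataset, panel, score_cutoff = 2L,
                         tmb_high_cutoff = 10, tmb_region_mb = 1.1,
                         n_bootstrap = 2000L, seed = 1L) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  scored <- score_cohort(dataset, panel, score_cutoff, tmb_high_cutoff,
                         tmb_region_mb)
  flags <- character(0)
  arms_present <- unique(scored$arm)
  if (!all(c("treated", "control") %in% arms_present)) {
    flags <- c(flags, paste("missing arm:",
                            setdiff(c("treated", "control"), arms_present)))
  }
  contrasts <- list()
  add_contrast <- function(lbl, expr) {
    res <- tryCatch(expr, error = function(e) {
      flags <<- c(flags, paste0(lbl, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) { res$label <- lbl; contrasts[[lbl]] <<- res }
    invisible(NULL)
  }
  groups <- list(score = "benefit_group", tmb = "tmb_group")
  markers <- list(score = "score", tmb = "tmb")

  for (ep in c("pfs", "os")) {
    tm <- scored[[paste0(ep, "_time")]]
    ev <- scored[[paste0(ep, "_event")]]
    for (mk in names(markers)) {
      for (a in intersect(c("treated", "control"), arms_present)) {
        sel <- scored$arm == a
        add_contrast(
          sprintf("%s_continuous_%s_%s", mk, ep, a),
          fit_cox(tm[sel], ev[sel], scored[[markers[[mk]]]][sel],
                  "continuous"))
        add_contrast(
          sprintf("%s_group_%s_%s", mk, ep, a),
          fit_cox(tm[sel], ev[sel], scored[[groups[[mk]]]][sel], "binary"))
      }
      for (s in c(0, 1)) {
        sel <- scored[[groups[[mk]]]] == s
        if (length(unique(scored$arm[sel])) < 2L) {
          flags <- c(flags, sprintf("degenerate stratum: %s=%d", mk, s))
          next
        }
        add_contrast(
          sprintf("arm_%s_%s_%s", ep, mk,
                  c("nonbenefit", "benefit")[s + 1L]),
          fit_cox(tm[sel], ev[sel],
                  as.integer(scored$arm[sel] == "treated"), "binary"))
      }
    }
  }

  orr <- list()
  auc <- list()
  if (!is.null(scored$response)) {
    orr$score <- orr_compare(scored$response, scored$benefit_group,
                             scored$arm,
                             c("non-benefit", "benefit"))
    orr$tmb <- orr_compare(scored$response, scored$tmb_group, scored$arm,
                           c("TMB-low", "TMB-high"))
    treated <- scored$arm == "treated" &
      scored$response %in% c("CR", "PR", "SD", "PD")
    responder <- as.integer(scored$response[treated] %in% c("CR", "PR"))
    if (length(unique(responder)) == 2L) {
      auc$score <- responder_auc(scored$score[treated], responder,
                                 n_bootstrap, seed)
      auc$tmb <- responder_auc(scored$tmb[treated], responder,
                               n_bootstrap, seed)
    } else {
      flags <- c(flags, "responder AUC skipped: one response class")
    }
  } else {
    flags <- c(flags, "no response column: ORR and AUC omitted")
  }

  spearman <- list(score_vs_tmb = spearman_rho(scored$score, scored$tmb))
  if (!is.null(scored$sld)) {
    spearman$score_vs_sld <- spearman_rho(scored$score, scored$sld)
  }

  km <- list()
  for (ep in c("pfs", "os")) {
    for (a in intersect(c("treated", "control"), arms_present)) {
      sel <- scored$arm == a
      if (length(unique(scored$benefit_group[sel])) == 2L) {
        km[[sprintf("%s_%s_by_benefit", ep, a)]] <- km_curve(
          scored[[paste0(ep, "_time")]][sel],
          scored[[paste0(ep, "_event")]][sel],
          c("non-benefit", "benefit")[scored$benefit_group[sel] + 1L])
      }
    }
  }

  structure(list(
    contrasts = contrasts, orr = orr, auc = auc, spearman = spearman,
    km = km, flags = flags,
    config = list(score_cutoff = score_cutoff,
                  tmb_high_cutoff = tmb_high_cutoff,
                  tmb_region_mb = tmb_region_mb,
                  n_bootstrap = n_bootstrap, seed = seed)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", length(x$contrasts), " survival contrasts\n",
      sep = "")
  for (key in grep("group_pfs", names(x$contrasts), value = TRUE)) {
    print(x$contrasts[[key]])
  }
  if (length(x$auc)) {
    for (mk in names(x$auc)) {
      cat(sprintf("  responder AUC (%s): %.3f (%.3f-%.3f)\n", mk,
                  x$auc[[mk]]$auc, x$auc[[mk]]$ci_low, x$auc[[mk]]$ci_high))
    }
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON (and back)
#'
#' Lossless for all numeric content; `report_from_json` restores the nested
#' list structure (classes are re-attached to contrasts).
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return `report_to_json` invisibly returns `path`.
#' @export
report_to_json <- function(report, path) {
  stripped <- rapply(unclass(report), function(z) z, how = "replace")
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
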