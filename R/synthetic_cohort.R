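#' Configuration for the synthetic two-arm trial simulator
#'
#' Describes a randomized two-arm (immunotherapy vs chemotherapy) cohort with a
#' planted panel of benefit genes. Each gene mutates independently per patient
#' with a per-gene Bernoulli rate drawn uniformly from `mutation_freq_range`.
#' The patient's benefit score is the count of mutated planted genes; survival
#' times are exponential with hazard
#'
#' \deqn{h = h_0 \exp(a \beta_{trt} + a s \beta_{trt/mut} + (1-a) s \beta_{ctl/mut})}
#'
#' where `a` is the treated-arm indicator and `s` the planted score, so each
#' planted mutation improves hazard in the treated arm
#' (`log_hr_treated_per_mutation < 0`) while leaving (or worsening) the control
#' arm. Objective response is Bernoulli on the logit scale with a
#' treatment-by-score interaction. Censoring is administrative:
#' uniform(0, `censor_time_max`) per patient, independent of covariates.
#'
#' Defaults emulate a second-line NSCLC trial population of ~850 patients
#' randomized ~1:1, profiled on a ~400-gene targeted panel: median PFS around 4
#' months and median OS around 10 months in the reference arm, follow-up capped
#' at 30 months, a control-arm response rate near 10%, and baseline tumor
#' burden (SLD) around 75 mm.
#'
#' @param n_patients number of patients.
#' @param n_genes number of genes on the simulated panel.
#' @param n_benefit_genes number of planted benefit genes (must be
#'   `<= n_genes`).
#' @param mutation_freq_range length-2 numeric in \[0,1\]; per-gene mutation
#'   rates are drawn uniformly from this interval.
#' @param arm_ratio probability of assignment to the treated arm.
#' @param log_hr_treated_per_mutation per-planted-mutation log hazard ratio in
#'   the treated arm (negative = benefit).
#' @param log_hr_control_per_mutation per-planted-mutation log hazard ratio in
#'   the control arm.
#' @param log_hr_treatment_main main-effect log hazard ratio of treatment.
#' @param baseline_hazard_pfs,baseline_hazard_os baseline exponential hazards,
#'   events per month; must be positive.
#' @param censor_time_max administrative censoring horizon in months; each
#'   patient's censoring time is uniform(0, `censor_time_max`). `Inf` disables
#'   censoring.
#' @param response_intercept intercept of the responder logit model.
#' @param response_score_by_arm_slope logit increase per planted mutation in
#'   the treated arm (treatment-by-score interaction).
#' @param sld_mean,sld_sd mean and sd (mm) of baseline sum of longest
#'   diameters; draws are truncated below at 10 mm.
#' @param seed integer seed; identical configs reproduce bit-identical cohorts.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_patients = 850L,
                              n_genes = 400L,
                              n_benefit_genes = 20L,
                              mutation_freq_range = c(0.02, 0.25),
                              arm_ratio = 0.5,
                              log_hr_treated_per_mutation = log(0.80),
                              log_hr_control_per_mutation = log(1.05),
                              log_hr_treatment_main = 0,
                              baseline_hazard_pfs = log(2) / 4,
                              baseline_hazard_os = log(2) / 10,
                              censor_time_max = 30,
                              response_intercept = stats::qlogis(0.10),
                              response_score_by_arm_slope = log(1.5),
                              sld_mean = 75,
                              sld_sd = 30,
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_genes = as.integer(n_genes),
    n_benefit_genes = as.integer(n_benefit_genes),
    mutation_freq_range = as.numeric(mutation_freq_range),
    arm_ratio = as.numeric(arm_ratio),
    log_hr_treated_per_mutation = as.numeric(log_hr_treated_per_mutation),
    log_hr_control_per_mutation = as.numeric(log_hr_control_per_mutation),
    log_hr_treatment_main = as.numeric(log_hr_treatment_main),
    baseline_hazard_pfs = as.numeric(baseline_hazard_pfs),
    baseline_hazard_os = as.numeric(baseline_hazard_os),
    censor_time_max = as.numeric(censor_time_max),
    response_intercept = as.numeric(response_intercept),
    response_score_by_arm_slope = as.numeric(response_score_by_arm_slope),
    sld_mean = as.numeric(sld_mean),
    sld_sd = as.numeric(sld_sd),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_patients >= 1L, cfg$n_genes >= 1L,
    length(cfg$mutation_freq_range) == 2L,
    all(cfg$mutation_freq_range >= 0), all(cfg$mutation_freq_range <= 1),
    cfg$mutation_freq_range[1] <= cfg$mutation_freq_range[2],
    cfg$arm_ratio >= 0, cfg$arm_ratio <= 1,
    cfg$censor_time_max > 0, cfg$sld_sd >= 0,
    length(cfg$seed) == 1L, !is.na(cfg$seed)
  )
  if (cfg$n_benefit_genes > cfg$n_genes) {
    stop("n_benefit_genes (", cfg$n_benefit_genes,
         ") exceeds n_genes (", cfg$n_genes, ")", call. = FALSE)
  }
  if (cfg$n_benefit_genes < 0L) stop("n_benefit_genes must be >= 0", call. = FALSE)
  if (!(cfg$baseline_hazard_pfs > 0) || !(cfg$baseline_hazard_os > 0)) {
    stop("baseline hazards must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Construct a cohort dataset
#'
#' The central container joining a binary patient-by-gene mutation matrix with
#' per-patient clinical outcomes. Times must be positive and events 0/1; the
#' matrix must be strictly binary with unique gene symbols. `pfs_time <=
#' os_time` is deliberately NOT enforced: real trial exports violate it.
#'
#' @param mutations binary integer matrix, patients x genes, with rownames
#'   (patient ids) and colnames (gene symbols).
#' @param clinical data.frame with one row per patient: `sample_id`, `arm`
#'   (`"treated"`/`"control"`), `pfs_time`, `pfs_event`, `os_time`, `os_event`,
#'   and optionally `response` (CR/PR/SD/PD/NE), `sld`, `tmb`.
#' @param truth optional character vector of planted benefit genes (simulated
#'   cohorts only).
#' @return An object of class `cohort_dataset`: list with elements `mutations`,
#'   `clinical`, `truth`.
#' @export
cohort_dataset <- function(mutations, clinical, truth = NULL) {
  stopifnot(is.matrix(mutations), !is.null(rownames(mutations)),
            !is.null(colnames(mutations)))
  if (anyDuplicated(colnames(mutations))) {
    stop("duplicate gene symbols in mutation matrix", call. = FALSE)
  }
  if (anyDuplicated(rownames(mutations))) {
    stop("duplicate patient ids in mutation matrix", call. = FALSE)
  }
  storage.mode(mutations) <- "integer"
  if (!all(mutations %in% c(0L, 1L))) {
    stop("mutation matrix must be strictly binary", call. = FALSE)
  }
  req <- c("sample_id", "arm", "pfs_time", "pfs_event", "os_time", "os_event")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(clinical$sample_id)) {
    stop("clinical table has duplicate sample_id", call. = FALSE)
  }
  if (!setequal(clinical$sample_id, rownames(mutations)) ||
      nrow(clinical) != nrow(mutations)) {
    stop("clinical sample_ids and mutation matrix rows do not match",
         call. = FALSE)
  }
  clinical <- clinical[match(rownames(mutations), clinical$sample_id), ,
                       drop = FALSE]
  rownames(clinical) <- NULL
  for (col in c("pfs", "os")) {
    tm <- clinical[[paste0(col, "_time")]]
    ev <- clinical[[paste0(col, "_event")]]
    if (!is.numeric(tm) || any(!is.finite(tm)) || any(tm <= 0)) {
      stop(col, "_time must be positive and finite", call. = FALSE)
    }
    if (!all(ev %in% c(0, 1))) {
      bad <- which(!ev %in% c(0, 1))[1]
      stop(col, "_event must be 0/1; offending row ", bad,
           " (sample ", clinical$sample_id[bad], ")", call. = FALSE)
    }
  }
  if (!all(clinical$arm %in% c("treated", "control"))) {
    stop("arm must be 'treated' or 'control'", call. = FALSE)
  }
  if (!is.null(clinical$response) &&
      !all(is.na(clinical$response) |
           clinical$response %in% c("CR", "PR", "SD", "PD", "NE"))) {
    stop("response must be one of CR/PR/SD/PD/NE (or NA)", call. = FALSE)
  }
  structure(list(mutations = mutations, clinical = clinical, truth = truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$mutations), " patients x ",
      ncol(x$mutations), " genes\n", sep = "")
  cat("  treated: ", sum(x$clinical$arm == "treated"),
      ", control: ", sum(x$clinical$arm == "control"), "\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  planted benefit genes: ", length(x$truth), "\n", sep = "")
  }
  invisible(x)
}

#' Simulate a randomized two-arm trial cohort with a planted benefit panel
#'
#' Draws the cohort described by a [simulation_config()]: gene mutation rates,
#' the binary mutation matrix, arm assignment, exponential PFS/OS with the
#' treatment-by-score hazard interaction, administrative censoring, RECIST-style
#' response labels (responders drawn from the logistic model and emitted as PR,
#' non-responders as PD), baseline SLD, and TMB derived as total mutated genes
#' per 1.1 Mb. The planted genes (the first `n_benefit_genes` columns, named
#' `BG001...`) are recorded in the `truth` field.
#'
#' @param config a [simulation_config()].
#' @return A [cohort_dataset()] with `truth` populated.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 50, n_genes = 30,
#'                                             n_benefit_genes = 5, seed = 7))
#' cohort
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  validate_simulation_config(config)
  n <- config$n_patients
  p <- config$n_genes
  nb <- config$n_benefit_genes

  genes <- c(
    if (nb > 0) sprintf("BG%03d", seq_len(nb)),
    if (p - nb > 0) sprintf("NG%03d", seq_len(p - nb))
  )
  ids <- sprintf("P%04d", seq_len(n))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  freqs <- stats::runif(p, config$mutation_freq_range[1],
                        config$mutation_freq_range[2])
  mut <- matrix(stats::rbinom(n * p, 1L, rep(freqs, each = n)),
                nrow = n, ncol = p, dimnames = list(ids, genes))
  storage.mode(mut) <- "integer"

  arm <- ifelse(stats::runif(n) < config$arm_ratio, "treated", "control")
  a <- as.integer(arm == "treated")
  score <- if (nb > 0) as.integer(rowSums(mut[, seq_len(nb), drop = FALSE])) else
    integer(n)

  lin <- a * config$log_hr_treatment_main +
    a * score * config$log_hr_treated_per_mutation +
    (1 - a) * score * config$log_hr_control_per_mutation
  pfs_t <- stats::rexp(n, rate = config$baseline_hazard_pfs * exp(lin))
  os_t <- stats::rexp(n, rate = config$baseline_hazard_os * exp(lin))
  cens <- if (is.finite(config$censor_time_max)) {
    stats::runif(n, 0, config$censor_time_max)
  } else rep(Inf, n)

  pfs_event <- as.integer(pfs_t <= cens)
  os_event <- as.integer(os_t <= cens)
  pfs_time <- pmax(pmin(pfs_t, cens), 1e-6)
  os_time <- pmax(pmin(os_t, cens), 1e-6)

  p_resp <- stats::plogis(config$response_intercept +
                            a * score * config$response_score_by_arm_slope)
  responder <- stats::rbinom(n, 1L, p_resp)
  response <- ifelse(responder == 1L, "PR", "PD")

  sld <- pmax(10, stats::rnorm(n, config$sld_mean, config$sld_sd))
  tmb <- rowSums(mut) / 1.1

  clinical <- data.frame(
    sample_id = ids, arm = arm,
    pfs_time = pfs_time, pfs_event = pfs_event,
    os_time = os_time, os_event = os_event,
    response = response, sld = sld, tmb = tmb,
    stringsAsFactors = FALSE
  )
  ds <- cohort_dataset(mut, clinical,
                       truth = if (nb > 0) genes[seq_len(nb)] else character(0))
  # generative per-gene rates, kept for property checks on the simulator
  ds$sim_freqs <- stats::setNames(freqs, genes)
  ds
}

#' Planted benefit genes of a simulated cohort
#'
#' @param dataset a [cohort_dataset()] produced by [simulate_cohort()].
#' @return Character vector of planted gene symbols.
#' @export
true_panel <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(dataset$truth)) {
    stop("dataset has no truth field: not a simulated cohort", call. = FALSE)
  }
  dataset$truth
}
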