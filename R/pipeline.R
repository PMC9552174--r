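#' Assemble a full pipeline run configuration
#'
#' Exactly one of `simulation` (a [simulation_config()] or list of its
#' arguments) or `inputs` (list with `mutations`, `clinical`, optionally
#' `dialect`, `gene_universe` file paths) must be supplied. All stage seeds
#' derive deterministically from `seed`, so stages rerun standalone reproduce
#' the pipeline's outputs.
#'
#' @param simulation simulation settings, or NULL when reading files.
#' @param inputs input file paths, or NULL when simulating.
#' @param selection a [selection_config()] or argument list.
#' @param score_cutoff benefit-score cutoff; `NULL` (default) means determine
#'   it with the cutpoint stage.
#' @param tmb_high_cutoff TMB-high threshold, mutations/Mb.
#' @param cutpoint list of cutpoint options (`endpoint`, `span`,
#'   `min_group_size`, `min_events`, `smooth`).
#' @param evaluation list of evaluation options (`n_bootstrap`).
#' @param out_dir output directory.
#' @param seed global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, inputs = NULL,
                       selection = list(), score_cutoff = NULL,
                       tmb_high_cutoff = 10,
                       cutpoint = list(), evaluation = list(),
                       out_dir = "panelsieve_run", seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of 'simulation' or 'inputs' must be supplied",
         call. = FALSE)
  }
  cfg <- list(
    simulation = simulation, inputs = inputs, selection = selection,
    score_cutoff = score_cutoff, tmb_high_cutoff = tmb_high_cutoff,
    cutpoint = utils::modifyList(
      list(endpoint = "pfs", span = 0.80, min_group_size = 20L,
           min_events = 5L, smooth = FALSE), cutpoint),
    evaluation = utils::modifyList(list(n_bootstrap = 2000L), evaluation),
    out_dir = out_dir, seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

# Deterministic stage-seed derivation from the global seed: distinct fixed
# offsets folded into 31 bits so every derived seed stays a valid R integer.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, select = 202L, evaluate = 303L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483647L
}

#' Run the full pipeline: simulate/load, select, score, cutpoint, evaluate
#'
#' Executes every stage, writing each stage's outputs under
#' `config$out_dir`: the cohort tables, the selected panel
#' (`panel.txt`, `panel_detail.tsv`), the stability trace
#' (`stability_trace.tsv`), the scored cohort (`scored.tsv`), the HR curve
#' and cutpoint (`hr_curve.tsv`, `cutpoint.json`), the evaluation report
#' (`report.json`), a run log (`log.txt`), and a resolved-config snapshot
#' (`config.json`) sufficient to reproduce the run bit-identically. A stage
#' failure aborts with the stage name; outputs of completed stages persist.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `selection`, `scored`, `curve`, `cutpoint`, `report`, `paths`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("ERROR in stage '", name, "': ",
                                     conditionMessage(e))),
                 file.path(config$out_dir, "log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage: cohort -------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      if (!inherits(sim, "simulation_config")) {
        if (is.null(sim$seed)) sim$seed <- derive_seed(config$seed, "simulate")
        sim <- do.call(simulation_config, sim)
      }
      config$simulation <- sim
      note("simulating cohort: ", sim$n_patients, " patients x ",
           sim$n_genes, " genes (seed ", sim$seed, ")")
      simulate_cohort(sim)
    } else {
      note("reading cohort from ", config$inputs$mutations)
      mut <- read_mutations(config$inputs$mutations,
                            dialect = config$inputs$dialect %||% "long")
      clin <- read_clinical(config$inputs$clinical)
      universe <- if (!is.null(config$inputs$gene_universe)) {
        read_gene_list(config$inputs$gene_universe)
      }
      build_dataset(mut, clin, gene_universe = universe)
    }
  })
  write_cohort(cohort, file.path(config$out_dir, "cohort"))
  note("cohort: ", nrow(cohort$mutations), " patients, ",
       ncol(cohort$mutations), " genes, ",
       sum(cohort$clinical$arm == "treated"), " treated")

  # --- stage: panel selection ---------------------------------------------
  selection <- stage("select", {
    sel_cfg <- config$selection
    if (!inherits(sel_cfg, "selection_config")) {
      if (is.null(sel_cfg$seed)) sel_cfg$seed <- derive_seed(config$seed,
                                                             "select")
      sel_cfg <- do.call(selection_config, sel_cfg)
    }
    config$selection <- sel_cfg
    note("selecting panel: ", sel_cfg$n_repetitions, " repetitions, top_k ",
         sel_cfg$top_k, ", mode ", sel_cfg$mode)
    select_panel(cohort, sel_cfg)
  })
  panel <- selection$panel
  writeLines(panel$gene, file.path(config$out_dir, "panel.txt"))
  utils::write.table(panel, file.path(config$out_dir, "panel_detail.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(selection$trace,
                     file.path(config$out_dir, "stability_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("panel: ", nrow(panel), " genes; plateau at ",
       ifelse(is.na(selection$plateau_at), "none", selection$plateau_at))

  # --- stage: scoring + cutpoint ------------------------------------------
  scores <- stage("score", ici_benefit_score(cohort, panel))
  cutres <- NULL
  curve <- NULL
  cutoff <- config$score_cutoff
  if (is.null(cutoff)) {
    cp <- config$cutpoint
    curve <- stage("cutpoint", hr_curve(
      cohort, scores, arm = "treated", endpoint = cp$endpoint,
      min_group_size = cp$min_group_size, min_events = cp$min_events,
      span = cp$span))
    cutres <- stage("cutpoint", select_cutoff(curve, smooth = cp$smooth))
    cutoff <- cutres$cutoff
    utils::write.table(as.data.frame(curve),
                       file.path(config$out_dir, "hr_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cutoff = cutres$cutoff,
           significant_break = cutres$significant_break,
           chow = cutres$chow, elbow_range = cutres$elbow_range),
      file.path(config$out_dir, "cutpoint.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    note("cutpoint: score >= ", cutoff,
         if (!cutres$significant_break) " (no significant structural break)")
  } else {
    note("cutpoint: fixed at score >= ", cutoff)
  }
  scored <- stage("score", score_cohort(cohort, panel, cutoff,
                                        config$tmb_high_cutoff))
  utils::write.table(scored, file.path(config$out_dir, "scored.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: evaluation ---------------------------------------------------
  report <- stage("evaluate", build_report(
    cohort, panel, score_cutoff = cutoff,
    tmb_high_cutoff = config$tmb_high_cutoff,
    n_bootstrap = config$evaluation$n_bootstrap,
    seed = derive_seed(config$seed, "evaluate")))
  report_to_json(report, file.path(config$out_dir, "report.json"))
  if (length(report$flags)) {
    note("evaluation flags: ", paste(report$flags, collapse = "; "))
  }

  snapshot <- config
  snapshot$simulation <- if (!is.null(config$simulation)) {
    unclass(config$simulation)
  }
  snapshot$selection <- unclass(config$selection)
  jsonlite::write_json(unclass(snapshot),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  invisible(list(cohort = cohort, selection = selection, scored = scored,
                 curve = curve, cutpoint = cutres, report = report,
                 paths = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
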