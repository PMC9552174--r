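#' Configuration for stability-based panel selection
#'
#' Controls the repeated-modeling loop: each repetition draws a fresh
#' stratified train/validation split of the treated-arm labeled patients
#' (default 8/2), fits a gradient-boosted tree classifier, and ranks genes by
#' importance. The panel is, by default, the set of genes appearing in at
#' least a fraction `freq_threshold` of the per-repetition top-`top_k` sets
#' (`mode = "frequency"`; 0.8 is the conventional stability-selection
#' threshold). `mode = "intersection"` takes the strict intersection of the
#' top-k sets instead; it is fragile — held-out permutation importance is
#' noisy enough that even a strongly predictive gene occasionally drops out
#' of one repetition's top-k, and a single drop removes it for good.
#'
#' @param n_repetitions number of modeling repetitions (default 350).
#' @param train_fraction training split fraction (default 0.8).
#' @param top_k genes retained per repetition (default 150, sized for a
#'   ~400-gene universe; the stability trace is the diagnostic for tuning it).
#' @param label_spec `"responder"` (CR/PR vs SD/PD, the default) or
#'   `"pfs_ge_m"` with `label_months`.
#' @param label_months months threshold for the `pfs_ge_m` label (default 6).
#' @param importance `"permutation_auc"` (held-out mean AUC decrease, the
#'   default) or `"native_gain"` (total split gain).
#' @param n_permutation_shuffles shuffles averaged per gene (default 5).
#' @param mode `"frequency"` (default) or `"intersection"` (strict).
#' @param freq_threshold top-k inclusion frequency cutoff for
#'   `mode = "frequency"` (default 0.8).
#' @param stability_window consecutive repetitions with an unchanged running
#'   intersection required to declare a plateau (default 25).
#' @param base_learner_params named list overriding [gbt_fit()] defaults
#'   (`nrounds`, `max_depth`, `eta`, `lambda`, `min_child_weight`).
#' @param seed integer seed; all per-repetition seeds derive from it.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_repetitions = 350L,
                             train_fraction = 0.8,
                             top_k = 150L,
                             label_spec = c("responder", "pfs_ge_m"),
                             label_months = 6,
                             importance = c("permutation_auc", "native_gain"),
                             n_permutation_shuffles = 5L,
                             mode = c("frequency", "intersection"),
                             freq_threshold = 0.8,
                             stability_window = 25L,
                             base_learner_params = list(),
                             seed = 1L) {
  cfg <- list(
    n_repetitions = as.integer(n_repetitions),
    train_fraction = as.numeric(train_fraction),
    top_k = as.integer(top_k),
    label_spec = match.arg(label_spec),
    label_months = as.numeric(label_months),
    importance = match.arg(importance),
    n_permutation_shuffles = as.integer(n_permutation_shuffles),
    mode = match.arg(mode),
    freq_threshold = as.numeric(freq_threshold),
    stability_window = as.integer(stability_window),
    base_learner_params = base_learner_params,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_repetitions >= 1L, cfg$top_k >= 1L,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$n_permutation_shuffles >= 1L, cfg$stability_window >= 1L)
  class(cfg) <- "selection_config"
  cfg
}

#' Build the binary training label for panel selection
#'
#' Restricted to treated-arm patients. `responder`: 1 for CR/PR, 0 for SD/PD,
#' NE/missing masked out. `pfs_ge_m`: 1 if `pfs_time >= m` (regardless of
#' event status), 0 if the event occurred before `m`; patients censored before
#' `m` are masked (their status at `m` is unknown).
#'
#' @param dataset a [cohort_dataset()].
#' @param label_spec `"responder"` or `"pfs_ge_m"`.
#' @param months threshold for `pfs_ge_m`.
#' @return List with `label` (0/1, length = treated patients, NA where
#'   masked), `mask` (logical usable-patient mask), and `sample_id`.
#' @export
make_label <- function(dataset, label_spec = c("responder", "pfs_ge_m"),
                       months = 6) {
  label_spec <- match.arg(label_spec)
  stopifnot(inherits(dataset, "cohort_dataset"))
  cl <- dataset$clinical
  treated <- cl$arm == "treated"
  cl <- cl[treated, , drop = FALSE]
  if (label_spec == "responder") {
    if (is.null(cl$response)) {
      stop("label_spec 'responder' requires a response column", call. = FALSE)
    }
    label <- ifelse(cl$response %in% c("CR", "PR"), 1L,
                    ifelse(cl$response %in% c("SD", "PD"), 0L, NA_integer_))
  } else {
    label <- ifelse(cl$pfs_time >= months, 1L,
                    ifelse(cl$pfs_event == 1L, 0L, NA_integer_))
  }
  list(label = label, mask = !is.na(label), sample_id = cl$sample_id,
       treated_rows = which(treated))
}

#' One panel-selection repetition: split, fit, rank
#'
#' Draws a stratified `train_fraction` split of the labeled patients, fits the
#' boosted-tree classifier on the training part, and scores every gene:
#' permutation importance (mean held-out AUC decrease over
#' `n_permutation_shuffles` column shuffles) or native total split gain.
#' Ranks order by (importance desc, gene symbol asc); genes the model never
#' uses score exactly 0 and fall after all positive-importance genes.
#'
#' @param x binary matrix of labeled treated patients x genes.
#' @param y 0/1 label vector.
#' @param config a [selection_config()].
#' @param repetition_seed integer seed for this repetition.
#' @return List: `importance` (named numeric), `rank` (named integer,
#'   1 = most important), `validation_auc`, `seed`.
#' @export
run_repetition <- function(x, y, config, repetition_seed) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2L) stop("degenerate label", call. = FALSE)
  if (ncol(x) < config$top_k) {
    stop("fewer genes (", ncol(x), ") than top_k (", config$top_k, ")",
         call. = FALSE)
  }
  genes <- colnames(x)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(repetition_seed)

  # stratified split: sample train_fraction within each class
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  tr <- sort(c(sample(idx1, round(config$train_fraction * length(idx1))),
               sample(idx0, round(config$train_fraction * length(idx0)))))
  va <- setdiff(seq_along(y), tr)
  if (sum(y[tr] == 1) < 20L || sum(y[tr] == 0) < 20L) {
    stop("fewer than 20 training patients in one class (",
         sum(y[tr] == 1), " responders, ", sum(y[tr] == 0),
         " non-responders)", call. = FALSE)
  }
  if (length(unique(y[va])) < 2L) stop("degenerate validation label",
                                       call. = FALSE)

  params <- utils::modifyList(
    list(nrounds = 200L, max_depth = 3L, eta = 0.1, lambda = 1.0,
         min_child_weight = 1.0),
    config$base_learner_params
  )
  model <- do.call(gbt_fit, c(list(x = x[tr, , drop = FALSE], y = y[tr]),
                              params))

  if (config$importance == "permutation_auc") {
    imp <- gbt_permutation_importance(model, x[va, , drop = FALSE], y[va],
                                      config$n_permutation_shuffles)
    validation_auc <- attr(imp, "base_auc")
    attr(imp, "base_auc") <- NULL
  } else {
    imp <- model$gain
    validation_auc <- auc_mann_whitney(predict(model, x[va, , drop = FALSE]),
                                       y[va])
  }
  ord <- order(-imp, genes)
  rk <- integer(length(genes))
  rk[ord] <- seq_along(genes)
  names(rk) <- genes
  list(importance = imp, rank = rk, validation_auc = validation_auc,
       seed = repetition_seed)
}

#' Select a stable gene panel by repeated modeling
#'
#' Runs `n_repetitions` of [run_repetition()] with per-repetition seeds
#' derived deterministically from `config$seed`, takes the top-`top_k` genes
#' of each repetition, and forms the panel by top-k inclusion frequency
#' (default) or as the strict intersection. The stability trace always
#' records the running intersection size after each repetition
#' (non-increasing by construction); a plateau is declared once it is
#' unchanged for `stability_window` consecutive repetitions.
#'
#' @param dataset a [cohort_dataset()].
#' @param config a [selection_config()].
#' @return List of class `panel_selection`: `panel` (a `gene_panel`
#'   data.frame: `gene`, `mean_importance`, `topk_frequency`, ordered by mean
#'   importance desc), `trace` (a `stability_trace` data.frame: `repetition`,
#'   `intersection_size`, `plateau`), `plateau_at` (first plateau repetition
#'   or NA), `rankings` (per-repetition rank matrix, genes x repetitions),
#'   `validation_auc` (per repetition), `config`.
#' @export
select_panel <- function(dataset, config = selection_config()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  lab <- make_label(dataset, config$label_spec, config$label_months)
  rows <- lab$treated_rows[lab$mask]
  x <- dataset$mutations[rows, , drop = FALSE]
  y <- lab$label[lab$mask]
  if (length(unique(y)) < 2L) stop("degenerate label", call. = FALSE)
  genes <- colnames(x)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_repetitions)

  n_rep <- config$n_repetitions
  imp_sum <- numeric(length(genes))
  in_topk <- integer(length(genes))
  names(imp_sum) <- names(in_topk) <- genes
  rank_mat <- matrix(NA_integer_, nrow = length(genes), ncol = n_rep,
                     dimnames = list(genes, NULL))
  vauc <- numeric(n_rep)
  inter_size <- integer(n_rep)
  running <- NULL

  for (r in seq_len(n_rep)) {
    rep_res <- run_repetition(x, y, config, rep_seeds[r])
    rank_mat[, r] <- rep_res$rank
    vauc[r] <- rep_res$validation_auc
    imp_sum <- imp_sum + rep_res$importance
    topk <- genes[rep_res$rank <= config$top_k]
    in_topk[topk] <- in_topk[topk] + 1L
    running <- if (r == 1L) topk else intersect(running, topk)
    inter_size[r] <- length(running)
  }

  w <- config$stability_window
  plateau <- rep(FALSE, n_rep)
  plateau_at <- NA_integer_
  if (n_rep >= w) {
    for (r in w:n_rep) {
      if (length(unique(inter_size[(r - w + 1L):r])) == 1L) {
        plateau[r] <- TRUE
        if (is.na(plateau_at)) plateau_at <- r
      }
    }
  }

  freq <- in_topk / n_rep
  panel_genes <- if (config$mode == "intersection") {
    running
  } else {
    genes[freq >= config$freq_threshold]
  }
  if (length(panel_genes) == 0L) {
    warning("empty final panel (no gene survived selection)", call. = FALSE)
  }
  mean_imp <- imp_sum / n_rep
  ord <- order(-mean_imp[panel_genes], panel_genes)
  panel <- data.frame(
    gene = panel_genes[ord],
    mean_importance = unname(mean_imp[panel_genes][ord]),
    topk_frequency = unname(freq[panel_genes][ord]),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  attr(panel, "config") <- config

  trace <- data.frame(repetition = seq_len(n_rep),
                      intersection_size = inter_size, plateau = plateau)
  class(trace) <- c("stability_trace", "data.frame")

  structure(list(panel = panel, trace = trace, plateau_at = plateau_at,
                 rankings = rank_mat, validation_auc = vauc, config = config),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("<panel_selection> ", nrow(x$panel), " genes after ",
      x$config$n_repetitions, " repetitions (mode: ", x$config$mode, ")\n",
      sep = "")
  cat("  mean validation AUC: ", round(mean(x$validation_auc), 3), "\n",
      sep = "")
  cat("  plateau at repetition: ",
      if (is.na(x$plateau_at)) "not reached" else x$plateau_at, "\n", sep = "")
  invisible(x)
}

#' Restrict a gene panel to the genes measurable by another assay
#'
#' Maps a panel onto a different sequencing panel's gene universe: keeps only
#' panel genes present in `assay_genes`, preserving the original ordering, and
#' reports how many were dropped.
#'
#' @param panel a `gene_panel` data.frame (or plain character vector).
#' @param assay_genes character vector of genes the assay can detect.
#' @return The restricted panel, same class as the input.
#' @export
restrict_panel <- function(panel, assay_genes) {
  genes <- if (is.data.frame(panel)) panel$gene else panel
  keep <- genes %in% assay_genes
  if (!any(keep)) {
    warning("no panel gene detectable by this assay: empty panel",
            call. = FALSE)
  } else if (any(!keep)) {
    message(sum(!keep), " panel gene(s) not detectable by this assay dropped")
  }
  if (is.data.frame(panel)) panel[keep, , drop = FALSE] else panel[keep]
}
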