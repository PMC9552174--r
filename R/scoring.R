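#' ICI-benefit score: mutated panel genes per patient
#'
#' The score of a patient is the number of *distinct* panel genes carrying a
#' mutation (the matrix is binary, so variant multiplicity never counts).
#' Panel genes absent from the dataset's gene universe contribute 0 and are
#' reported.
#'
#' @param dataset a [cohort_dataset()].
#' @param panel a `gene_panel` data.frame or character vector of gene symbols.
#' @return Named integer vector (one score per patient, `0 <= score <=
#'   length(panel)`), with attribute `missing_genes`.
#' @export
ici_benefit_score <- function(dataset, panel) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  genes <- if (is.data.frame(panel)) panel$gene else panel
  present <- intersect(genes, colnames(dataset$mutations))
  missing <- setdiff(genes, present)
  if (length(missing)) {
    message(length(missing), " panel gene(s) absent from dataset contribute 0")
  }
  score <- if (length(present)) {
    as.integer(rowSums(dataset$mutations[, present, drop = FALSE]))
  } else {
    integer(nrow(dataset$mutations))
  }
  names(score) <- rownames(dataset$mutations)
  attr(score, "missing_genes") <- missing
  score
}

#' Tumor mutational burden per megabase
#'
#' @param mutation_count non-negative mutation count(s) per patient.
#' @param region_mb sequenced coding region in megabases (default 1.1, the
#'   F1CDx target region).
#' @return Mutations per Mb.
#' @export
tmb_per_mb <- function(mutation_count, region_mb = 1.1) {
  stopifnot(region_mb > 0, all(mutation_count >= 0))
  mutation_count / region_mb
}

#' TMB for a cohort
#'
#' Uses the clinical table's `tmb` column verbatim when present; otherwise
#' approximates TMB as total mutated genes / `region_mb` from the binary
#' matrix (a documented approximation: the assay counts variants, the matrix
#' counts genes).
#'
#' @param dataset a [cohort_dataset()].
#' @param region_mb megabases (default 1.1).
#' @return Named numeric vector of TMB values.
#' @export
cohort_tmb <- function(dataset, region_mb = 1.1) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!is.null(dataset$clinical$tmb) && !all(is.na(dataset$clinical$tmb))) {
    stats::setNames(dataset$clinical$tmb, dataset$clinical$sample_id)
  } else {
    tmb_per_mb(rowSums(dataset$mutations), region_mb)
  }
}

#' Dichotomize a marker at a cutoff
#'
#' @param values numeric marker values.
#' @param cutoff threshold.
#' @param direction `"ge"` (high group iff `value >= cutoff`, default) or
#'   `"gt"`.
#' @return Integer 0/1 vector (1 = high/benefit group). A degenerate split
#'   (one empty stratum) is flagged via attribute `degenerate` and a warning.
#' @export
stratify <- function(values, cutoff, direction = c("ge", "gt")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) return(integer(0))
  g <- if (direction == "ge") as.integer(values >= cutoff) else
    as.integer(values > cutoff)
  names(g) <- names(values)
  if (length(unique(g)) < 2L) {
    warning("degenerate stratification: all patients on one side of cutoff ",
            cutoff, call. = FALSE)
    attr(g, "degenerate") <- TRUE
  }
  g
}

#' Score a cohort and append stratification columns
#'
#' Convenience wrapper: computes the benefit score, the benefit group at
#' `score_cutoff`, TMB, and the TMB-high group, returned as the clinical table
#' plus `score`, `benefit_group`, `tmb`, `tmb_group` columns.
#'
#' @param dataset a [cohort_dataset()].
#' @param panel gene panel (data.frame or character).
#' @param score_cutoff benefit iff `score >= score_cutoff` (default 2).
#' @param tmb_high_cutoff TMB-high iff `tmb >= tmb_high_cutoff` mutations/Mb
#'   (default 10; the paper's own TMB dichotomization threshold is unstated,
#'   10 mut/Mb is the conventional one).
#' @param tmb_region_mb megabases for TMB derivation (default 1.1).
#' @return data.frame (`scored_cohort`).
#' @export
score_cohort <- function(dataset, panel, score_cutoff = 2L,
                         tmb_high_cutoff = 10, tmb_region_mb = 1.1) {
  score <- ici_benefit_score(dataset, panel)
  tmb <- cohort_tmb(dataset, tmb_region_mb)
  out <- dataset$clinical
  out$score <- unname(score)
  out$benefit_group <- unname(suppressWarnings(stratify(score, score_cutoff)))
  out$tmb <- unname(tmb)
  out$tmb_group <- unname(suppressWarnings(stratify(tmb, tmb_high_cutoff)))
  attr(out, "score_cutoff") <- score_cutoff
  attr(out, "tmb_high_cutoff") <- tmb_high_cutoff
  out
}
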