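#' Read a somatic mutation table (MAF or long-format TSV)
#'
#' MAF dialect requires the standard `Hugo_Symbol` and `Tumor_Sample_Barcode`
#' columns (a `Variant_Classification` column is needed only when
#' `variant_filter` is used); long-TSV dialect requires `sample_id` and `gene`
#' columns. Duplicate (sample, gene) pairs are kept here and collapsed later
#' when the binary matrix is built. Comment lines starting with `#` are
#' skipped.
#'
#' @param path file path.
#' @param dialect `"long"` or `"maf"`.
#' @param variant_filter optional character vector of `Variant_Classification`
#'   values to keep (MAF only); default keeps all rows.
#' @return A `mutation_table`: data.frame with columns `sample_id`, `gene`
#'   (and `variant_class` for MAF), plus attributes `dialect` and
#'   `n_filtered` (rows dropped by `variant_filter`).
#' @export
read_mutations <- function(path, dialect = c("long", "maf"),
                           variant_filter = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("empty mutation file: ", path, call. = FALSE)

  if (dialect == "maf") {
    for (col in c("Hugo_Symbol", "Tumor_Sample_Barcode")) {
      if (!col %in% names(df)) {
        stop("MAF file missing required column '", col, "'", call. = FALSE)
      }
    }
    out <- data.frame(sample_id = trimws(df$Tumor_Sample_Barcode),
                      gene = trimws(df$Hugo_Symbol),
                      stringsAsFactors = FALSE)
    if ("Variant_Classification" %in% names(df)) {
      out$variant_class <- df$Variant_Classification
    }
    n_filtered <- 0L
    if (!is.null(variant_filter)) {
      if (is.null(out$variant_class)) {
        stop("variant_filter given but MAF has no Variant_Classification column",
             call. = FALSE)
      }
      keep <- out$variant_class %in% variant_filter
      n_filtered <- sum(!keep)
      out <- out[keep, , drop = FALSE]
      message(n_filtered, " mutation row(s) dropped by variant_filter")
    }
  } else {
    for (col in c("sample_id", "gene")) {
      if (!col %in% names(df)) {
        stop("long-TSV mutation file missing required column '", col, "'",
             call. = FALSE)
      }
    }
    out <- data.frame(sample_id = trimws(as.character(df$sample_id)),
                      gene = trimws(as.character(df$gene)),
                      stringsAsFactors = FALSE)
    n_filtered <- 0L
  }
  if (any(out$gene == "")) stop("empty gene symbol in mutation table",
                                call. = FALSE)
  rownames(out) <- NULL
  structure(out, dialect = dialect, n_filtered = n_filtered,
            class = c("mutation_table", "data.frame"))
}

#' Read a clinical table (TSV)
#'
#' Required columns: `sample_id`, `arm`, `pfs_time`, `pfs_event`, `os_time`,
#' `os_event`. Optional: `response`, `sld`, `tmb`. `arm` may be coded
#' `treated`/`control` or `ICI`/`chemo`. Event columns must parse as 0/1 and
#' times as positive reals; violations name the offending row.
#'
#' @param path file path.
#' @return data.frame, one row per patient.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "arm", "pfs_time", "pfs_event", "os_time", "os_event")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         df$sample_id[anyDuplicated(df$sample_id)], call. = FALSE)
  }
  arm_map <- c(treated = "treated", control = "control",
               ICI = "treated", chemo = "control")
  if (!all(df$arm %in% names(arm_map))) {
    bad <- which(!df$arm %in% names(arm_map))[1]
    stop("unrecognized arm value '", df$arm[bad], "' at row ", bad,
         call. = FALSE)
  }
  df$arm <- unname(arm_map[df$arm])
  for (col in c("pfs_time", "os_time")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop("column ", col, " must be a positive number; offending row ",
           bad[1], " (sample ", df$sample_id[bad[1]], ", value '",
           df[[col]][bad[1]], "')", call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in c("pfs_event", "os_event")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !v %in% c(0, 1))
    if (length(bad)) {
      stop("column ", col, " must be 0/1; offending row ", bad[1],
           " (sample ", df$sample_id[bad[1]], ", value '",
           df[[col]][bad[1]], "')", call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  df
}

#' Assemble a validated cohort from mutation and clinical tables
#'
#' Builds the binary patient-by-gene matrix over the union of observed genes,
#' or over `gene_universe` when given (off-panel genes dropped, count
#' reported). Mutation presence is binary per (patient, gene) regardless of
#' variant multiplicity. Patients with a clinical row but no mutations get an
#' all-zero row. Gene symbols match case-sensitively after whitespace
#' stripping.
#'
#' @param mutations a `mutation_table` from [read_mutations()] (or any
#'   data.frame with `sample_id` and `gene` columns).
#' @param clinical data.frame as returned by [read_clinical()].
#' @param gene_universe optional character vector of panel genes defining the
#'   matrix columns.
#' @param on_unknown_sample `"error"` (default) or `"drop"`: what to do with
#'   mutation rows whose sample is absent from the clinical table.
#' @return A [cohort_dataset()].
#' @export
build_dataset <- function(mutations, clinical, gene_universe = NULL,
                          on_unknown_sample = c("error", "drop")) {
  on_unknown_sample <- match.arg(on_unknown_sample)
  stopifnot(all(c("sample_id", "gene") %in% names(mutations)))
  mut <- data.frame(sample_id = trimws(mutations$sample_id),
                    gene = trimws(mutations$gene), stringsAsFactors = FALSE)

  unknown <- setdiff(unique(mut$sample_id), clinical$sample_id)
  if (length(unknown)) {
    if (on_unknown_sample == "error") {
      stop("mutation sample(s) absent from clinical table: ",
           paste(utils::head(unknown, 5), collapse = ", "),
           if (length(unknown) > 5) ", ...", call. = FALSE)
    }
    warning(length(unknown), " mutation sample(s) absent from clinical ",
            "table dropped", call. = FALSE)
    mut <- mut[mut$sample_id %in% clinical$sample_id, , drop = FALSE]
  }

  if (is.null(gene_universe)) {
    genes <- sort(unique(mut$gene))
  } else {
    genes <- trimws(gene_universe)
    if (anyDuplicated(genes)) stop("gene_universe has duplicates", call. = FALSE)
    off_panel <- setdiff(unique(mut$gene), genes)
    if (length(off_panel)) {
      message(length(off_panel), " gene symbol(s) outside gene_universe dropped")
      mut <- mut[mut$gene %in% genes, , drop = FALSE]
    }
  }

  ids <- clinical$sample_id
  m <- matrix(0L, nrow = length(ids), ncol = length(genes),
              dimnames = list(ids, genes))
  if (nrow(mut)) {
    m[cbind(match(mut$sample_id, ids), match(mut$gene, genes))] <- 1L
  }
  cohort_dataset(m, clinical)
}

#' Write a cohort to disk as plain-text tables
#'
#' Emits `<prefix>_mutations.tsv` (long format: `sample_id`, `gene`),
#' `<prefix>_clinical.tsv` (one row per patient), and, for simulated cohorts,
#' `<prefix>_truth.txt` (one planted gene per line). All UTF-8,
#' tab-separated.
#'
#' @param dataset a [cohort_dataset()].
#' @param prefix output path prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_cohort <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  idx <- which(dataset$mutations == 1L, arr.ind = TRUE)
  long <- data.frame(
    sample_id = rownames(dataset$mutations)[idx[, 1]],
    gene = colnames(dataset$mutations)[idx[, 2]],
    stringsAsFactors = FALSE
  )
  long <- long[order(long$sample_id, long$gene), , drop = FALSE]
  paths <- c(mutations = paste0(prefix, "_mutations.tsv"),
             clinical = paste0(prefix, "_clinical.tsv"))
  utils::write.table(long, paths["mutations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    paths["truth"] <- paste0(prefix, "_truth.txt")
    writeLines(dataset$truth, paths["truth"])
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param prefix path prefix used by [write_cohort()].
#' @param gene_universe optional gene list defining matrix columns; defaults
#'   to the genes observed in the mutation file.
#' @return A [cohort_dataset()] (with `truth` restored when the truth file
#'   exists).
#' @export
read_cohort <- function(prefix, gene_universe = NULL) {
  mut <- read_mutations(paste0(prefix, "_mutations.tsv"), dialect = "long")
  clin <- read_clinical(paste0(prefix, "_clinical.tsv"))
  ds <- build_dataset(mut, clin, gene_universe = gene_universe)
  truth_path <- paste0(prefix, "_truth.txt")
  if (file.exists(truth_path)) ds$truth <- readLines(truth_path)
  ds
}

#' Read a gene panel file (one symbol per line)
#'
#' @param path file path; blank lines and `#` comments ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[x != "" & !startsWith(x, "#")]
  if (anyDuplicated(x)) stop("duplicate genes in ", path, call. = FALSE)
  x
}
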