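#' Construct a cohort object
#'
#' A cohort pairs a nonnegative expression matrix (samples x genes) with
#' aligned progression-free-interval follow-up: a time in years and an event
#' indicator (1 = progression observed, 0 = censored).
#'
#' @param X numeric matrix, samples in rows, genes in columns; nonnegative.
#' @param time numeric vector of follow-up times in years, strictly positive.
#' @param event integer vector in \{0, 1\}.
#' @param sample_ids unique sample identifiers; defaults to rownames of `X`.
#' @param genes unique gene symbols; defaults to colnames of `X`.
#' @param cancer_type single string label.
#' @return An object of class `"cohort"`: a list with elements `X`, `time`,
#'   `event`, `sample_ids`, `genes`, `cancer_type` and a `provenance` list
#'   recording transformations applied to the expression values.
#' @export
cohort <- function(X, time, event, sample_ids = rownames(X),
                   genes = colnames(X), cancer_type = "unknown") {
  X <- as.matrix(X)
  if (is.null(sample_ids)) sc_stop("sample_ids required (or rownames on X)")
  if (is.null(genes)) sc_stop("gene names required (or colnames on X)")
  sample_ids <- as.character(sample_ids)
  genes <- as.character(genes)
  if (anyDuplicated(sample_ids)) sc_stop("duplicate sample ids")
  if (anyDuplicated(genes)) sc_stop("duplicate gene symbols")
  if (nrow(X) != length(sample_ids) || ncol(X) != length(genes))
    sc_stop("X dimensions do not match sample_ids/genes")
  if (length(time) != nrow(X) || length(event) != nrow(X))
    sc_stop("time/event length must equal number of samples")
  if (anyNA(X) || anyNA(time) || anyNA(event)) sc_stop("missing values not allowed")
  if (!is.numeric(X)) sc_stop("expression values must be numeric")
  if (any(X < 0)) sc_stop("negative expression values rejected")
  if (any(time <= 0)) sc_stop("follow-up times must be strictly positive")
  if (!all(event %in% c(0, 1))) sc_stop("event indicator must be 0 or 1")
  dimnames(X) <- list(sample_ids, genes)
  structure(list(X = X, time = as.numeric(time), event = as.integer(event),
                 sample_ids = sample_ids, genes = genes,
                 cancer_type = as.character(cancer_type)[1],
                 provenance = list()),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d samples x %d genes, %d events (%.0f%% censored)\n",
              x$cancer_type, length(x$sample_ids), length(x$genes),
              sum(x$event), 100 * mean(x$event == 0)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$X)

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

#' Load a cohort from expression and clinical tables
#'
#' The expression file is delimited text, either genes x samples (first
#' column gene symbols, remaining columns samples) or samples x genes;
#' orientation is auto-detected as the axis whose labels overlap the clinical
#' sample ids.  The clinical file must contain a sample id, a follow-up time
#' and an event column.  Sample sets are intersected; times given in days are
#' converted to years (365.25 days/year).
#'
#' @param expression_path,clinical_path paths to delimited text files
#'   (TSV or CSV, sniffed from the header line).
#' @param time_unit `"days"` or `"years"`.
#' @param columns named list overriding clinical column names; defaults are
#'   `sample_id`, `PFI_time`, `PFI_event`, `cancer_type` (the last optional).
#' @return A [cohort()].
#' @export
load_cohort <- function(expression_path, clinical_path,
                        time_unit = c("days", "years"),
                        columns = list()) {
  time_unit <- match.arg(time_unit)
  cols <- utils::modifyList(list(sample_id = "sample_id", time = "PFI_time",
                                 event = "PFI_event", cancer_type = "cancer_type"),
                            columns)
  clin <- read_delim_auto(clinical_path)
  for (nm in c("sample_id", "time", "event"))
    if (!cols[[nm]] %in% names(clin))
      sc_stop("clinical file lacks column '%s'", cols[[nm]])
  clin_ids <- as.character(clin[[cols$sample_id]])

  expr <- read_delim_auto(expression_path)
  row_labels <- as.character(expr[[1L]])
  col_labels <- names(expr)[-1L]
  M <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(M)) sc_stop("non-numeric expression values in %s", expression_path)
  n_row_hit <- length(intersect(row_labels, clin_ids))
  n_col_hit <- length(intersect(col_labels, clin_ids))
  if (n_row_hit == n_col_hit)
    sc_stop("cannot detect expression orientation: %d row and %d column labels match clinical sample ids",
            n_row_hit, n_col_hit)
  if (n_col_hit > n_row_hit) {            # genes x samples -> transpose
    X <- t(M); rownames(X) <- col_labels; colnames(X) <- row_labels
  } else {
    X <- M; rownames(X) <- row_labels
  }

  ids <- intersect(rownames(X), clin_ids)  # keeps expression-file order
  if (length(ids) == 0L) sc_stop("no overlap between expression and clinical sample ids")
  if (length(ids) < nrow(X) || length(ids) < length(clin_ids))
    sc_warn("sample intersection: %d kept (%d expression, %d clinical)",
            length(ids), nrow(X), length(clin_ids))
  clin <- clin[match(ids, clin_ids), , drop = FALSE]
  time <- as.numeric(clin[[cols$time]])
  if (time_unit == "days") time <- time / DAYS_PER_YEAR
  event <- clin[[cols$event]]
  if (!all(event %in% c(0, 1))) sc_stop("event values outside {0,1}")
  ctype <- if (cols$cancer_type %in% names(clin))
    as.character(clin[[cols$cancer_type]][1]) else "unknown"
  cohort(X[ids, , drop = FALSE], time, event, sample_ids = ids,
         cancer_type = ctype)
}

#' Write a cohort as an expression/clinical TSV pair
#'
#' Inverse of [load_cohort()]: full-precision round trip of `X`, `time`
#' (written in days) and `event`.
#'
#' @param cohort a [cohort()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the two file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  cp <- file.path(dir, "clinical.tsv")
  df <- data.frame(sample_id = cohort$sample_ids, cohort$X,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     ep, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- data.frame(sample_id = cohort$sample_ids,
                     PFI_time = format(cohort$time * DAYS_PER_YEAR, digits = 17),
                     PFI_event = cohort$event,
                     cancer_type = cohort$cancer_type)
  utils::write.table(clin, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = ep, clinical = cp))
}

#' Normalize expression against housekeeping genes
#'
#' Divides every expression value of a sample by the geometric mean of
#' (1 + housekeeping counts) for that sample, then applies log2(1 + value).
#' This removes per-sample scale (sequencing depth) using a small reference
#' gene set, the way recurrence-score assays normalize target genes against
#' reference genes.
#'
#' @param cohort a [cohort()] with raw nonnegative counts.
#' @param hk_genes character vector of housekeeping gene symbols; at least one
#'   must be present in the cohort.
#' @return The cohort with transformed `X`; the housekeeping set and any
#'   missing symbols are recorded under `provenance$housekeeping`.
#' @export
normalize_housekeeping <- function(cohort, hk_genes) {
  found <- intersect(hk_genes, cohort$genes)
  if (length(found) == 0L) sc_stop("none of the housekeeping genes are present")
  if (length(found) < length(hk_genes))
    sc_warn("%d housekeeping gene(s) absent from cohort",
            length(hk_genes) - length(found))
  H <- cohort$X[, found, drop = FALSE]
  divisor <- exp(rowMeans(log1p(H)))          # geometric mean of 1 + counts
  if (any(divisor <= 0) || any(!is.finite(divisor)))
    sc_stop("invalid housekeeping divisor")
  cohort$X <- log2(1 + cohort$X / divisor)
  cohort$provenance$housekeeping <- list(genes = found,
                                         missing = setdiff(hk_genes, found))
  cohort$provenance$log2 <- TRUE
  cohort
}

#' Align a cohort's genes to a reference gene order
#'
#' Reorders columns to exactly `reference_genes`; genes the cohort lacks are
#' filled with zero (the convention for applying a trained model to an
#' external cohort with missing genes), and genes outside the reference are
#' dropped.
#'
#' @param cohort a [cohort()].
#' @param reference_genes character vector, the gene order of a trained model.
#' @return The cohort with `X` having columns exactly `reference_genes`;
#'   `provenance$alignment` records the missing/dropped counts.
#' @export
align_genes <- function(cohort, reference_genes) {
  reference_genes <- as.character(reference_genes)
  if (length(reference_genes) == 0L) sc_stop("reference_genes is empty")
  missing <- setdiff(reference_genes, cohort$genes)
  dropped <- setdiff(cohort$genes, reference_genes)
  if (length(missing) == length(reference_genes))
    sc_warn("no overlap with reference genes: expression is all zero")
  else if (length(missing))
    sc_warn("%d reference gene(s) missing from cohort, zero-filled", length(missing))
  X <- matrix(0, nrow(cohort$X), length(reference_genes),
              dimnames = list(cohort$sample_ids, reference_genes))
  keep <- intersect(reference_genes, cohort$genes)
  X[, keep] <- cohort$X[, keep]
  cohort$X <- X
  cohort$genes <- reference_genes
  cohort$provenance$alignment <- list(n_missing = length(missing),
                                      n_dropped = length(dropped))
  cohort
}

#' Subset a cohort by sample index
#'
#' @param cohort a [cohort()].
#' @param idx integer or logical index over samples.
#' @return The subsetted cohort.
#' @export
subset_cohort <- function(cohort, idx) {
  cohort$X <- cohort$X[idx, , drop = FALSE]
  cohort$time <- cohort$time[idx]
  cohort$event <- cohort$event[idx]
  cohort$sample_ids <- cohort$sample_ids[idx]
  cohort
}
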