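#' Define a cross-cancer pooling plan
#'
#' @param group_name label for the pooled group (e.g. a transcriptional
#'   cluster of cancer types).
#' @param members cancer-type labels pooled for encoder training (>= 2).
#' @param target the member whose downstream head is trained and evaluated.
#' @return A `"pooling_plan"` list.
#' @export
pooling_plan <- function(group_name, members, target) {
  members <- as.character(members)
  if (length(members) < 2L) sc_stop("pooling needs >= 2 member cohorts")
  if (!target %in% members) sc_stop("target '%s' not among members", target)
  structure(list(group_name = group_name, members = members, target = target),
            class = "pooling_plan")
}

#' Pool cohorts on their shared gene set
#'
#' Row-concatenates the member cohorts on the intersection of their gene
#' sets; per-sample cancer-type labels are retained so downstream heads can
#' be trained on the target cohort only.  Contrastive group labels must be
#' recomputed on the pooled sample (the pooled n changes the bin count).
#'
#' @param cohorts named list of [cohort()]s (names = cancer types).
#' @param plan a [pooling_plan()]; defaults to pooling everything with the
#'   first cohort as target.
#' @return A [cohort()] with an extra `sample_types` field mapping each
#'   pooled sample to its source cancer type.
#' @export
pool_cohorts <- function(cohorts, plan = NULL) {
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, function(ch) ch$cancer_type, "")
  if (is.null(plan))
    plan <- pooling_plan("pool", names(cohorts), names(cohorts)[1])
  use <- cohorts[plan$members]
  if (any(vapply(use, is.null, TRUE)))
    sc_stop("pooling plan names a missing cohort")
  genes <- Reduce(intersect, lapply(use, function(ch) ch$genes))
  if (length(genes) == 0L) sc_stop("empty gene intersection across cohorts")
  ids <- unlist(lapply(use, function(ch) ch$sample_ids), use.names = FALSE)
  if (anyDuplicated(ids))
    sc_stop("duplicate sample ids across pooled cohorts (same cohort pooled twice?)")
  X <- do.call(rbind, lapply(use, function(ch) ch$X[, genes, drop = FALSE]))
  pooled <- cohort(X,
                   unlist(lapply(use, function(ch) ch$time), use.names = FALSE),
                   unlist(lapply(use, function(ch) ch$event), use.names = FALSE),
                   sample_ids = ids, genes = genes,
                   cancer_type = plan$group_name)
  pooled$sample_types <- rep(plan$members,
                             vapply(use, function(ch) length(ch$sample_ids), 0L))
  pooled$provenance$pooled <- list(members = plan$members, target = plan$target)
  pooled
}
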