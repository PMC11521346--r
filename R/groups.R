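#' Assign contrastive group labels by progression-free-interval rank
#'
#' Samples are sorted by ascending follow-up time (ties broken by original
#' index) and cut into `m = max(2, round(n / target_size))` contiguous groups,
#' so each group holds `floor(n/m)` or `floor(n/m)+1` samples with similar
#' outcome; the `n mod m` remainder samples go to the earliest (shortest-PFI)
#' groups.  These bins are the class labels of the supervised contrastive
#' loss.
#'
#' @param time numeric vector of follow-up times.
#' @param target_size desired samples per group (default 15).
#' @return A `"group_labeling"` list: `labels` (0-based group index per sample
#'   in the original order), `m`, and `group_sizes`.
#' @export
assign_pfi_groups <- function(time, target_size = 15) {
  n <- length(time)
  if (n < 2L) sc_stop("need at least 2 samples to form groups")
  m <- max(2L, as.integer(round(n / target_size)))
  base <- n %/% m
  rem <- n %% m
  sizes <- rep(base, m)
  if (rem > 0) sizes[seq_len(rem)] <- base + 1L
  ord <- order(time, seq_len(n))           # ties by original index
  labels_sorted <- rep.int(seq_len(m) - 1L, sizes)
  labels <- integer(n)
  labels[ord] <- labels_sorted
  structure(list(labels = labels, m = m, group_sizes = sizes),
            class = "group_labeling")
}

#' @export
print.group_labeling <- function(x, ...) {
  cat(sprintf("<group_labeling> m=%d groups, sizes %s\n", x$m,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Binary recurrence-risk labels from follow-up outcomes
#'
#' A sample progressing before the cutoff is high risk; a sample followed to
#' the cutoff or beyond (event or not) is low risk; a sample censored before
#' the cutoff cannot be labeled and is excluded.  Times exactly at the cutoff
#' count as low risk.
#'
#' @param time follow-up times in years.
#' @param event event indicators in \{0, 1\}.
#' @param cutoff_years risk-group cutoff (default 3 years).
#' @return A `"risk_labeling"` list: `labels` (factor with levels
#'   `high`, `low`, `excluded`), `cutoff_years`, and per-class `counts`.
#' @export
assign_risk_labels <- function(time, event, cutoff_years = 3) {
  stopifnot(length(time) == length(event), cutoff_years > 0)
  lab <- ifelse(time >= cutoff_years, "low",
                ifelse(event == 1, "high", "excluded"))
  lab <- factor(lab, levels = c("high", "low", "excluded"))
  counts <- table(lab)
  if (counts[["high"]] < 2L || counts[["low"]] < 2L)
    sc_stop("fewer than 2 samples in a risk class after exclusion (high=%d, low=%d)",
            counts[["high"]], counts[["low"]])
  structure(list(labels = lab, cutoff_years = cutoff_years,
                 counts = c(counts)),
            class = "risk_labeling")
}
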