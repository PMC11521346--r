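# ---- train/test leakage guard -------------------------------------------
# While active, every fitting routine in the package records the sample ids
# of the rows it was trained on; after each Monte-Carlo repeat the harness
# asserts that no held-out id ever reached a training call.

.sc_registry <- new.env(parent = emptyenv())
.sc_registry$active <- FALSE
.sc_registry$ids <- list()

leakage_guard_start <- function() {
  .sc_registry$active <- TRUE
  .sc_registry$ids <- list()
}

leakage_guard_stop <- function() {
  .sc_registry$active <- FALSE
  ids <- .sc_registry$ids
  .sc_registry$ids <- list()
  ids
}

record_training_ids <- function(ids) {
  if (isTRUE(.sc_registry$active) && !is.null(ids))
    .sc_registry$ids[[length(.sc_registry$ids) + 1L]] <- ids
  invisible(NULL)
}

#' Monte-Carlo cross-validation of pipeline variants
#'
#' Per repeat: a seeded 80/20 split of the cohort, full retraining of every
#' configured variant on the training split only, and evaluation on the
#' held-out split.  A leakage guard records the sample ids of every training
#' call (encoder, Cox head, classifier) and the run aborts if a held-out id
#' is ever seen in one.  Aggregates and pairwise Wilcoxon rank-sum
#' comparisons across variants are computed on the per-repeat metrics.
#'
#' @param cohort a [cohort()], already normalized.
#' @param variants named list of variant configurations.  Each is a list with
#'   `type` (`"cox"` or `"classifier"`), `cl` (use the contrastive encoder?),
#'   and optionally `head` (`"elastic_net"`, `"gradient_boosted"`, `"neural"`
#'   for Cox; `"gradient_boosted"`, `"mlp"` for classifiers), `encoder` (an
#'   [encoder_spec()]), `tap`, `head_args`, `clf_grid`, `cutoff_years`,
#'   `target_size`.
#' @param repeats number of Monte-Carlo repeats (default 40).
#' @param train_frac training fraction (default 0.8).
#' @param base_seed integer; repeat `r` uses seed `base_seed + r`.
#' @return An `"eval_report"`: `records` (one row per repeat x variant x
#'   metric), `aggregates`, `comparisons` (pairwise rank-sum p-values on the
#'   shared metric), `leakage` (per-repeat guard verdicts) and `failures`.
#' @export
monte_carlo_cv <- function(cohort, variants, repeats = 40, train_frac = 0.8,
                           base_seed = 1) {
  stopifnot(inherits(cohort, "cohort"), length(variants) >= 1,
            !is.null(names(variants)))
  n <- nrow(cohort$X)
  records <- list(); leakage <- list(); failures <- list()
  for (r in seq_len(repeats)) {
    seed <- base_seed + r
    set.seed(seed)
    tr_idx <- sort(sample.int(n, floor(train_frac * n)))
    te_idx <- setdiff(seq_len(n), tr_idx)
    stopifnot(length(intersect(tr_idx, te_idx)) == 0L)
    split_hash <- child_seed(0L, te_idx)
    train <- subset_cohort(cohort, tr_idx)
    test <- subset_cohort(cohort, te_idx)
    leakage_guard_start()
    for (v in names(variants)) {
      res <- tryCatch(
        run_variant(variants[[v]], train, test, child_seed(seed, utf8ToInt(v))),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(repeat_id = r, variant = v, message = conditionMessage(res))
        next
      }
      for (mname in names(res))
        records[[length(records) + 1L]] <-
          data.frame(repeat_id = r, seed = seed, split_hash = split_hash,
                     variant = v, metric = mname, value = res[[mname]])
    }
    seen <- unique(unlist(leakage_guard_stop()))
    bad <- intersect(seen, test$sample_ids)
    leakage[[r]] <- data.frame(repeat_id = r, n_training_calls_ok = TRUE,
                               n_leaked = length(bad))
    if (length(bad) > 0L)
      sc_stop("leakage: %d held-out sample(s) reached a training call in repeat %d",
              length(bad), r)
  }
  records <- do.call(rbind, records)
  agg <- stats::aggregate(value ~ variant + metric, records,
                          function(x) c(mean = mean(x), sd = stats::sd(x),
                                        n_repeats = length(x)))
  agg <- cbind(agg[c("variant", "metric")], as.data.frame(agg$value))
  comparisons <- pairwise_comparisons(records)
  structure(list(records = records, aggregates = agg,
                 comparisons = comparisons,
                 leakage = do.call(rbind, leakage),
                 failures = if (length(failures)) do.call(rbind, failures),
                 repeats = repeats, base_seed = base_seed),
            class = "eval_report")
}

pairwise_comparisons <- function(records) {
  out <- list()
  for (m in unique(records$metric)) {
    sub <- records[records$metric == m, ]
    vs <- unique(sub$variant)
    if (length(vs) < 2L) next
    for (i in seq_len(length(vs) - 1L)) for (j in seq(i + 1L, length(vs))) {
      a <- sub$value[sub$variant == vs[i]]
      b <- sub$value[sub$variant == vs[j]]
      out[[length(out) + 1L]] <-
        data.frame(metric = m, a = vs[i], b = vs[j],
                   mean_a = mean(a), mean_b = mean(b),
                   p = wilcoxon_rank_sum(a, b))
    }
  }
  if (length(out)) do.call(rbind, out)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d repeats (base seed %d)\n", x$repeats, x$base_seed))
  print(x$aggregates, row.names = FALSE)
  if (!is.null(x$failures))
    cat(sprintf("  %d variant run(s) failed\n", nrow(x$failures)))
  invisible(x)
}

# one variant on one split; returns a named list of metrics
run_variant <- function(variant, train, test, seed) {
  type <- variant$type %||% "cox"
  use_cl <- isTRUE(variant$cl)
  enc <- NULL
  if (use_cl) {
    groups <- assign_pfi_groups(train$time, variant$target_size %||% 15)
    spec <- variant$encoder %||% encoder_spec(max_epochs = 150, min_epochs = 30,
                                              patience = 60)
    spec$seed <- child_seed(seed, 47L)
    enc <- train_encoder(train$X, groups, spec)
  }
  # candidate feature spaces: one per requested tap (or the raw genes),
  # selected jointly with the head grid by held-out partial likelihood /
  # classifier CV AUC when more than one candidate is configured
  taps <- if (use_cl) (variant$taps %||% variant$tap %||% "hidden1") else "raw"
  feats <- lapply(taps, function(tp) {
    if (identical(tp, "raw")) list(tr = train$X, te = test$X)
    else list(tr = embed(enc, train$X, tp), te = embed(enc, test$X, tp))
  })
  names(feats) <- taps
  if (type == "cox") {
    fitter <- switch(variant$head %||% "elastic_net",
                     elastic_net = fit_cox_en,
                     gradient_boosted = fit_cox_gb,
                     neural = fit_cox_nn)
    grid <- variant$head_grid %||% list(variant$head_args %||% list())
    pick <- select_cox_candidate(feats, grid, fitter, train$time, train$event,
                                 child_seed(seed, 59L))
    Ftr <- feats[[pick$tap]]$tr; Fte <- feats[[pick$tap]]$te
    head <- do.call(fitter, c(list(Ftr, train$time, train$event),
                              grid[[pick$grid_id]]))
    s_te <- cox_linear_predictor(head, Fte)
    out <- list(cindex = concordance_index(test$time, test$event, s_te))
    if (isTRUE(variant$ibs)) {
      head <- estimate_baseline(head, Ftr, train$time, train$event)
      et <- train$time[train$event == 1]
      t_grid <- seq(stats::quantile(et, 0.05),
                    min(stats::quantile(et, 0.95), max(test$time)),
                    length.out = 20)
      sp <- predict_survival(head, Fte, t_grid)
      out$ibs <- brier_and_ibs(sp, test$time, test$event, t_grid,
                               cens_time = train$time,
                               cens_event = train$event)$ibs
    }
    if (isTRUE(variant$logrank)) {
      hr_tr <- exp(cox_linear_predictor(head, Ftr))
      strata <- stratify_by_hr(hr_tr, exp(s_te))
      if (length(unique(strata)) == 2L) {
        lr <- logrank_test(test$time[strata == "low"], test$event[strata == "low"],
                           test$time[strata == "high"], test$event[strata == "high"])
        out$logrank_p <- lr$p
      }
    }
    out
  } else {
    cutoff <- variant$cutoff_years %||% 3
    lab_tr <- assign_risk_labels(train$time, train$event, cutoff)
    kind <- variant$head %||% "gradient_boosted"
    fits <- lapply(feats, function(fe)
      fit_risk_classifier(fe$tr, lab_tr, kind, grid = variant$clf_grid,
                          seed = child_seed(seed, 53L)))
    best <- which.max(vapply(fits, function(f) max(f$cv_auc, na.rm = TRUE), 0))
    clf <- fits[[best]]
    Fte <- feats[[best]]$te
    lab_te <- assign_risk_labels(test$time, test$event, cutoff)
    keep <- lab_te$labels != "excluded"
    y <- as.integer(lab_te$labels[keep] == "high")
    p <- predict_risk(clf, Fte[keep, , drop = FALSE])
    list(auc = roc_auc(y, p)$auc)
  }
}

# choose (feature space, head hyperparameters) by mean held-out-fold partial
# likelihood per event over 3 stratified folds; single candidate short-circuits
select_cox_candidate <- function(feats, grid, fitter, time, event, seed) {
  if (length(feats) == 1L && length(grid) == 1L)
    return(list(tap = names(feats)[1], grid_id = 1L))
  k <- 3L
  folds <- stratified_folds(event, k, seed)
  best <- list(tap = names(feats)[1], grid_id = 1L, score = Inf)
  for (tp in names(feats)) for (gi in seq_along(grid)) {
    pll <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (sum(event[tr]) == 0 || sum(event[!tr]) == 0) return(NA_real_)
      hd <- tryCatch(
        do.call(fitter, c(list(feats[[tp]]$tr[tr, , drop = FALSE],
                               time[tr], event[tr]), grid[[gi]])),
        error = function(e) NULL)
      if (is.null(hd)) return(NA_real_)
      sv <- cox_linear_predictor(hd, feats[[tp]]$tr[!tr, , drop = FALSE])
      neg_log_partial_likelihood(sv, time[!tr], event[!tr]) / sum(event[!tr])
    }, 0)
    score <- mean(pll, na.rm = TRUE)
    if (is.finite(score) && score < best$score)
      best <- list(tap = tp, grid_id = gi, score = score)
  }
  best
}
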