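#' Fit a contrastive-learning Cox model
#'
#' The headline fitting function: bins the training samples by
#' progression-free-interval rank ([assign_pfi_groups()]), trains a
#' contrastive MLP encoder on those bins ([train_encoder()] — or a
#' cross-validated selection when `grid` is given), embeds the samples at
#' `tap`, fits a Cox proportional-hazards head on the embedding and estimates
#' the Breslow baseline hazard so survival probabilities can be predicted.
#'
#' @param cohort a [cohort()], already normalized.
#' @param head `"elastic_net"`, `"gradient_boosted"` or `"neural"`.
#' @param encoder an [encoder_spec()] (ignored if `grid` given); `NULL`
#'   disables the contrastive module (ablation arm: the head sees raw
#'   expression).
#' @param grid optional list of [encoder_spec()]s for CV selection.
#' @param tap encoder layer feeding the head (default `"hidden1"`).
#' @param target_size contrastive group size (default 15).
#' @param head_args named list passed to the head fitter.
#' @param seed integer seed.
#' @return A `"clcox"` object with `print`, `summary`, `coef`, `predict`,
#'   `plot` and `residuals` methods.
#' @seealso [clrisk()] for the binary recurrence-risk classifier.
#' @export
clcox <- function(cohort, head = c("elastic_net", "gradient_boosted", "neural"),
                  encoder = encoder_spec(), grid = NULL, tap = "hidden1",
                  target_size = 15, head_args = list(), seed = 1) {
  head <- match.arg(head)
  stopifnot(inherits(cohort, "cohort"))
  if (sum(cohort$event) < 1) sc_stop("at least one event required for a Cox fit")
  enc <- NULL
  if (!is.null(grid)) {
    groups <- assign_pfi_groups(cohort$time, target_size)
    encs <- select_encoders_cv(cohort$X, groups, grid, keep = 1, seed = seed)
    enc <- encs[[1]]
  } else if (!is.null(encoder)) {
    groups <- assign_pfi_groups(cohort$time, target_size)
    encoder$seed <- child_seed(seed, encoder$seed)
    enc <- train_encoder(cohort$X, groups, encoder)
  }
  F <- if (is.null(enc)) cohort$X else embed(enc, cohort$X, tap)
  rownames(F) <- cohort$sample_ids
  fitter <- switch(head, elastic_net = fit_cox_en,
                   gradient_boosted = fit_cox_gb, neural = fit_cox_nn)
  hd <- do.call(fitter, c(list(F, cohort$time, cohort$event), head_args))
  hd$feature_tap <- if (is.null(enc)) NA_character_ else tap
  hd <- estimate_baseline(hd, F, cohort$time, cohort$event)
  lp <- cox_linear_predictor(hd, F)
  structure(list(encoder = enc, head = hd, tap = tap,
                 genes = cohort$genes, cancer_type = cohort$cancer_type,
                 provenance = cohort$provenance,
                 train = list(time = cohort$time, event = cohort$event,
                              lp = lp, hr_median = stats::median(exp(lp)),
                              n = length(cohort$time)),
                 seed = seed, call = match.call()),
            class = "clcox")
}

#' @export
print.clcox <- function(x, ...) {
  cat(sprintf("<clcox> %s head%s, %d genes, n=%d (%d events)\n",
              x$head$kind,
              if (!is.null(x$encoder))
                sprintf(", contrastive encoder %s @ %s",
                        paste(x$encoder$spec$layer_widths, collapse = "-"), x$tap)
              else " on raw expression",
              length(x$genes), x$train$n, sum(x$train$event)))
  invisible(x)
}

#' @export
summary.clcox <- function(object, ...) {
  ci <- concordance_index(object$train$time, object$train$event,
                          object$train$lp)
  out <- list(head_kind = object$head$kind,
              contrastive = !is.null(object$encoder),
              tap = object$tap, n = object$train$n,
              events = sum(object$train$event),
              train_cindex = ci,
              hr_median = object$train$hr_median,
              encoder_stop = if (!is.null(object$encoder))
                object$encoder$stop_reason)
  class(out) <- "summary.clcox"
  out
}

#' @export
print.summary.clcox <- function(x, ...) {
  cat(sprintf("Contrastive Cox model (%s head)\n", x$head_kind))
  cat(sprintf("  n = %d (%d events); training c-index %.3f\n",
              x$n, x$events, x$train_cindex))
  cat(sprintf("  contrastive module: %s\n",
              if (x$contrastive) sprintf("on (tap %s, stopped: %s)", x$tap,
                                         x$encoder_stop) else "off"))
  cat(sprintf("  median training hazard ratio: %.3f\n", x$hr_median))
  invisible(x)
}

#' @export
coef.clcox <- function(object, ...) {
  if (object$head$kind != "elastic_net")
    sc_stop("coefficients are only defined for the elastic-net head")
  object$head$params$beta
}

#' Predict from a contrastive Cox model
#'
#' @param object a [clcox()] fit.
#' @param newdata a [cohort()] or a numeric matrix; genes are aligned to the
#'   training gene order with zero fill ([align_genes()]).
#' @param type `"lp"` (log hazard), `"hr"` (hazard ratio, `exp(lp)`),
#'   `"survival"` (matrix of `S(t|x)` at `times`) or `"strata"`
#'   (median-HR low/high groups, threshold from the training set).
#' @param times horizons for `type = "survival"`.
#' @param ... unused.
#' @return Vector (lp/hr/strata) or matrix (survival).
#' @export
predict.clcox <- function(object, newdata, type = c("lp", "hr", "survival", "strata"),
                          times = NULL, ...) {
  type <- match.arg(type)
  X <- model_input(object, newdata)
  F <- if (is.null(object$encoder)) X else embed(object$encoder, X, object$tap)
  lp <- cox_linear_predictor(object$head, F)
  switch(type,
         lp = lp,
         hr = exp(lp),
         survival = {
           if (is.null(times)) sc_stop("type='survival' needs times")
           predict_survival(object$head, F, times)
         },
         strata = factor(ifelse(exp(lp) <= object$train$hr_median, "low", "high"),
                         levels = c("low", "high")))
}

model_input <- function(object, newdata) {
  if (inherits(newdata, "cohort")) {
    if (!identical(newdata$genes, object$genes))
      newdata <- align_genes(newdata, object$genes)
    newdata$X
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$genes))
      sc_stop("newdata has %d columns; model expects %d genes", ncol(X),
              length(object$genes))
    X
  }
}

#' Martingale residuals of a contrastive Cox model
#'
#' `delta_i - H0(t_i) * exp(lp_i)` on the training data.
#'
#' @param object a [clcox()] fit.
#' @param ... unused.
#' @export
residuals.clcox <- function(object, ...) {
  H0 <- object$head$baseline(object$train$time)
  object$train$event - H0 * exp(object$train$lp)
}

#' Kaplan-Meier plot of median-HR risk strata
#'
#' Splits samples at the training-set median hazard ratio and draws the two
#' Kaplan-Meier curves with the log-rank p-value.
#'
#' @param x a [clcox()] fit.
#' @param newdata optional evaluation [cohort()]; defaults to the training
#'   outcome.
#' @param ... passed to [graphics::plot()].
#' @export
plot.clcox <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    time <- x$train$time; event <- x$train$event
    strata <- factor(ifelse(exp(x$train$lp) <= x$train$hr_median, "low", "high"),
                     levels = c("low", "high"))
  } else {
    time <- newdata$time; event <- newdata$event
    strata <- predict(x, newdata, type = "strata")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ strata)
  lr <- logrank_test(time[strata == "low"], event[strata == "low"],
                     time[strata == "high"], event[strata == "high"])
  graphics::plot(fit, col = c("red", "blue"), xlab = "years",
                 ylab = "progression-free probability",
                 main = sprintf("median-HR strata (log-rank p = %.3g)", lr$p), ...)
  graphics::legend("bottomleft", c("high risk", "low risk"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(fit)
}

#' Fit a contrastive-learning recurrence-risk classifier
#'
#' Binary counterpart of [clcox()]: trains the contrastive encoder on
#' PFI-rank bins, labels samples high/low risk at `cutoff_years`
#' ([assign_risk_labels()]; censored-before-cutoff samples are excluded) and
#' fits a classifier head on the embeddings.
#'
#' @inheritParams clcox
#' @param kind `"gradient_boosted"` or `"mlp"`.
#' @param cutoff_years risk cutoff (default 3).
#' @param tap encoder layer feeding the classifier (default `"output"`).
#' @param clf_grid grid for [fit_risk_classifier()].
#' @return A `"clrisk"` object with `print` and `predict` methods.
#' @export
clrisk <- function(cohort, kind = c("gradient_boosted", "mlp"),
                   encoder = encoder_spec(), grid = NULL, tap = "output",
                   cutoff_years = 3, target_size = 15, clf_grid = NULL,
                   seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(cohort, "cohort"))
  enc <- NULL
  if (!is.null(grid)) {
    groups <- assign_pfi_groups(cohort$time, target_size)
    enc <- select_encoders_cv(cohort$X, groups, grid, keep = 1, seed = seed)[[1]]
  } else if (!is.null(encoder)) {
    groups <- assign_pfi_groups(cohort$time, target_size)
    encoder$seed <- child_seed(seed, encoder$seed)
    enc <- train_encoder(cohort$X, groups, encoder)
  }
  F <- if (is.null(enc)) cohort$X else embed(enc, cohort$X, tap)
  rownames(F) <- cohort$sample_ids
  labels <- assign_risk_labels(cohort$time, cohort$event, cutoff_years)
  clf <- fit_risk_classifier(F, labels, kind, grid = clf_grid, seed = seed)
  structure(list(encoder = enc, classifier = clf, tap = tap,
                 genes = cohort$genes, cutoff_years = cutoff_years,
                 cancer_type = cohort$cancer_type,
                 label_counts = labels$counts, seed = seed,
                 call = match.call()),
            class = "clrisk")
}

#' @export
print.clrisk <- function(x, ...) {
  cat(sprintf("<clrisk> %s classifier%s, cutoff %g years; trained on %d high / %d low (%d excluded)\n",
              x$classifier$kind,
              if (!is.null(x$encoder)) " on contrastive embeddings"
              else " on raw expression",
              x$cutoff_years, x$label_counts[["high"]],
              x$label_counts[["low"]], x$label_counts[["excluded"]]))
  invisible(x)
}

#' Predict recurrence-risk probability
#'
#' @param object a [clrisk()] fit.
#' @param newdata a [cohort()] or matrix (genes aligned with zero fill).
#' @param ... unused.
#' @return Scores in [0, 1]; higher = higher recurrence risk.
#' @export
predict.clrisk <- function(object, newdata, ...) {
  X <- model_input(object, newdata)
  F <- if (is.null(object$encoder)) X else embed(object$encoder, X, object$tap)
  predict_risk(object$classifier, F)
}
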