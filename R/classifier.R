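#' Fit a binary recurrence-risk classifier on embeddings
#'
#' Drops excluded samples, then selects a grid point by 5-fold stratified CV
#' maximizing validation AUC and refits it on all labeled rows.  `"gradient_boosted"`
#' uses xgboost's logistic objective; `"mlp"` a sigmoid-hidden-layer network
#' with logistic output trained by mini-batch SGD.
#'
#' @param F feature matrix (samples x features).
#' @param labels an [assign_risk_labels()] result aligned to rows of `F`.
#' @param kind `"gradient_boosted"` or `"mlp"`.
#' @param grid list of named argument lists.  Gradient-boosted entries may set
#'   `n_trees`, `max_depth`, `learning_rate`; mlp entries `hidden_widths`,
#'   `learning_rate`, `l2_weight`, `epochs`.
#' @param k CV folds (default 5).
#' @param seed integer seed.
#' @return A `"risk_classifier"`: fitted parameters, the selected grid point,
#'   and the CV table.
#' @export
fit_risk_classifier <- function(F, labels, kind = c("gradient_boosted", "mlp"),
                                grid = NULL, k = 5, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(labels, "risk_labeling"))
  F <- as.matrix(F)
  if (nrow(F) != length(labels$labels)) sc_stop("F rows must match labels")
  keep <- labels$labels != "excluded"
  F <- F[keep, , drop = FALSE]
  y <- as.integer(labels$labels[keep] == "high")   # 1 = high risk
  if (length(unique(y)) < 2L) sc_stop("both risk classes required")
  record_training_ids(rownames(F))
  if (is.null(grid))
    grid <- if (kind == "gradient_boosted")
      list(list(n_trees = 50, max_depth = 2, learning_rate = 0.1),
           list(n_trees = 100, max_depth = 3, learning_rate = 0.1))
    else
      list(list(hidden_widths = 8, learning_rate = 0.1, l2_weight = 1e-4,
                epochs = 200),
           list(hidden_widths = c(16, 8), learning_rate = 0.1,
                l2_weight = 1e-4, epochs = 200))
  folds <- stratified_folds(y, k, child_seed(seed, 37L))
  cv_auc <- vapply(seq_along(grid), function(gi) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L)
        return(NA_real_)
      fit <- fit_classifier_once(F[tr, , drop = FALSE], y[tr], kind,
                                 grid[[gi]], child_seed(seed, gi, f))
      roc_auc(y[!tr], fit$predict(F[!tr, , drop = FALSE]))$auc
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  if (all(is.na(cv_auc))) sc_stop("CV failed: single-class folds throughout")
  best <- which.max(cv_auc)
  fit <- fit_classifier_once(F, y, kind, grid[[best]], child_seed(seed, 0L, 0L))
  structure(list(kind = kind, fit = fit, grid = grid, selected = best,
                 cv_auc = cv_auc, n_train = nrow(F)),
            class = "risk_classifier")
}

fit_classifier_once <- function(F, y, kind, pars, seed) {
  if (kind == "gradient_boosted") {
    M <- F; dimnames(M) <- NULL
    dtrain <- xgboost::xgb.DMatrix(M, label = y, nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = pars$learning_rate %||% 0.1,
                    max_depth = pars$max_depth %||% 2,
                    seed = seed, nthread = 1),
      data = dtrain, nrounds = pars$n_trees %||% 50, verbose = 0)
    list(booster = bst,
         predict = function(Fnew) {
           M <- as.matrix(Fnew); dimnames(M) <- NULL
           stats::predict(bst, xgboost::xgb.DMatrix(M, nthread = 1))
         })
  } else {
    widths <- c(pars$hidden_widths %||% 8, 1L)
    net <- mlp_init(ncol(F), widths, child_seed(seed, 41L))
    lr <- pars$learning_rate %||% 0.1
    l2 <- pars$l2_weight %||% 1e-4
    epochs <- pars$epochs %||% 200
    bs <- min(64L, nrow(F))
    set.seed(child_seed(seed, 43L))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(F))
      for (start in seq(1L, nrow(F), by = bs)) {
        idx <- ord[start:min(start + bs - 1L, nrow(F))]
        A <- mlp_forward(net, F[idx, , drop = FALSE])
        p <- sigmoid(drop(A[[length(A)]]))
        dOut <- matrix((p - y[idx]) / length(idx), ncol = 1)  # d(mean CE)/d(logit)
        net <- mlp_step(net, mlp_backward(net, A, dOut), lr, l2)
      }
    }
    list(net = net,
         predict = function(Fnew) {
           A <- mlp_forward(net, as.matrix(Fnew))
           sigmoid(drop(A[[length(A)]]))
         })
  }
}

#' Predict recurrence-risk probabilities
#'
#' @param classifier a [fit_risk_classifier()] result.
#' @param F feature matrix.
#' @return Scores in [0, 1]; higher = higher predicted recurrence risk.
#' @export
predict_risk <- function(classifier, F) {
  stopifnot(inherits(classifier, "risk_classifier"))
  p <- classifier$fit$predict(as.matrix(F))
  stopifnot(all(is.finite(p)), all(p >= 0), all(p <= 1))
  p
}
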