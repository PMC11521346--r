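#' Negative log partial likelihood of a Cox model
#'
#' \deqn{L = -\sum_{i: \delta_i = 1} \left[ s_i -
#'   \log \sum_{j: t_j \ge t_i} \exp(s_j) \right]}
#' with the risk set containing every individual whose observed time is at
#' least the event time (censored-at-event-time individuals included).  Tied
#' event times share the full risk set (Breslow's approximation).  The inner
#' log-sum is stabilized by max subtraction.
#'
#' @param scores numeric vector of risk scores `f(x_i)`.
#' @param time observed times.
#' @param event event indicators in \{0, 1\}; at least one event required.
#' @return Nonnegative scalar.
#' @export
neg_log_partial_likelihood <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (!all(is.finite(scores))) sc_stop("non-finite risk scores")
  if (sum(event) == 0) sc_stop("no events: partial likelihood undefined")
  m <- max(scores)
  ord <- order(time, decreasing = TRUE)     # latest first
  e <- exp(scores[ord] - m)
  csum <- cumsum(e)                          # sum over {j: t_j >= t} walking down
  # tied times share the largest risk set: index csum at the end of a tie run
  t_sorted <- time[ord]
  risk_lse <- m + log(csum[ave(seq_len(n), t_sorted, FUN = max)])
  ll <- sum((scores[ord] - risk_lse)[event[ord] == 1])
  -ll
}

# gradient of neg_log_partial_likelihood w.r.t. scores (Breslow);
# d/ds_i = -delta_i + exp(s_i) * sum_{events k: t_k <= t_i} 1 / sum_{R(t_k)} exp(s_j)
cox_score_gradient <- function(scores, time, event) {
  n <- length(scores)
  m <- max(scores)
  ord <- order(time, decreasing = TRUE)
  e <- exp(scores[ord] - m)
  csum <- cumsum(e)
  t_sorted <- time[ord]
  risk_sum <- csum[ave(seq_len(n), t_sorted, FUN = max)]   # per sorted position
  inv <- ifelse(event[ord] == 1, 1 / risk_sum, 0)
  # cumulative (from the end, i.e. earliest times upward) sum of 1/risk over
  # events with t_k <= t_i
  cuminv <- rev(cumsum(rev(inv)))
  # tied times: every member of a tie run gets the full run's contribution
  first_of_tie <- ave(seq_len(n), t_sorted, FUN = min)
  cuminv <- cuminv[first_of_tie]
  g_sorted <- -event[ord] + e * cuminv
  g <- numeric(n)
  g[ord] <- g_sorted
  g
}

new_cox_head <- function(kind, params, predict_fn, feature_tap = NA_character_) {
  structure(list(kind = kind, params = params, predict_fn = predict_fn,
                 baseline = NULL, feature_tap = feature_tap),
            class = "cox_head")
}

#' @export
print.cox_head <- function(x, ...) {
  cat(sprintf("<cox_head> kind=%s%s%s\n", x$kind,
              if (!is.na(x$feature_tap)) paste0(", tap=", x$feature_tap) else "",
              if (!is.null(x$baseline)) ", with baseline hazard" else ""))
  invisible(x)
}

cox_linear_predictor <- function(head, F) head$predict_fn(as.matrix(F))

#' Elastic-net penalized linear Cox head
#'
#' Maximizes the partial likelihood minus
#' `alpha * (l1_ratio*||b||_1 + (1-l1_ratio)/2*||b||_2^2)`.  With a positive
#' penalty this is glmnet's Cox path at a single lambda; with `alpha = 0` an
#' unpenalized Cox fit (Breslow ties) is used.
#'
#' @param F feature matrix (samples x features).
#' @param time,event survival outcome; at least one event.
#' @param alpha penalty strength (glmnet's lambda).
#' @param l1_ratio elastic-net mixing in [0, 1] (1 = lasso).
#' @param ties `"breslow"` (default) or `"efron"` for the unpenalized fit.
#' @return A `"cox_head"` whose `params$beta` holds the coefficients.
#' @export
fit_cox_en <- function(F, time, event, alpha = 0.01, l1_ratio = 0.5,
                       ties = c("breslow", "efron")) {
  F <- as.matrix(F)
  ties <- match.arg(ties)
  stopifnot(sum(event) >= 1, l1_ratio >= 0, l1_ratio <= 1, alpha >= 0)
  record_training_ids(rownames(F))
  if (alpha == 0) {
    df <- data.frame(F)
    colnames(df) <- paste0("f", seq_len(ncol(df)))
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(colnames(df), collapse = "+")))
    df$time <- time; df$event <- event
    fit <- survival::coxph(fml, data = df, ties = ties)
    beta <- stats::coef(fit)
  } else {
    if (ncol(F) < 2L) sc_stop("penalized fit needs >= 2 features; use alpha = 0")
    y <- survival::Surv(time, event)
    fit <- glmnet::glmnet(F, y, family = "cox", alpha = l1_ratio,
                          lambda = alpha, standardize = FALSE)
    beta <- as.numeric(stats::coef(fit))
  }
  names(beta) <- colnames(F)
  beta[!is.finite(beta)] <- 0
  new_cox_head("elastic_net",
               list(beta = beta, alpha = alpha, l1_ratio = l1_ratio),
               predict_fn = function(Fnew) drop(as.matrix(Fnew) %*% beta))
}

#' Gradient-boosted Cox head
#'
#' Boosted regression trees trained on the Cox partial-likelihood loss
#' (xgboost's `survival:cox` objective; censored times enter with a negative
#' label).  `n_trees = 0` yields the constant null model.
#'
#' @param F feature matrix.
#' @param time,event survival outcome.
#' @param n_trees boosting rounds.
#' @param max_depth tree depth.
#' @param learning_rate shrinkage per round.
#' @param seed integer seed.
#' @return A `"cox_head"`; scores are log-hazard margins (0-centred by the
#'   objective's convention).
#' @export
fit_cox_gb <- function(F, time, event, n_trees = 100, max_depth = 2,
                       learning_rate = 0.1, seed = 1) {
  F <- as.matrix(F)
  stopifnot(sum(event) >= 1, n_trees >= 0)
  record_training_ids(rownames(F))
  if (n_trees == 0)
    return(new_cox_head("gradient_boosted", list(n_trees = 0),
                        predict_fn = function(Fnew) rep(0, nrow(as.matrix(Fnew)))))
  y <- ifelse(event == 1, time, -time)
  Ftr <- F; dimnames(Ftr) <- NULL
  dtrain <- xgboost::xgb.DMatrix(Ftr, label = y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "survival:cox", eta = learning_rate,
                  max_depth = max_depth, seed = seed, nthread = 1),
    data = dtrain, nrounds = n_trees, verbose = 0)
  new_cox_head("gradient_boosted",
               list(booster = bst, n_trees = n_trees, max_depth = max_depth,
                    learning_rate = learning_rate),
               predict_fn = function(Fnew, rounds = NULL) {
                 M <- as.matrix(Fnew); dimnames(M) <- NULL
                 stats::predict(bst, xgboost::xgb.DMatrix(M, nthread = 1),
                                outputmargin = TRUE,
                                iterationrange = if (!is.null(rounds)) c(1, rounds))
               })
}

#' One-hidden-layer neural Cox head
#'
#' A single sigmoid hidden layer feeding a linear log-hazard output, trained
#' by full-batch gradient descent on the mean negative log partial likelihood
#' plus an L2 weight penalty, with the same early-stopping protocol as the
#' contrastive encoder on a held-out eighth of the rows.
#'
#' @param F feature matrix.
#' @param time,event survival outcome.
#' @param hidden_width hidden-layer width.
#' @param learning_rate gradient-descent step size.
#' @param l2_weight L2 penalty weight.
#' @param max_epochs,min_epochs,patience,delta early-stopping parameters
#'   (see [early_stop_monitor()]); defaults are desk-scale.
#' @param seed integer seed.
#' @return A `"cox_head"`.
#' @export
fit_cox_nn <- function(F, time, event, hidden_width = 8, learning_rate = 0.05,
                       l2_weight = 1e-4, max_epochs = 500, min_epochs = 50,
                       patience = 200, delta = 0.01, seed = 1) {
  F <- as.matrix(F)
  n <- nrow(F)
  stopifnot(sum(event) >= 1)
  record_training_ids(rownames(F))
  set.seed(child_seed(seed, 23L))
  val <- sort(sample.int(n, max(2L, round(n / 8))))
  if (sum(event[val]) == 0 || sum(event[-val]) == 0) {
    # make sure both partitions carry an event
    ev <- which(event == 1)
    val <- sort(unique(c(setdiff(val, ev[1]), ev[2])))
    if (sum(event[-val]) == 0) val <- setdiff(val, which(event == 1)[1])
  }
  net <- mlp_init(ncol(F), c(hidden_width, 1L), child_seed(seed, 29L))
  best <- net
  mon <- early_stop_monitor(min_epochs, delta, patience, max_epochs)
  tr <- setdiff(seq_len(n), val)
  repeat {
    A <- mlp_forward(net, F[tr, , drop = FALSE])
    s <- drop(A[[length(A)]])
    if (!all(is.finite(s))) sc_stop("neural Cox head diverged")
    ds <- cox_score_gradient(s, time[tr], event[tr]) / sum(event[tr])
    grads <- mlp_backward(net, A, matrix(ds, ncol = 1))
    net <- mlp_step(net, grads, learning_rate, l2_weight)
    sv <- drop(mlp_forward(net, F[val, , drop = FALSE])[[3]])
    vloss <- neg_log_partial_likelihood(sv, time[val], event[val]) /
      sum(event[val])
    verdict <- mon$update(vloss)
    if (mon$best_epoch == mon$epoch) best <- net
    if (verdict != "continue") break
  }
  new_cox_head("neural",
               list(net = best, hidden_width = hidden_width,
                    stop_reason = verdict, best_epoch = mon$best_epoch),
               predict_fn = function(Fnew) {
                 drop(mlp_forward(best, as.matrix(Fnew))[[3]])
               })
}

#' Predicted hazard ratios
#'
#' `exp(f(x))` per sample: the hazard relative to the model's zero-score
#' baseline, usable as a prognostic index.
#'
#' @param head a fitted `"cox_head"`.
#' @param F feature matrix.
#' @return Vector of positive reals.
#' @export
predict_hr <- function(head, F) {
  stopifnot(inherits(head, "cox_head"))
  exp(cox_linear_predictor(head, F))
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' \deqn{H_0(t) = \sum_{t_i \le t,\ \delta_i = 1} d_i / \sum_{j \in R(t_i)} e^{s_j}}
#' so that `S(t|x) = exp(-H0(t) * exp(f(x)))`.
#'
#' @param head a fitted `"cox_head"`.
#' @param F,time,event the training features and outcome.
#' @return The head with `baseline` set to a right-continuous step function
#'   `H0(t)` (a `stepfun`).
#' @export
estimate_baseline <- function(head, F, time, event) {
  s <- cox_linear_predictor(head, F)
  m <- max(s)
  ut <- sort(unique(time[event == 1]))
  d <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  risk <- vapply(ut, function(t) sum(exp(s[time >= t] - m)), 0)
  H0 <- cumsum(d / (risk * exp(m)))
  head$baseline <- stats::stepfun(ut, c(0, H0), right = FALSE)
  head
}

#' Survival probabilities from a Cox head with a baseline estimate
#'
#' @param head a `"cox_head"` after [estimate_baseline()].
#' @param F feature matrix.
#' @param times evaluation times.
#' @return Matrix `nrow(F)` x `length(times)` of `S(t|x)`.
#' @export
predict_survival <- function(head, F, times) {
  if (is.null(head$baseline)) sc_stop("head has no baseline; run estimate_baseline()")
  hr <- predict_hr(head, F)
  H0 <- head$baseline(times)
  exp(-outer(hr, H0))
}

#' Joint selection of encoder, tap and Cox-head hyperparameters
#'
#' Scores every combination of encoder, embedding tap and head setting by the
#' mean held-out-fold negative log partial likelihood (per event) across `k`
#' stratified folds; the held-out c-index is logged alongside.  The best
#' combination is refit on the full data.
#'
#' @param encoders list of `"sc_encoder"` objects (e.g. from
#'   [select_encoders_cv()]).
#' @param X training expression matrix (encoder input space).
#' @param time,event survival outcome.
#' @param head_kind `"elastic_net"`, `"gradient_boosted"` or `"neural"`.
#' @param grid list of named argument lists for the head fitter.
#' @param k folds (default 5).
#' @param taps candidate taps; default all taps of each encoder.
#' @param seed integer seed for fold assignment.
#' @return List: `encoder`, `tap`, `head` (refit on all rows, with baseline),
#'   and `scores` (the CV table).
#' @export
select_head_cv <- function(encoders, X, time, event,
                           head_kind = c("elastic_net", "gradient_boosted", "neural"),
                           grid = list(list()), k = 5, taps = NULL, seed = 1) {
  head_kind <- match.arg(head_kind)
  X <- as.matrix(X)
  fitter <- switch(head_kind, elastic_net = fit_cox_en,
                   gradient_boosted = fit_cox_gb, neural = fit_cox_nn)
  folds <- stratified_folds(event, k, child_seed(seed, 31L))
  rows <- list()
  for (ei in seq_along(encoders)) {
    enc <- encoders[[ei]]
    tap_set <- taps %||% enc$taps
    for (tp in tap_set) {
      Fall <- embed(enc, X, tp)
      rownames(Fall) <- rownames(X)
      for (gi in seq_along(grid)) {
        fold_pll <- fold_ci <- numeric(k)
        for (f in seq_len(k)) {
          tr <- folds != f
          if (sum(event[tr]) == 0 || sum(event[!tr]) == 0) {
            fold_pll[f] <- NA; fold_ci[f] <- NA; next
          }
          head <- tryCatch(
            do.call(fitter, c(list(Fall[tr, , drop = FALSE],
                                   time[tr], event[tr]), grid[[gi]])),
            error = function(e) NULL)       # degenerate taps lose, not crash
          if (is.null(head)) { fold_pll[f] <- NA; fold_ci[f] <- NA; next }
          sv <- cox_linear_predictor(head, Fall[!tr, , drop = FALSE])
          fold_pll[f] <- neg_log_partial_likelihood(sv, time[!tr], event[!tr]) /
            sum(event[!tr])
          fold_ci[f] <- concordance_index(time[!tr], event[!tr], sv)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(encoder = ei, tap = tp, grid_id = gi,
                     mean_val_pll = mean(fold_pll, na.rm = TRUE),
                     mean_val_cindex = mean(fold_ci, na.rm = TRUE))
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$mean_val_pll, tab$encoder, tab$tap, tab$grid_id), ]
  best <- tab[1L, ]
  enc <- encoders[[best$encoder]]
  Fbest <- embed(enc, X, best$tap)
  rownames(Fbest) <- rownames(X)
  head <- do.call(fitter, c(list(Fbest, time, event), grid[[best$grid_id]]))
  head$feature_tap <- best$tap
  head <- estimate_baseline(head, Fbest, time, event)
  list(encoder = enc, tap = best$tap, head = head, scores = tab)
}
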