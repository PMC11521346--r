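#' Harrell's concordance index
#'
#' Fraction of comparable pairs `(i, j)` with `t_i < t_j` and `delta_i = 1`
#' in which the earlier-event sample has the higher risk score; tied scores
#' credit 0.5.  Pairs with exactly tied observed times are not comparable
#' under this definition (stricter than `survival::concordance`, which also
#' credits tied-time event/censored pairs).
#'
#' @param time,event survival outcome.
#' @param scores risk scores (higher = worse prognosis).
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(time, event, scores) {
  stopifnot(length(time) == length(event), length(time) == length(scores))
  cmp <- outer(time, time, "<")              # [i, j] <=> t_i < t_j
  cmp[event != 1, ] <- FALSE                 # the earlier time must be an event
  n_pairs <- sum(cmp)
  if (n_pairs == 0) sc_stop("no comparable pairs")
  d <- outer(scores, scores, "-")[cmp]       # s_i - s_j over comparable pairs
  (sum(d > 0) + 0.5 * sum(d == 0)) / n_pairs
}

#' Kaplan-Meier estimate of the survival function
#'
#' @param time,event survival outcome.
#' @return A right-continuous step function `S(t)` with `S(0) = 1`
#'   (product-limit estimator; drops only at event times), carrying the
#'   underlying `survfit` object as attribute `"fit"`.
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  f <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  attr(f, "fit") <- fit
  f
}

#' Two-group log-rank test
#'
#' @param time1,event1 outcome of group 1.
#' @param time2,event2 outcome of group 2.
#' @return List with `chi2` and `p` (chi-squared with 1 df).
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  time <- c(time1, time2); event <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Stratify samples by hazard-ratio thresholds from the training set
#'
#' Thresholds are computed on training hazard ratios only and applied to the
#' evaluation set: either a median split into `low`/`high`, or a three-group
#' split at the `p_low`-th and `p_high`-th percentiles into
#' `low`/`medium`/`high` (linear-interpolation quantiles; values at a
#' threshold go to the lower group).
#'
#' @param hr_train training hazard ratios (define the thresholds).
#' @param hr_eval hazard ratios to stratify.
#' @param scheme `"median_two_group"` or `"percentile_three_group"`.
#' @param p_low,p_high percentiles for the three-group scheme (defaults
#'   51 and 73).
#' @return Factor of group labels for `hr_eval`.
#' @export
stratify_by_hr <- function(hr_train, hr_eval,
                           scheme = c("median_two_group", "percentile_three_group"),
                           p_low = 51, p_high = 73) {
  scheme <- match.arg(scheme)
  if (scheme == "median_two_group") {
    thr <- stats::median(hr_train)
    factor(ifelse(hr_eval <= thr, "low", "high"), levels = c("low", "high"))
  } else {
    q <- stats::quantile(hr_train, c(p_low, p_high) / 100, names = FALSE)
    factor(ifelse(hr_eval <= q[1], "low",
                  ifelse(hr_eval <= q[2], "medium", "high")),
           levels = c("low", "medium", "high"))
  }
}

#' ROC curve and AUC
#'
#' AUC is the normalized Mann-Whitney U statistic (midrank handling of tied
#' scores), identical to the area under the trapezoid-interpolated ROC curve.
#'
#' @param labels binary labels (0/1, or logical).
#' @param scores classifier scores, higher = more positive.
#' @return List with `auc` and a `curve` data.frame (`fpr`, `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) sc_stop("labels must be binary")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) sc_stop("both classes required for AUC")
  r <- rank(scores)                          # midranks handle ties
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(y[ord] == 1L) / n1
  fpr <- cumsum(y[ord] == 0L) / n0
  # collapse tied-score runs to single ROC vertices
  keep <- c(diff(scores[ord]) != 0, TRUE)
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep])))
}

# censoring-distribution KM: G(t) = P(censoring time > t); left-limit G(t-)
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(at = stats::stepfun(fit$time, c(1, fit$surv), right = FALSE),
       before = stats::stepfun(fit$time, c(1, fit$surv), right = TRUE))
}

#' Brier score curve and integrated Brier score
#'
#' Inverse-probability-of-censoring-weighted (IPCW) Brier score:
#' \deqn{BS(t) = n^{-1} \sum_i S(t|x_i)^2 \frac{1\{t_i \le t, \delta_i = 1\}}{G(t_i^-)}
#'   + (1 - S(t|x_i))^2 \frac{1\{t_i > t\}}{G(t)}}
#' with `G` the Kaplan-Meier estimate of the censoring distribution (by
#' default from the evaluation data; pass `cens_time`/`cens_event` to use the
#' training split).  IBS is the trapezoidal integral over `t_grid` divided by
#' the grid span.
#'
#' @param surv_prob matrix `n x length(t_grid)` of predicted `S(t|x_i)`.
#' @param time,event evaluation outcome.
#' @param t_grid evaluation times; defaults to 20 equally spaced times
#'   between the 5th and 95th percentile of observed event times.
#' @param cens_time,cens_event optional outcome used to estimate the
#'   censoring distribution (e.g. the training split).
#' @return List with `t_grid`, `brier` (curve) and `ibs`.
#' @export
brier_and_ibs <- function(surv_prob, time, event, t_grid = NULL,
                          cens_time = time, cens_event = event) {
  n <- length(time)
  if (is.null(t_grid)) {
    et <- time[event == 1]
    if (length(et) < 2L) sc_stop("too few events for a default time grid")
    t_grid <- seq(stats::quantile(et, 0.05), stats::quantile(et, 0.95),
                  length.out = 20)
  }
  surv_prob <- as.matrix(surv_prob)
  stopifnot(nrow(surv_prob) == n, ncol(surv_prob) == length(t_grid))
  tmax <- max(time)
  if (any(t_grid > tmax)) {
    sc_warn("time grid truncated to the follow-up span")
    keep <- t_grid <= tmax
    t_grid <- t_grid[keep]
    surv_prob <- surv_prob[, keep, drop = FALSE]
  }
  G <- censoring_km(cens_time, cens_event)
  g_before <- pmax(G$before(time), 1e-10)    # G(t_i-)
  brier <- vapply(seq_along(t_grid), function(k) {
    t <- t_grid[k]
    gt <- max(G$at(t), 1e-10)
    had_event <- time <= t & event == 1
    still_ok <- time > t
    mean(surv_prob[, k]^2 * had_event / g_before +
           (1 - surv_prob[, k])^2 * still_ok / gt)
  }, 0)
  span <- diff(range(t_grid))
  ibs <- if (span > 0)
    sum(diff(t_grid) * (utils::head(brier, -1) + utils::tail(brier, -1)) / 2) / span
  else brier[1]
  list(t_grid = t_grid, brier = brier, ibs = ibs)
}

#' Time-dependent AUC (cumulative cases, dynamic controls)
#'
#' IPCW-weighted AUC at horizon `t`: cases are samples with an observed event
#' by `t` (weight `1/G(t_i-)`), controls are samples still event-free past
#' `t` (weight `1/G(t)`).  Without censoring this reduces exactly to
#' [roc_auc()] on the labels `time <= t`.
#'
#' @param time,event survival outcome.
#' @param scores risk scores, higher = earlier event expected.
#' @param t horizon.
#' @param cens_time,cens_event optional censoring-distribution sample.
#' @return AUC(t) in [0, 1].
#' @export
time_dependent_auc <- function(time, event, scores, t,
                               cens_time = time, cens_event = event) {
  case <- which(time <= t & event == 1)
  ctrl <- which(time > t)
  if (length(case) == 0L || length(ctrl) == 0L)
    sc_stop("no cases or no controls at horizon t=%g", t)
  G <- censoring_km(cens_time, cens_event)
  w_case <- 1 / pmax(G$before(time[case]), 1e-10)
  w_ctrl <- rep(1 / max(G$at(t), 1e-10), length(ctrl))
  conc <- outer(scores[case], scores[ctrl],
                function(a, b) (a > b) + 0.5 * (a == b))
  wt <- outer(w_case, w_ctrl)
  sum(conc * wt) / sum(wt)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when both samples are small and untied, normal approximation with
#' continuity and tie correction otherwise (`stats::wilcox.test`).
#'
#' @param a,b numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == length(b) && all(sort(a) == sort(b))) return(1)
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}
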