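test_that("concordance index matches the pairwise oracle exactly", {
  # perfect ranking and all-ties closed forms
  tt <- sort(rexp(30)); ev <- rep(1L, 30)
  expect_equal(concordance_index(tt, ev, -tt), 1)
  expect_equal(concordance_index(tt, ev, rep(2, 30)), 0.5)
  set.seed(83)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    time <- round(rexp(n), 1)
    event <- rbinom(n, 1, 0.6); if (sum(event) == 0) event[1] <- 1
    s <- round(rnorm(n), 1)                # rounded -> score ties exercised
    expect_equal(concordance_index(time, event, s),
                 cindex_oracle(time, event, s))
  }
})

test_that("ROC AUC equals the midrank oracle and behaves at the null", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  set.seed(89)
  for (r in 1:10) {
    n <- sample(20:500, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), 1)
    expect_equal(roc_auc(y, s)$auc, auc_oracle(y, s))
  }
  # permutation null: mean AUC near 0.5 over 20 seeds
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    roc_auc(rbinom(60, 1, 0.5) | c(1, rep(0, 59)), rnorm(60))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
  # ROC curve endpoints
  rc <- roc_auc(c(0, 1, 1, 0, 1), c(1, 3, 2, 2, 5))$curve
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  S <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(S(c(1, 2, 3, 4)), c(3 / 4, 1 / 2, 1 / 4, 0))
  expect_equal(S(0), 1)
  expect_equal(S(2.5), 1 / 2)              # right-continuous step
  # all censored: S identically 1
  Sc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(Sc(c(0.5, 1.5, 10)), c(1, 1, 1))
  # non-increasing
  set.seed(97)
  Sr <- km_estimate(rexp(50), rbinom(50, 1, 0.5))
  g <- seq(0, 5, by = 0.1)
  expect_true(all(diff(Sr(g)) <= 0))
})

test_that("log-rank test: identical groups give p ~ 1, strong separation rejects", {
  tt <- rexp(40); ev <- rbinom(40, 1, 0.7)
  r <- logrank_test(tt, ev, tt, ev)
  expect_lt(r$chi2, 1e-10)
  expect_gt(r$p, 0.99)
  # power: strongly different hazards
  set.seed(101)
  hits <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    t1 <- rexp(50, 1); t2 <- rexp(50, 4)
    logrank_test(t1, rep(1, 50), t2, rep(1, 50))$p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("log-rank null calibration: rejection near the nominal 5% level", {
  set.seed(103)
  rej <- vapply(1:500, function(s) {
    set.seed(2000 + s)
    tt <- rexp(60); ev <- rbinom(60, 1, 0.7)
    grp <- rep(1:2, each = 30)
    logrank_test(tt[grp == 1], ev[grp == 1], tt[grp == 2], ev[grp == 2])$p < 0.05
  }, NA)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("HR stratification thresholds come from the training set only", {
  expect_equal(as.character(stratify_by_hr(c(1, 2, 3, 4), c(2, 3))),
               c("low", "high"))
  expect_true(all(stratify_by_hr(c(10, 20, 30), c(1, 2, 3)) == "low"))
  # three-group proportions on a large uniform draw
  set.seed(107)
  hr_train <- runif(2000)
  hr_eval <- runif(20000)
  g3 <- stratify_by_hr(hr_train, hr_eval, "percentile_three_group")
  props <- as.vector(table(g3)) / 20000
  expect_equal(props, c(0.51, 0.22, 0.27), tolerance = 0.03)
})

test_that("IPCW Brier score: constant predictor closed form, propriety, bounds", {
  n <- 60
  set.seed(109)
  tt <- rexp(n); ev <- rep(1L, n)
  grid <- seq(0.1, 2, length.out = 10)
  S_half <- matrix(0.5, n, length(grid))
  bb <- brier_and_ibs(S_half, tt, ev, grid)
  expect_equal(bb$brier, rep(0.25, 10), tolerance = 1e-12)
  expect_equal(bb$ibs, 0.25, tolerance = 1e-12)
  # oracle survival functions never lose to the null KM predictor
  sim <- simulate_cohort(sim_config(n = 300, p = 10, k = 2, effect_size = 2,
                                    censor_rate = 0.2, seed = 11))
  ch <- sim$cohort
  rate <- 0.2 * exp(sim$truth$risk_score)
  grid2 <- seq(stats::quantile(ch$time, 0.05), stats::quantile(ch$time, 0.9),
               length.out = 15)
  S_oracle <- exp(-outer(rate, grid2))
  km <- km_estimate(ch$time, ch$event)
  S_km <- matrix(km(grid2), nrow(ch$X), length(grid2), byrow = TRUE)
  ibs_oracle <- brier_and_ibs(S_oracle, ch$time, ch$event, grid2)$ibs
  ibs_km <- brier_and_ibs(S_km, ch$time, ch$event, grid2)$ibs
  expect_lte(ibs_oracle, ibs_km)
  expect_gte(ibs_oracle, 0); expect_lte(ibs_km, 1)
  # grid beyond follow-up is truncated with a warning
  expect_warning(brier_and_ibs(S_oracle[, 1:2, drop = FALSE], ch$time, ch$event,
                               c(grid2[1], max(ch$time) + 10)), "truncated")
})

test_that("time-dependent AUC reduces to plain AUC without censoring", {
  set.seed(113)
  n <- 120
  tt <- rexp(n); ev <- rep(1L, n)
  s <- -tt + rnorm(n, sd = 0.3)
  for (t0 in stats::quantile(tt, c(0.3, 0.5, 0.7))) {
    expect_equal(time_dependent_auc(tt, ev, s, t0),
                 roc_auc(as.integer(tt <= t0), s)$auc, tolerance = 1e-9)
  }
  # perfect ranking scores
  expect_equal(time_dependent_auc(tt, ev, -tt, median(tt)), 1)
  # random scores: near chance on average
  aucs <- vapply(1:20, function(r) {
    set.seed(3000 + r)
    time_dependent_auc(tt, ev, rnorm(n), median(tt))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("Wilcoxon rank-sum wrapper: symmetry, identity, separation", {
  a <- c(1, 5, 3, 7); b <- c(2, 8, 4, 9)
  expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a))
  expect_equal(wilcoxon_rank_sum(a, a), 1)
  expect_lt(wilcoxon_rank_sum(1:10, 101:110), 0.01)
})
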