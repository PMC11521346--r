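test_that("negative log partial likelihood matches hand cases and the oracle", {
  # single subject with an event: s - log(e^s) = 0
  expect_equal(neg_log_partial_likelihood(2.3, 1, 1), 0)
  # hand-evaluated two-subject case
  expect_equal(neg_log_partial_likelihood(c(1, 0), c(1, 2), c(1, 1)),
               log(1 + exp(1)) - 1, tolerance = 1e-12)
  # random censored data with ties vs explicit-risk-set enumeration
  set.seed(43)
  for (r in 1:25) {
    n <- sample(3:50, 1)
    time <- round(rexp(n), 1)              # rounding induces ties
    event <- rbinom(n, 1, 0.6); if (sum(event) == 0) event[1] <- 1
    s <- rnorm(n)
    expect_equal(neg_log_partial_likelihood(s, time, event),
                 npll_oracle(s, time, event), tolerance = 1e-9)
  }
  expect_error(neg_log_partial_likelihood(c(1, 2), c(1, 2), c(0, 0)),
               "no events")
})

test_that("partial likelihood is invariant to score shifts; gradient is exact", {
  set.seed(47)
  n <- 40
  time <- round(rexp(n), 1)
  event <- rbinom(n, 1, 0.5); event[1] <- 1
  s <- rnorm(n)
  expect_equal(neg_log_partial_likelihood(s, time, event),
               neg_log_partial_likelihood(s + 17.3, time, event),
               tolerance = 1e-9)
  g <- survcontrast:::cox_score_gradient(s, time, event)
  gn <- vapply(seq_len(n), function(i) {
    sp <- s; sp[i] <- sp[i] + 1e-6
    sm <- s; sm[i] <- sm[i] - 1e-6
    (neg_log_partial_likelihood(sp, time, event) -
       neg_log_partial_likelihood(sm, time, event)) / 2e-6
  }, 0)
  expect_equal(g, gn, tolerance = 1e-6)
})

test_that("elastic-net Cox head recovers signs, shrinks, and zeroes under lasso", {
  sim <- simulate_cohort(sim_config(n = 200, p = 2, k = 1, effect_size = 2,
                                    censor_rate = 0.2, seed = 53))
  ch <- sim$cohort
  # the true risk score has a positive log-hazard coefficient by construction
  set.seed(1)
  hd <- fit_cox_en(cbind(sim$truth$risk_score, rnorm(200)), ch$time, ch$event,
                   alpha = 0.01, l1_ratio = 0.5)
  expect_gt(unname(hd$params$beta[1]), 0)
  # alpha -> infinity: full shrinkage, all hazard ratios equal
  hd_inf <- fit_cox_en(matrix(rnorm(400), 200), ch$time, ch$event,
                       alpha = 1e4, l1_ratio = 0.5)
  expect_true(all(hd_inf$params$beta == 0))
  expect_true(all(predict_hr(hd_inf, matrix(rnorm(40), 20)) == 1))
  # lasso sparsity: most null coefficients exactly zero
  set.seed(59)
  Fmat <- matrix(rnorm(200 * 50), 200, 50)
  s_true <- Fmat[, 1:5] %*% rep(1, 5)
  tt <- rexp(200, rate = 0.2 * exp(s_true))
  hd_l1 <- fit_cox_en(Fmat, tt, rep(1, 200), alpha = 0.1, l1_ratio = 1)
  expect_gte(sum(hd_l1$params$beta[6:50] == 0), 22)
})

test_that("unpenalized 1-feature fit matches a golden-section partial-likelihood maximizer", {
  set.seed(61)
  n <- 80
  x <- rnorm(n)
  time <- rexp(n, rate = 0.3 * exp(0.8 * x))
  event <- rbinom(n, 1, 0.8); event[1] <- 1
  hd <- fit_cox_en(matrix(x, ncol = 1), time, event, alpha = 0)
  # independent 1-D maximizer by golden-section search on the oracle npll
  golden <- function(f, lo, hi, tol = 1e-8) {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c <- b - phi * (b - a); d <- a + phi * (b - a)
    while (abs(b - a) > tol) {
      if (f(c) < f(d)) b <- d else a <- c
      c <- b - phi * (b - a); d <- a + phi * (b - a)
    }
    (a + b) / 2
  }
  beta_star <- golden(function(b) npll_oracle(b * x, time, event), -5, 5)
  expect_equal(unname(hd$params$beta[1]), beta_star, tolerance = 1e-4)
})

test_that("gradient-boosted Cox head: null model at 0 trees, non-increasing training loss, nonlinear gain", {
  sim <- simulate_cohort(sim_config(n = 200, p = 10, k = 2, effect_size = 1.5,
                                    censor_rate = 0.2, seed = 67))
  ch <- sim$cohort
  hd0 <- fit_cox_gb(ch$X, ch$time, ch$event, n_trees = 0)
  s0 <- survcontrast:::cox_linear_predictor(hd0, ch$X)
  expect_true(all(s0 == 0))
  expect_equal(neg_log_partial_likelihood(s0, ch$time, ch$event),
               npll_oracle(rep(0, 200), ch$time, ch$event))
  # staged predictions: training loss non-increasing in boosting round
  hd <- fit_cox_gb(ch$X, ch$time, ch$event, n_trees = 40, learning_rate = 0.1)
  losses <- vapply(c(1, 5, 10, 20, 40), function(k) {
    s <- hd$predict_fn(ch$X, rounds = k)
    neg_log_partial_likelihood(s, ch$time, ch$event)
  }, 0)
  expect_true(all(diff(losses) <= 1e-8))
  # planted nonlinear signal: trees beat the linear head
  set.seed(71)
  n <- 800
  L1 <- rnorm(n)
  Fmat <- cbind(L1, matrix(rnorm(n * 4), n))
  s_true <- abs(L1) * 2
  tt <- rexp(n, 0.2 * exp(s_true))
  tr <- 1:600; te <- 601:800
  ev <- rep(1L, n)
  gb <- fit_cox_gb(Fmat[tr, ], tt[tr], ev[tr], n_trees = 150, max_depth = 2)
  en <- fit_cox_en(Fmat[tr, ], tt[tr], ev[tr], alpha = 0.01, l1_ratio = 0.5)
  ci_gb <- concordance_index(tt[te], ev[te],
                             survcontrast:::cox_linear_predictor(gb, Fmat[te, ]))
  ci_en <- concordance_index(tt[te], ev[te],
                             survcontrast:::cox_linear_predictor(en, Fmat[te, ]))
  expect_gt(ci_gb, ci_en + 0.02)
})

test_that("neural Cox head: untrained net is chance, linear signal matches EN, reproducible", {
  set.seed(73)
  n <- 600
  Fmat <- matrix(rnorm(n * 4), n, 4)
  s_true <- Fmat %*% c(1, -1, 0.5, 0)
  tt <- rexp(n, 0.2 * exp(s_true))
  ev <- rbinom(n, 1, 0.8); ev[1] <- 1
  tr <- 1:450; te <- 451:600
  nn1 <- fit_cox_nn(Fmat[tr, ], tt[tr], ev[tr], hidden_width = 8,
                    learning_rate = 0.05, max_epochs = 300, seed = 5)
  nn2 <- fit_cox_nn(Fmat[tr, ], tt[tr], ev[tr], hidden_width = 8,
                    learning_rate = 0.05, max_epochs = 300, seed = 5)
  s1 <- survcontrast:::cox_linear_predictor(nn1, Fmat[te, ])
  expect_identical(s1, survcontrast:::cox_linear_predictor(nn2, Fmat[te, ]))
  en <- fit_cox_en(Fmat[tr, ], tt[tr], ev[tr], alpha = 0.001, l1_ratio = 0.5)
  ci_nn <- concordance_index(tt[te], ev[te], s1)
  ci_en <- concordance_index(tt[te], ev[te],
                             survcontrast:::cox_linear_predictor(en, Fmat[te, ]))
  expect_lt(abs(ci_nn - ci_en), 0.03)
  # all-equal scores (zeroed net, no training) give chance concordance
  net0 <- survcontrast:::mlp_init(4, c(8, 1), 1)
  net0$W <- lapply(net0$W, function(w) w * 0)
  s_const <- drop(survcontrast:::mlp_forward(net0, Fmat[te, ])[[3]])
  expect_true(all(s_const == s_const[1]))
  expect_equal(concordance_index(tt[te], ev[te], s_const), 0.5)
})

test_that("hazard ratios exponentiate scores and preserve order", {
  beta <- log(2)
  hd <- survcontrast:::new_cox_head("elastic_net", list(beta = beta),
                                    function(F) drop(as.matrix(F) %*% beta))
  hr <- predict_hr(hd, matrix(c(0, 1), ncol = 1))
  expect_equal(hr[1], 1)
  expect_equal(hr[2] / hr[1], 2)           # unit increase doubles the hazard
  s <- rnorm(20)
  hd2 <- survcontrast:::new_cox_head("elastic_net", list(beta = 1),
                                     function(F) drop(as.matrix(F)))
  expect_identical(order(predict_hr(hd2, matrix(s, ncol = 1))), order(s))
})

test_that("Breslow baseline: closed form under zero scores, monotone, S(0)=1", {
  n <- 8
  time <- 1:8; event <- rep(1L, n)
  hd <- survcontrast:::new_cox_head("elastic_net", list(beta = 0),
                                    function(F) rep(0, nrow(as.matrix(F))))
  hd <- estimate_baseline(hd, matrix(0, n, 1), time, event)
  # k-th event adds 1/(n-k+1)
  expect_equal(hd$baseline(time), cumsum(1 / (n - seq_len(n) + 1)),
               tolerance = 1e-12)
  expect_equal(hd$baseline(0), 0)
  grid <- seq(0, 10, by = 0.25)
  expect_true(all(diff(hd$baseline(grid)) >= 0))
  S <- predict_survival(hd, matrix(0, 3, 1), c(0, 2, 5))
  expect_equal(S[, 1], rep(1, 3))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("joint encoder/tap/head selection prefers the signal-carrying tap", {
  sim <- simulate_cohort(sim_config(n = 150, p = 25, k = 2, effect_size = 2,
                                    censor_rate = 0.2, seed = 79))
  ch <- sim$cohort
  g <- assign_pfi_groups(ch$time)
  enc <- train_encoder(ch$X, g, quick_spec(seed = 3))
  # degenerate call returns the single option unchanged
  one <- select_head_cv(list(enc), ch$X, ch$time, ch$event, "elastic_net",
                        grid = list(list(alpha = 0.05)), k = 3,
                        taps = "hidden1", seed = 2)
  expect_identical(one$tap, "hidden1")
  expect_s3_class(one$head, "cox_head")
  expect_identical(one$head$feature_tap, "hidden1")
  # deterministic given seed
  two <- select_head_cv(list(enc), ch$X, ch$time, ch$event, "elastic_net",
                        grid = list(list(alpha = 0.05), list(alpha = 0.2)),
                        k = 3, seed = 2)
  three <- select_head_cv(list(enc), ch$X, ch$time, ch$event, "elastic_net",
                          grid = list(list(alpha = 0.05), list(alpha = 0.2)),
                          k = 3, seed = 2)
  expect_identical(two$scores, three$scores)
  expect_identical(two$tap, three$tap)
})

test_that("a signal-bearing tap is selected over a pure-noise tap", {
  # hand-built encoder whose hidden layer passes the signal and whose output
  # layer destroys it: selection must pick the hidden tap in most seeds
  wins <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 120
    x <- rnorm(n)
    time <- rexp(n, 0.3 * exp(1.5 * x))
    event <- rbinom(n, 1, 0.8); event[1] <- 1
    X <- cbind(x, matrix(rnorm(n * 3), n, 3))
    net <- survcontrast:::mlp_init(4, c(4, 2), s)
    net$W[[1]] <- diag(1, 4)[, 1:4] * 3    # hidden ~ sigmoid(3x): signal kept
    net$b[[1]] <- rep(0, 4)
    net$W[[2]] <- matrix(0, 4, 2)          # output: constant -> pure noise
    enc <- structure(list(spec = quick_spec(), net = net,
                          taps = c("hidden1", "output"), training_log = NULL,
                          stop_reason = "handmade", best_epoch = NA,
                          min_val_loss = NA, input_genes = colnames(X)),
                     class = "sc_encoder")
    sel <- select_head_cv(list(enc), X, time, event, "elastic_net",
                          grid = list(list(alpha = 0.01)), k = 3, seed = s)
    if (sel$tap == "hidden1") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
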