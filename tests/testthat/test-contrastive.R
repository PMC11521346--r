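test_that("supervised contrastive loss matches its closed forms and the oracle", {
  # two same-label rows: the single positive equals the whole denominator
  expect_equal(supcon_loss(matrix(rnorm(4), 2), c("A", "A"), tau = 0.07), 0)
  # hand-derived three-row case
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(supcon_loss(Z, c("A", "A", "B"), tau = 1),
               2 * log(1 + exp(-1)), tolerance = 1e-12)
  # random batches against the double-loop oracle
  set.seed(19)
  for (r in 1:25) {
    b <- sample(2:32, 1); d <- sample(1:8, 1)
    Zb <- matrix(rnorm(b * d), b, d)
    lab <- sample(3, b, replace = TRUE)
    tau <- sample(c(0.07, 1), 1)
    expect_equal(supcon_loss(Zb, lab, tau), supcon_oracle(Zb, lab, tau),
                 tolerance = 1e-6)
  }
  expect_error(supcon_loss(Z, c(1, 1, 2), tau = 0), "positive")
  expect_error(supcon_loss(Z, c(1, 1), tau = 1), "length")
})

test_that("supcon loss is nonnegative, permutation-invariant, sharpens with tau", {
  set.seed(23)
  for (r in 1:10) {
    b <- sample(3:16, 1)
    Zb <- matrix(rnorm(b * 4), b, 4)
    lab <- sample(2, b, replace = TRUE)
    L <- supcon_loss(Zb, lab, tau = 0.5)
    expect_gte(L, 0)
    perm <- sample(b)
    expect_equal(supcon_loss(Zb[perm, ], lab[perm], tau = 0.5), L,
                 tolerance = 1e-10)
  }
  # correctly clustered batch: smaller tau sharpens the softmax, lower loss
  Zc <- rbind(c(1, 0), c(1, 0), c(0, 1))
  lc <- c("A", "A", "B")
  expect_lt(supcon_loss(Zc, lc, tau = 0.5), supcon_loss(Zc, lc, tau = 1))
})

test_that("analytic supcon gradient matches finite differences", {
  set.seed(29)
  Zb <- matrix(rnorm(18), 6, 3)
  lab <- c(1, 1, 2, 2, 3, 3)
  lg <- survcontrast:::supcon_loss_grad(Zb, lab, tau = 0.3)
  expect_equal(lg$loss, supcon_loss(Zb, lab, tau = 0.3), tolerance = 1e-10)
  eps <- 1e-6
  num <- matrix(0, 6, 3)
  for (i in 1:6) for (j in 1:3) {
    Zp <- Zb; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Zb; Zm[i, j] <- Zm[i, j] - eps
    num[i, j] <- (supcon_loss(Zp, lab, 0.3) - supcon_loss(Zm, lab, 0.3)) / (2 * eps)
  }
  expect_equal(lg$dZ, num, tolerance = 1e-6)
})

test_that("early stopping reproduces the three stop behaviors exactly", {
  # threshold rule: min 0.50 at epoch 60, epoch 61 exceeds min + 0.01
  seq1 <- c(seq(1, 0.5, length.out = 60), 0.515, rep(0.5, 100))
  r1 <- replay_early_stopping(seq1)
  expect_equal(r1$stop_epoch, 61L)
  expect_equal(r1$reason, "threshold")
  expect_equal(r1$best_epoch, 60L)
  # plateau rule: constant 0.505 after the epoch-60 minimum -> stop at 1560
  seq2 <- c(seq(1, 0.5, length.out = 60), rep(0.505, 2000))
  r2 <- replay_early_stopping(seq2)
  expect_equal(r2$stop_epoch, 1560L)
  expect_equal(r2$reason, "plateau")
  # strictly decreasing forever -> hard cap at 5000
  r3 <- replay_early_stopping(seq(1, 0.01, length.out = 6000))
  expect_equal(r3$stop_epoch, 5000L)
  expect_equal(r3$reason, "max_epochs")
  expect_equal(r3$best_epoch, 5000L)
  # clauses are armed only after epoch 50: an early spike does not stop
  seq4 <- c(0.5, 2, seq(0.49, 0.4, length.out = 100))
  r4 <- replay_early_stopping(seq4)
  expect_gt(r4$stop_epoch, 2L)
})

test_that("encoder training is reproducible and embeddings are deterministic", {
  sim <- simulate_cohort(sim_config(n = 120, p = 30, k = 3, effect_size = 1.5,
                                    censor_rate = 0.2, seed = 31))
  ch <- sim$cohort
  g <- assign_pfi_groups(ch$time)
  enc1 <- train_encoder(ch$X, g, quick_spec(seed = 4))
  enc2 <- train_encoder(ch$X, g, quick_spec(seed = 4))
  expect_identical(enc1$training_log, enc2$training_log)
  expect_identical(enc1$net$W, enc2$net$W)
  expect_identical(enc1$stop_reason, enc2$stop_reason)
  # taps include every hidden layer and the output layer; shape contract
  expect_identical(enc1$taps, c("hidden1", "output"))
  E1 <- embed(enc1, ch$X, "hidden1")
  expect_equal(dim(E1), c(120L, 16L))
  expect_identical(E1, embed(enc1, ch$X, "hidden1"))
  expect_equal(dim(embed(enc1, ch$X, "output")), c(120L, 8L))
  expect_error(embed(enc1, ch$X, "hidden9"), "unknown tap")
  # different seed, different training path
  enc3 <- train_encoder(ch$X, g, quick_spec(seed = 5))
  expect_false(identical(enc1$training_log, enc3$training_log))
})

test_that("trained embeddings separate outcome groups better than raw input", {
  sim <- simulate_cohort(sim_config(n = 200, p = 60, k = 3, effect_size = 3,
                                    censor_rate = 0, seed = 37))
  ch <- sim$cohort
  g <- assign_pfi_groups(ch$time, target_size = 50)   # few, large groups
  spec <- encoder_spec(layer_widths = c(32, 8), learning_rate = 2e-5,
                       l2_weight = 1e-3, batch_size = 200, max_epochs = 500,
                       min_epochs = 50, patience = 500, seed = 2)
  enc <- train_encoder(ch$X, g, spec)
  # mean silhouette w.r.t. group labels, plain euclidean
  silhouette <- function(M, lab) {
    D <- as.matrix(dist(M))
    mean(vapply(seq_len(nrow(M)), function(i) {
      same <- which(lab == lab[i] & seq_along(lab) != i)
      a <- mean(D[i, same])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(gg) mean(D[i, lab == gg]), 0))
      (b - a) / max(a, b)
    }, 0))
  }
  Z <- embed(enc, ch$X, "output")
  expect_gt(silhouette(Z, g$labels), silhouette(ch$X, g$labels))
})

test_that("cross-validated encoder selection ranks by fold loss, order-invariantly", {
  sim <- simulate_cohort(sim_config(n = 100, p = 20, k = 2, effect_size = 2,
                                    censor_rate = 0.2, seed = 41))
  ch <- sim$cohort
  g <- assign_pfi_groups(ch$time)
  # single-spec grid returns that spec
  one <- select_encoders_cv(ch$X, g, list(quick_spec()), k = 3, keep = 1)
  expect_length(one, 1L)
  expect_s3_class(one[[1]], "sc_encoder")
  # grid order must not change the ranked result
  grid <- list(quick_spec(), quick_spec(learning_rate = 2e-5))
  expect_warning(rank_ab <- select_encoders_cv(ch$X, g, grid, k = 3, keep = 5,
                                               seed = 9), "returning all")
  expect_warning(rank_ba <- select_encoders_cv(ch$X, g, rev(grid), k = 3,
                                               keep = 5, seed = 9), "returning all")
  expect_equal(attr(rank_ab, "cv_scores")$digest,
               attr(rank_ba, "cv_scores")$digest)
  expect_equal(rank_ab[[1]]$spec$learning_rate, rank_ba[[1]]$spec$learning_rate)
})
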