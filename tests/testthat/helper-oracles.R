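# Independent brute-force oracles: literal double-loop transcriptions of the
# defining formulas, shared by unit and acceptance tests.  They must stay
# independent of the package's implementations.

supcon_oracle <- function(Z, labels, tau) {
  b <- nrow(Z)
  total <- 0
  for (j in seq_len(b)) {
    A <- setdiff(seq_len(b), j)
    P <- A[labels[A] == labels[j]]
    if (length(P) == 0) next
    denom <- sum(exp(sapply(A, function(a) sum(Z[j, ] * Z[a, ]) / tau)))
    for (p in P)
      total <- total - log(exp(sum(Z[j, ] * Z[p, ]) / tau) / denom) / length(P)
  }
  total
}

npll_oracle <- function(scores, time, event) {
  total <- 0
  for (i in seq_along(scores)) {
    if (event[i] != 1) next
    R <- which(time >= time[i])
    total <- total - (scores[i] - log(sum(exp(scores[R]))))
  }
  total
}

cindex_oracle <- function(time, event, scores) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

auc_oracle <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  num <- 0
  for (i in pos) for (j in neg)
    num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  num / (length(pos) * length(neg))
}

# small deterministic cohort for I/O and labeling tests
toy_cohort <- function(n = 24, p = 6, seed = 42) {
  set.seed(seed)
  X <- matrix(rexp(n * p, rate = 0.2), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:p)))
  cohort(X, time = sort(rexp(n, 0.3)) + 0.05,
         event = rbinom(n, 1, 0.6) | seq_len(n) == 1,  # ensure >=1 event
         cancer_type = "TOY")
}

quick_spec <- function(...) {
  args <- utils::modifyList(
    list(layer_widths = c(16, 8), learning_rate = 1e-5, l2_weight = 1e-3,
         batch_size = 64, max_epochs = 60, min_epochs = 20, patience = 30),
    list(...))
  do.call(encoder_spec, args)
}
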