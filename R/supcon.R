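#' Supervised contrastive loss
#'
#' For each anchor `j` in the batch, the positives `P(j)` are the other rows
#' with the same label and the denominator runs over all other rows `A(j)`:
#' \deqn{L = \sum_j \frac{-1}{|P(j)|} \sum_{p \in P(j)}
#'   \log \frac{\exp(z_j^\top z_p / \tau)}{\sum_{a \in A(j)} \exp(z_j^\top z_a / \tau)}}
#' Anchors without positives contribute zero.  Inner products use the raw
#' embeddings (no unit-normalization) unless `normalize = TRUE`; the
#' log-sum-exp is stabilized by max subtraction.
#'
#' @param Z numeric matrix, batch x embedding dimension.
#' @param labels vector of batch class labels.
#' @param tau positive temperature (default 0.07).
#' @param normalize if TRUE, rows of `Z` are scaled to unit norm first.
#' @return Nonnegative scalar loss (sum over anchors).
#' @export
supcon_loss <- function(Z, labels, tau = 0.07, normalize = FALSE) {
  Z <- as.matrix(Z)
  b <- nrow(Z)
  if (length(labels) != b) sc_stop("labels length must match rows of Z")
  if (tau <= 0) sc_stop("tau must be positive")
  if (b < 2L) sc_stop("batch must have at least 2 rows")
  if (normalize) Z <- Z / pmax(sqrt(rowSums(Z^2)), .Machine$double.eps)
  S <- tcrossprod(Z) / tau
  total <- 0
  for (j in seq_len(b)) {
    a_idx <- setdiff(seq_len(b), j)
    pos <- a_idx[labels[a_idx] == labels[j]]
    if (length(pos) == 0L) next
    lse <- logsumexp(S[j, a_idx])
    total <- total + (lse - mean(S[j, pos]))
  }
  total
}

# loss and gradient dL/dZ for a mini-batch; used by the encoder trainer.
# G[j,k] = softmax_jk - 1{k in P(j)}/|P(j)| over k != j (rows with positives),
# dL/dZ = (G + G') Z / tau  because S = Z Z' / tau is bilinear in Z.
supcon_loss_grad <- function(Z, labels, tau = 0.07) {
  b <- nrow(Z)
  S <- tcrossprod(Z) / tau
  diag(S) <- -Inf                          # exclude self from denominators
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)
  denom <- rowSums(E)
  Q <- E / denom                           # row softmax over A(j)
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  active <- npos > 0
  loss <- 0
  G <- matrix(0, b, b)
  if (any(active)) {
    lse <- mx + log(denom)
    mean_pos <- rowSums(ifelse(same, S, 0))[active] / npos[active]
    loss <- sum(lse[active] - mean_pos)
    G[active, ] <- Q[active, , drop = FALSE] -
      same[active, , drop = FALSE] / npos[active]
  }
  list(loss = loss, dZ = (G + t(G)) %*% Z / tau)
}
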