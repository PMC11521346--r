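# Minimal multilayer-perceptron machinery shared by the contrastive encoder,
# the neural Cox head and the MLP classifier head: sigmoid hidden layers,
# linear output, mini-batch SGD with an L2 penalty on the weights.

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(input_dim, widths, seed) {
  set.seed(seed)
  dims <- c(input_dim, widths)
  W <- vector("list", length(widths)); b <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = 1 / sqrt(dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, widths = widths, input_dim = input_dim)
}

# forward pass keeping every activation; A[[l]] is the output of layer l
# (sigmoid for hidden layers, linear for the last layer)
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    H <- A[[l]] %*% net$W[[l]]
    H <- sweep(H, 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) sigmoid(H) else H
  }
  A
}

mlp_taps <- function(net) {
  L <- length(net$W)
  c(if (L > 1) paste0("hidden", seq_len(L - 1L)), "output")
}

# activations at a named tap
mlp_tap_output <- function(net, X, tap) {
  taps <- mlp_taps(net)
  pos <- match(tap, taps)
  if (is.na(pos)) sc_stop("unknown tap '%s' (have: %s)", tap,
                          paste(taps, collapse = ", "))
  A <- mlp_forward(net, X)
  A[[pos + 1L]]
}

# backprop: dOut is dL/d(output activations); returns weight/bias gradients
mlp_backward <- function(net, A, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * A[[l + 1L]] * (1 - A[[l + 1L]])  # sigmoid'
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- delta %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb)
}

# SGD step with L2 penalty l2*||W||^2 (gradient 2*l2*W; biases unpenalized)
mlp_step <- function(net, grads, lr, l2) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] - lr * (grads$gW[[l]] + 2 * l2 * net$W[[l]])
    net$b[[l]] <- net$b[[l]] - lr * grads$gb[[l]]
  }
  net
}

mlp_l2 <- function(net) sum(vapply(net$W, function(w) sum(w^2), 0))
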