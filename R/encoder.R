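#' Specification of a contrastive MLP encoder
#'
#' The encoder is a multilayer perceptron with sigmoid hidden layers and a
#' linear output layer, trained by mini-batch SGD on the supervised
#' contrastive loss plus an L2 weight penalty, with early stopping on a
#' held-out eighth of the training data (see [early_stop_monitor()]).
#'
#' @param layer_widths integer vector: hidden widths then output width
#'   (1 hidden layer minimum, i.e. 2 layers counting the output).
#' @param learning_rate SGD learning rate.
#' @param l2_weight L2 penalty weight on the connection weights.
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs hard epoch cap (default 5000).
#' @param min_epochs epochs before early stopping is armed (default 50).
#' @param patience plateau length for early stopping (default 1500).
#' @param delta early-stopping tolerance above the minimum (default 0.01).
#' @param tau contrastive temperature (default 0.07).
#' @param normalize unit-normalize embeddings before dot products
#'   (default FALSE: the loss uses raw inner products).
#' @param seed integer seed controlling initialization, the validation split
#'   and batch shuffling.
#' @return An `"encoder_spec"` list.
#' @export
encoder_spec <- function(layer_widths = c(32, 16), learning_rate = 1e-4,
                         l2_weight = 1e-3, batch_size = 64,
                         max_epochs = 5000, min_epochs = 50, patience = 1500,
                         delta = 0.01, tau = 0.07, normalize = FALSE,
                         seed = 1) {
  stopifnot(length(layer_widths) >= 2, all(layer_widths >= 1),
            learning_rate > 0, l2_weight >= 0, batch_size >= 2, tau > 0)
  structure(list(layer_widths = as.integer(layer_widths),
                 hidden_activation = "sigmoid",
                 learning_rate = learning_rate, l2_weight = l2_weight,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 min_epochs = as.integer(min_epochs),
                 patience = as.integer(patience), delta = delta,
                 tau = tau, normalize = normalize, seed = as.integer(seed)),
            class = "encoder_spec")
}

spec_digest <- function(spec) {
  s <- paste(c(spec$layer_widths, format(spec$learning_rate),
               format(spec$l2_weight), spec$batch_size, format(spec$tau),
               spec$normalize), collapse = "|")
  child_seed(0L, utf8ToInt(s))
}

# group-stratified hold-out of ~1/8 of rows; both partitions keep >= 2 groups
validation_split <- function(labels, seed) {
  set.seed(seed)
  n <- length(labels)
  val <- integer(0)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    take <- round(length(idx) / 8)
    if (take > 0) val <- c(val, sample(idx, take))
  }
  if (length(unique(labels[val])) < 2L) {
    # force one sample from each of the two largest groups
    big <- names(sort(table(labels), decreasing = TRUE))[1:2]
    val <- unique(c(val, vapply(big, function(g)
      sample(which(labels == as.integer(g)), 1L), 0L)))
  }
  sort(val)
}

#' Train a contrastive encoder
#'
#' Holds out a group-stratified eighth of the rows as the validation set,
#' then runs mini-batch SGD on the supervised contrastive loss with L2
#' regularization.  The mean per-anchor validation loss is computed after
#' every epoch and drives the early-stopping protocol; the returned weights
#' are those of the minimum-validation-loss epoch.
#'
#' @param X numeric matrix of training expression/features (samples x genes).
#' @param labels a [assign_pfi_groups()] result, or an integer vector of
#'   class labels.
#' @param spec an [encoder_spec()].
#' @return An `"sc_encoder"` object: the fitted weights, `taps` (layer names
#'   usable with [embed()]), a per-epoch `training_log`, `stop_reason`,
#'   `best_epoch`, and the input gene order.
#' @export
train_encoder <- function(X, labels, spec = encoder_spec()) {
  X <- as.matrix(X)
  if (inherits(labels, "group_labeling")) labels <- labels$labels
  if (length(labels) != nrow(X)) sc_stop("labels must match rows of X")
  if (length(unique(labels)) < 2L) sc_stop("need >= 2 groups to contrast")
  record_training_ids(rownames(X))

  val_idx <- validation_split(labels, child_seed(spec$seed, 11L))
  Xv <- X[val_idx, , drop = FALSE]; lv <- labels[val_idx]
  Xt <- X[-val_idx, , drop = FALSE]; lt <- labels[-val_idx]
  if (length(unique(lt)) < 2L || length(unique(lv)) < 2L)
    sc_stop("validation split left fewer than 2 groups in a partition")

  net <- mlp_init(ncol(X), spec$layer_widths, child_seed(spec$seed, 13L))
  best_net <- net
  mon <- early_stop_monitor(spec$min_epochs, spec$delta, spec$patience,
                            spec$max_epochs)
  nt <- nrow(Xt)
  bs <- min(spec$batch_size, nt)
  log_epoch <- numeric(0); log_val <- numeric(0)
  zero_grad_batches <- 0L
  set.seed(child_seed(spec$seed, 17L))      # batch shuffling stream
  repeat {
    ord <- sample.int(nt)
    for (start in seq(1L, nt, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, nt)]
      if (length(idx) < 2L) next
      A <- mlp_forward(net, Xt[idx, , drop = FALSE])
      Zb <- A[[length(A)]]
      if (spec$normalize) {
        nr <- pmax(sqrt(rowSums(Zb^2)), .Machine$double.eps)
        lg <- supcon_loss_grad(Zb / nr, lt[idx], spec$tau)
        # gradient through the normalization
        dZn <- lg$dZ
        lg$dZ <- dZn / nr - Zb * rowSums(dZn * Zb) / nr^3
      } else {
        lg <- supcon_loss_grad(Zb, lt[idx], spec$tau)
      }
      if (all(lg$dZ == 0)) { zero_grad_batches <- zero_grad_batches + 1L; next }
      grads <- mlp_backward(net, A, lg$dZ)
      net <- mlp_step(net, grads, spec$learning_rate, spec$l2_weight)
    }
    Zv <- mlp_forward(net, Xv)
    val_loss <- supcon_loss(Zv[[length(Zv)]], lv, spec$tau,
                            normalize = spec$normalize) / nrow(Xv)
    if (!is.finite(val_loss))
      sc_stop("validation loss diverged at epoch %d (lr=%g)", mon$epoch + 1L,
              spec$learning_rate)
    verdict <- mon$update(val_loss)
    if (mon$best_epoch == mon$epoch) best_net <- net
    log_epoch <- c(log_epoch, mon$epoch); log_val <- c(log_val, val_loss)
    if (verdict != "continue") break
  }
  structure(list(spec = spec, net = best_net, taps = mlp_taps(best_net),
                 training_log = data.frame(epoch = log_epoch,
                                           val_loss = log_val),
                 stop_reason = verdict, best_epoch = mon$best_epoch,
                 min_val_loss = mon$min_loss,
                 zero_grad_batches = zero_grad_batches,
                 input_genes = colnames(X)),
            class = "sc_encoder")
}

#' @export
print.sc_encoder <- function(x, ...) {
  cat(sprintf("<sc_encoder> %d -> %s; stopped '%s' at epoch %d (best %d, min val loss %.4f)\n",
              x$net$input_dim, paste(x$spec$layer_widths, collapse = "-"),
              x$stop_reason, max(x$training_log$epoch), x$best_epoch,
              x$min_val_loss))
  invisible(x)
}

#' Extract embeddings at a named encoder layer
#'
#' Deterministic forward pass to a layer tap; `"hidden1"`, `"hidden2"`, ...
#' are the sigmoid hidden layers and `"output"` the linear output layer.
#'
#' @param encoder an [train_encoder()] result.
#' @param X matrix with the encoder's input genes as columns.
#' @param tap layer name from `encoder$taps`.
#' @return Numeric matrix, rows matching `X`.
#' @export
embed <- function(encoder, X, tap = "output") {
  stopifnot(inherits(encoder, "sc_encoder"))
  X <- as.matrix(X)
  if (ncol(X) != encoder$net$input_dim)
    sc_stop("X has %d columns; encoder expects %d", ncol(X),
            encoder$net$input_dim)
  mlp_tap_output(encoder$net, X, tap)
}

#' Cross-validated encoder selection
#'
#' Scores every specification in `grid` by the mean, across `k`
#' group-stratified folds, of the trained encoder's minimum validation loss,
#' then refits the `keep` best specifications on the full data and returns
#' them ranked.  Fold membership and per-spec training seeds are derived from
#' `seed` and the spec's content, so the ranking is invariant to the order of
#' `grid`.
#'
#' @param X training matrix.
#' @param labels group labels as in [train_encoder()].
#' @param grid list of [encoder_spec()]s.
#' @param k number of folds (default 5).
#' @param keep number of encoders to refit and return (default 5).
#' @param seed integer seed for fold assignment.
#' @return List of `"sc_encoder"` objects, best first, with a `cv_scores`
#'   attribute (data.frame of spec digests and mean fold losses).
#' @export
select_encoders_cv <- function(X, labels, grid, k = 5, keep = 5, seed = 1) {
  if (length(grid) == 0L) sc_stop("empty encoder grid")
  if (inherits(labels, "group_labeling")) labels <- labels$labels
  if (length(grid) < keep) {
    sc_warn("grid has %d specs < keep=%d; returning all", length(grid), keep)
    keep <- length(grid)
  }
  folds <- stratified_folds(labels, k, child_seed(seed, 19L))
  digests <- vapply(grid, spec_digest, 0)
  scores <- vapply(seq_along(grid), function(gi) {
    spec <- grid[[gi]]
    fold_losses <- vapply(seq_len(k), function(f) {
      tr <- which(folds != f)
      sp <- spec; sp$seed <- child_seed(seed, digests[gi], f)
      enc <- train_encoder(X[tr, , drop = FALSE], labels[tr], sp)
      enc$min_val_loss
    }, 0)
    mean(fold_losses)
  }, 0)
  ord <- order(scores, digests)
  top <- ord[seq_len(keep)]
  fits <- lapply(top, function(gi) {
    sp <- grid[[gi]]; sp$seed <- child_seed(seed, digests[gi], 0L)
    train_encoder(X, labels, sp)
  })
  attr(fits, "cv_scores") <- data.frame(digest = digests, mean_val_loss = scores)[ord, ]
  fits
}

# seeded fold assignment, stratified by class label
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
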