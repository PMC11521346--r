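#' Early-stopping monitor for validation-loss sequences
#'
#' Implements the stopping protocol shared by the contrastive encoder and the
#' neural Cox head.  The running minimum validation loss is updated every
#' epoch.  Once `min_epochs` epochs have elapsed, training stops at the first
#' epoch where either (a) the validation loss exceeds the running minimum
#' plus `delta`, or (b) `patience` consecutive epochs since the last
#' minimum update have stayed at or below minimum + `delta` without setting a
#' new minimum.  A hard cap of `max_epochs` always applies.  The weights
#' reported by a trainer are those of the minimum-loss epoch.
#'
#' @param min_epochs epochs before either stopping clause is armed (default 50).
#' @param delta tolerance above the running minimum (default 0.01).
#' @param patience plateau length in epochs (default 1500).
#' @param max_epochs hard cap (default 5000).
#' @return An environment with `update(loss)` returning one of `"continue"`,
#'   `"threshold"`, `"plateau"`, `"max_epochs"`, and fields `epoch`,
#'   `min_loss`, `best_epoch`.
#' @export
early_stop_monitor <- function(min_epochs = 50, delta = 0.01,
                               patience = 1500, max_epochs = 5000) {
  st <- new.env(parent = emptyenv())
  st$epoch <- 0L; st$min_loss <- Inf; st$best_epoch <- NA_integer_
  st$plateau <- 0L
  st$update <- function(loss) {
    st$epoch <- st$epoch + 1L
    if (!is.finite(loss)) return("diverged")
    if (loss < st$min_loss) {
      st$min_loss <- loss; st$best_epoch <- st$epoch; st$plateau <- 0L
    } else if (loss > st$min_loss + delta) {
      if (st$epoch >= min_epochs) return("threshold")
      st$plateau <- 0L
    } else {
      st$plateau <- st$plateau + 1L
      if (st$epoch >= min_epochs && st$plateau >= patience) return("plateau")
    }
    if (st$epoch >= max_epochs) return("max_epochs")
    "continue"
  }
  st
}

#' Replay a validation-loss sequence through the early-stopping rules
#'
#' Drives [early_stop_monitor()] with a scripted loss sequence and reports
#' where and why training would stop — the protocol's behavior independent of
#' any actual model.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @inheritParams early_stop_monitor
#' @return List with `stop_epoch`, `reason` (`"exhausted"` if the sequence
#'   ends first), `best_epoch` and `min_loss`.
#' @export
replay_early_stopping <- function(val_losses, min_epochs = 50, delta = 0.01,
                                  patience = 1500, max_epochs = 5000) {
  mon <- early_stop_monitor(min_epochs, delta, patience, max_epochs)
  for (loss in val_losses) {
    verdict <- mon$update(loss)
    if (verdict != "continue")
      return(list(stop_epoch = mon$epoch, reason = verdict,
                  best_epoch = mon$best_epoch, min_loss = mon$min_loss))
  }
  list(stop_epoch = mon$epoch, reason = "exhausted",
       best_epoch = mon$best_epoch, min_loss = mon$min_loss)
}
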