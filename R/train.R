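#' Training configuration
#'
#' Defaults follow the study protocol: 100 epochs of adadelta at learning
#' rate 0.05, batch size 128, mean-squared-error loss against one-hot
#' targets, and an adaptive sharpening schedule that starts at epoch 20 and
#' narrows one layer at a time (input-most first) by `sharpen_delta` per
#' advancing epoch, pausing while the training loss is still moving by more
#' than `sharpen_tol` (relative) over a `sharpen_patience`-epoch window.
#'
#' @param epochs number of training epochs.
#' @param learning_rate adadelta learning-rate multiplier.
#' @param batch_size minibatch size.
#' @param seed seed controlling weight init and batch shuffling.
#' @param sharpen_start first epoch eligible for sharpening.
#' @param sharpen_delta half-width decrement per advancing epoch per layer.
#' @param sharpen_patience loss-smoothness window, epochs.
#' @param sharpen_tol relative loss-change tolerance for advancing.
#' @param rho,eps adadelta accumulator decay and stabilizer.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100, learning_rate = 0.05, batch_size = 128,
                         seed = 1, sharpen_start = 20, sharpen_delta = 0.01,
                         sharpen_patience = 3, sharpen_tol = 0.05,
                         rho = 0.95, eps = 1e-6) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            sharpen_delta >= 0, sharpen_patience >= 1, sharpen_tol >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = seed,
                 sharpen_start = sharpen_start, sharpen_delta = sharpen_delta,
                 sharpen_patience = sharpen_patience,
                 sharpen_tol = sharpen_tol, rho = rho, eps = eps),
            class = "train_config")
}

# adadelta step on one gradient array; state carries Eg2/Edx2 accumulators
adadelta_update <- function(par, grad, state, cfg) {
  state$Eg2 <- cfg$rho * state$Eg2 + (1 - cfg$rho) * grad^2
  dx <- -sqrt(state$Edx2 + cfg$eps) / sqrt(state$Eg2 + cfg$eps) * grad
  state$Edx2 <- cfg$rho * state$Edx2 + (1 - cfg$rho) * dx^2
  list(par = par + cfg$learning_rate * dx, state = state)
}

#' Train a sharpened spiking detector
#'
#' Minibatch backpropagation (through time for the recurrent layers) with
#' adadelta and MSE loss against one-hot targets, followed at the end of
#' each eligible epoch by the adaptive sharpening step: the input-most layer
#' whose bounded ReLU is not yet a threshold is narrowed by
#' `cfg$sharpen_delta`, unless the recent training loss is still changing by
#' more than the tolerance, in which case sharpening pauses for that epoch.
#' The run is fully determined by `cfg$seed`.
#'
#' @param spec a [build_detector()] spec.
#' @param train_ds,val_ds training and optional validation `spike_dataset`s
#'   (must share `L_max` with the spec).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return a `trained_detector` with per-epoch `history` (loss, train/val
#'   accuracy, total sharpness, applied delta).
#' @export
train_detector <- function(spec, train_ds, val_ds = NULL, cfg = train_config(),
                           verbose = FALSE) {
  stopifnot(inherits(spec, "detector_spec"), inherits(cfg, "train_config"),
            inherits(train_ds, "spike_dataset"))
  if (train_ds$L_max != spec$L_max)
    stop("training dataset L_max does not match detector spec")
  if (!is.null(val_ds) && val_ds$L_max != spec$L_max)
    stop("validation dataset L_max does not match detector spec")
  if (!all(train_ds$label %in% c(0L, 1L))) stop("labels must be binary")

  X <- dataset_input(train_ds)
  Y <- dataset_onehot(train_ds)
  n <- nrow(X)
  n_layers <- length(spec$layers)

  weights <- init_weights(spec, seed = derive_seed(cfg$seed, "init"))
  states <- replicate(n_layers, brelu_state(0, 1), simplify = FALSE)
  ad_state <- lapply(weights, function(w)
    lapply(w, function(p) list(Eg2 = p * 0, Edx2 = p * 0)))

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0),
                        sharpness = numeric(0), delta = numeric(0))
  loss_hist <- numeric(0)
  policy <- list(start_epoch = cfg$sharpen_start, delta = cfg$sharpen_delta,
                 patience = cfg$sharpen_patience, tol = cfg$sharpen_tol)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed_(derive_seed(cfg$seed, sprintf("epoch%04d", epoch)),
                      sample.int(n))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      layers <- layers_for_cpp(spec, weights, states)
      res <- cpp_nn_grad(layers, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      if (!is.finite(res$loss))
        stop(sprintf("non-finite training loss at epoch %d (batch starting %d)",
                     epoch, start))
      ep_loss <- ep_loss + res$loss * length(idx)
      pred <- max.col(res$out_post, ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == train_ds$label[idx])
      for (li in seq_len(n_layers)) {
        for (pn in names(weights[[li]])) {
          g <- res$grads[[li]][[pn]]
          if (pn == "b") g <- as.numeric(g)
          up <- adadelta_update(weights[[li]][[pn]], g,
                                ad_state[[li]][[pn]], cfg)
          weights[[li]][[pn]] <- up$par
          ad_state[[li]][[pn]] <- up$state
        }
      }
    }
    ep_loss <- ep_loss / n
    loss_hist <- c(loss_hist, ep_loss)

    # sharpening decision for this epoch (never after the final epoch, so a
    # schedule starting at `epochs` leaves the network untouched)
    delta_now <- 0
    if (epoch < cfg$epochs) {
      deltas <- adaptive_schedule(loss_hist, policy)
      delta_now <- deltas[epoch]
      if (delta_now > 0) {
        target <- which(vapply(states, function(s) s$w, 1) > 0)[1]
        if (!is.na(target))
          states[[target]] <- sharpen(states[[target]], delta_now)
        else delta_now <- 0
      }
    }

    val_acc <- NA_real_
    if (!is.null(val_ds)) {
      det_tmp <- new_trained_detector(spec, weights, states,
                                      history = data.frame(), seed = cfg$seed)
      val_acc <- mean(predict(det_tmp, val_ds, "binary") == val_ds$label)
    }
    total_sharp <- sum(vapply(states, sharpness, 1))
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss, train_acc = ep_correct / n,
      val_acc = val_acc, sharpness = total_sharp, delta = delta_now))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  acc %.4f  val %.4f  sharp %.2f",
                      epoch, ep_loss, ep_correct / n, val_acc, total_sharp))
  }
  new_trained_detector(spec, weights, states, history, cfg$seed, cfg)
}
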