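#' Bounded-ReLU activation state
#'
#' The activation is parameterized by `(alpha, beta)` with the symmetry
#' constraint `|beta - 0.5| = |alpha - 0.5|`, equivalently by the half-width
#' `w = (beta - alpha) / 2` of the linear segment about 0.5. Training starts
#' at `(0, 1)` (`w = 0.5`, a unit-slope ramp clipped to `[0, 1]`) and the
#' sharpening schedule shrinks `w` to 0, at which point the activation is a
#' binary threshold at 0.5.
#'
#' @param alpha lower knee.
#' @param beta upper knee; `alpha <= beta`.
#' @return an object of class `brelu_state` with fields `alpha`, `beta`, `w`.
#' @export
brelu_state <- function(alpha = 0, beta = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha <= beta)
  if (abs(abs(beta - 0.5) - abs(alpha - 0.5)) > 1e-12)
    stop("brelu state must satisfy |beta - 0.5| = |alpha - 0.5|")
  w <- (beta - alpha) / 2
  if (w > 0.5 + 1e-12) stop("brelu half-width must lie in [0, 0.5]")
  structure(list(alpha = alpha, beta = beta, w = min(w, 0.5)),
            class = "brelu_state")
}

#' Bounded-ReLU activation
#'
#' Returns 1 where `x >= beta`, 0 where `x <= alpha`, and the linear ramp
#' `(x - alpha) / (beta - alpha)` between. Fully sharpened (`w = 0`) it is a
#' step at 0.5 whose value at exactly 0.5 is 1 (the `x >= beta` branch).
#'
#' @param x numeric scalar, vector, or array.
#' @param state a [brelu_state()].
#' @return values in `[0, 1]`, same shape as `x`.
#' @export
brelu <- function(x, state) {
  stopifnot(inherits(state, "brelu_state"))
  a <- state$alpha; b <- state$beta
  if (b > a) {
    out <- (x - a) / (b - a)
    out[x >= b] <- 1
    out[x <= a] <- 0
  } else {
    out <- as.numeric(x >= 0.5)
    dim(out) <- dim(x)
  }
  out
}

#' Sharpen a bounded-ReLU state
#'
#' Shrinks the half-width by `delta`, preserving the symmetry constraint;
#' idempotent at `w = 0`.
#'
#' @param state a [brelu_state()].
#' @param delta non-negative shrink amount.
#' @return a new `brelu_state`.
#' @export
sharpen <- function(state, delta) {
  stopifnot(inherits(state, "brelu_state"), delta >= 0)
  w <- max(0, state$w - delta)
  brelu_state(0.5 - w, 0.5 + w)
}

#' Sharpness of a bounded-ReLU state
#'
#' `0.5 - w`: 0 for the initial ramp, 0.5 for a fully sharpened threshold.
#'
#' @param state a [brelu_state()].
#' @return scalar in `[0, 0.5]`.
#' @export
sharpness <- function(state) {
  stopifnot(inherits(state, "brelu_state"))
  0.5 - state$w
}

#' Per-epoch sharpening decisions from a training-loss history
#'
#' Implements the adaptive schedule: sharpening advances by `policy$delta`
#' at the end of every epoch from `policy$start_epoch` on, but pauses (delta
#' 0) whenever the relative training-loss change over the trailing
#' `policy$patience`-epoch window exceeds `policy$tol` -- sharpening only
#' proceeds while the loss is settling. The cumulative decision sequence is
#' therefore monotone non-decreasing.
#'
#' @param history numeric vector of per-epoch training losses.
#' @param policy list with `start_epoch`, `delta`, `patience`, `tol`.
#' @return numeric vector, one delta (0 or `policy$delta`) per epoch.
#' @export
adaptive_schedule <- function(history, policy) {
  stopifnot(length(history) >= 1, is.list(policy))
  start <- policy$start_epoch %||% 20
  delta <- policy$delta %||% 0.01
  patience <- policy$patience %||% 3
  tol <- policy$tol %||% 0.05
  vapply(seq_along(history), function(e) {
    if (e < start) return(0)
    win <- history[max(1, e - patience + 1):e]
    if (length(win) >= 2) {
      rel <- abs(diff(win)) / pmax(abs(win[-length(win)]), 1e-12)
      if (max(rel) > tol) return(0)
    }
    delta
  }, numeric(1))
}
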