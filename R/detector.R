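#' Build a detector architecture specification
#'
#' Three named presets:
#' \describe{
#'   \item{`slstm8`}{8 layers: two recurrent spiking (LSTM) layers of width
#'     64, dense spiking layers 256-128-64-32-16, output 2.}
#'   \item{`slstm7`}{as `slstm8` with one dense layer dropped
#'     (256-128-64-32).}
#'   \item{`snn7`}{7 feedforward layers: dense spiking 256-128-64-64-32-16,
#'     output 2, consuming the flattened padded time vector.}
#' }
#' Widths are configuration, not biology: override them with `widths` or
#' scale them uniformly with `widths_scale`. The output layer always has one
#' unit per class. Every layer carries its own bounded-ReLU state, initially
#' `(0, 1)`.
#'
#' @param arch_id `"slstm8"`, `"slstm7"` or `"snn7"`.
#' @param L_max input vector length the detector consumes.
#' @param widths optional integer vector of hidden widths (excluding the
#'   output layer) overriding the preset.
#' @param widths_scale multiplier applied to preset hidden widths.
#' @return an object of class `detector_spec`.
#' @export
build_detector <- function(arch_id = c("slstm8", "slstm7", "snn7"),
                           L_max = 128, widths = NULL, widths_scale = 1) {
  arch_id <- match.arg(arch_id)
  preset <- switch(arch_id,
    slstm8 = list(kinds = c("lstm", "lstm", rep("dense", 5)),
                  widths = c(64, 64, 256, 128, 64, 32, 16)),
    slstm7 = list(kinds = c("lstm", "lstm", rep("dense", 4)),
                  widths = c(64, 64, 256, 128, 64, 32)),
    snn7 = list(kinds = rep("dense", 6),
                widths = c(256, 128, 64, 64, 32, 16)))
  hw <- if (!is.null(widths)) as.integer(widths)
        else pmax(2L, as.integer(round(preset$widths * widths_scale)))
  if (length(hw) != length(preset$kinds))
    stop(sprintf("%s needs %d hidden widths, got %d", arch_id,
                 length(preset$kinds), length(hw)))
  layers <- c(Map(function(k, w) list(kind = k, width = w),
                  preset$kinds, hw),
              list(list(kind = "output", width = 2L)))
  names(layers) <- NULL
  structure(list(arch_id = arch_id, L_max = as.integer(L_max),
                 layers = layers),
            class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("detector_spec '%s' (%d layers, input length %d):\n",
              x$arch_id, length(x$layers), x$L_max))
  for (l in x$layers) cat(sprintf("  %-6s %d\n", l$kind, l$width))
  invisible(x)
}

# Glorot-uniform weight init. The forget-gate bias starts high (3, i.e.
# f ~ 0.95) so the cell can integrate evidence across the full padded
# sequence from the first epoch; dense biases start at 0.5, the center of
# the initial bRELU ramp.
init_weights <- function(spec, seed = NULL) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  build <- function() {
    d_in <- if (spec$layers[[1]]$kind == "lstm") 1L else spec$L_max
    lapply(spec$layers, function(l) {
      if (l$kind == "lstm") {
        H <- l$width
        out <- list(W = glorot(d_in, 4 * H), U = glorot(H, 4 * H),
                    b = c(rep(0, H), rep(3, H), rep(0, 2 * H)))
        d_in <<- H
        out
      } else if (l$kind == "output") {
        # both output units start mid-ramp with small weights, so neither
        # class unit is born in a zero-gradient region of the bounded
        # activation
        out <- list(W = 0.25 * glorot(d_in, l$width), b = rep(0.5, l$width))
        d_in <<- l$width
        out
      } else {
        out <- list(W = glorot(d_in, l$width), b = rep(0, l$width))
        d_in <<- l$width
        out
      }
    })
  }
  with_seed_(seed, build())
}

# assemble the flat layer list the compiled forward/backward consumes
layers_for_cpp <- function(spec, weights, brelu_states) {
  lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    st <- brelu_states[[i]]
    if (l$kind == "lstm") {
      list(type = "lstm", W = weights[[i]]$W, U = weights[[i]]$U,
           b = weights[[i]]$b, alpha = st$alpha, beta = st$beta)
    } else {
      list(type = if (l$kind == "output") "output" else "dense",
           W = weights[[i]]$W, b = weights[[i]]$b,
           alpha = st$alpha, beta = st$beta)
    }
  })
}

# dataset -> model input matrix: padded times scaled into [0, 1] by the
# dataset's own window length, so a common rescaling of times and T_max
# leaves the input (hence predictions) unchanged
dataset_input <- function(ds) ds$times / ds$T_max

dataset_onehot <- function(ds) {
  y <- matrix(0, length(ds$label), 2)
  y[cbind(seq_along(ds$label), ds$label + 1L)] <- 1
  y
}

#' Predict labels or scores for a dataset
#'
#' Binary mode returns the arg-max class over the two output units'
#' pre-threshold activations (a tie is resolved to class 0 and reported
#' via a warning). Score mode returns the PD output unit's pre-threshold
#' activation, suitable for rank-based AUC.
#'
#' @param object a `trained_detector` from [train_detector()].
#' @param ds a `spike_dataset` with the detector's `L_max`.
#' @param mode `"binary"` or `"score"`.
#' @param batch_size inference batch size (memory control only).
#' @param ... unused.
#' @return integer labels (binary mode) or numeric scores.
#' @export
predict.trained_detector <- function(object, ds, mode = c("binary", "score"),
                                     batch_size = 1024, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "spike_dataset"))
  if (ds$L_max != object$spec$L_max)
    stop(sprintf("dataset L_max %d does not match detector L_max %d",
                 ds$L_max, object$spec$L_max))
  X <- dataset_input(ds)
  layers <- layers_for_cpp(object$spec, object$weights, object$brelu)
  n <- nrow(X)
  pre <- matrix(0, n, 2)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- cpp_nn_forward(layers, X[idx, , drop = FALSE], FALSE)
    pre[idx, ] <- fw$out_pre
  }
  if (mode == "score") return(pre[, 2])
  ties <- pre[, 1] == pre[, 2]
  if (any(ties))
    warning(sprintf("%d tied output activations resolved to class 0", sum(ties)))
  as.integer(pre[, 2] > pre[, 1])
}

#' Export trained-detector weights to a hierarchical JSON container
#'
#' One group per layer holding `W`, `U` (recurrent layers), `b`, `alpha`,
#' `beta`; root attributes carry the architecture id, `L_max`, seed and the
#' per-epoch training history. Numeric payloads are written at full
#' precision so `import_weights(export_weights(det))` reproduces the
#' detector exactly.
#'
#' @param det a `trained_detector`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
export_weights <- function(det, path) {
  stopifnot(inherits(det, "trained_detector"))
  payload <- list(
    arch_id = det$spec$arch_id,
    L_max = det$spec$L_max,
    widths = vapply(det$spec$layers, function(l) l$width, 1L),
    kinds = vapply(det$spec$layers, function(l) l$kind, ""),
    seed = det$seed,
    history = as.list(det$history),   # column-wise arrays
    layers = lapply(seq_along(det$spec$layers), function(i) {
      w <- det$weights[[i]]
      st <- det$brelu[[i]]
      c(lapply(w, encode_array), list(alpha = st$alpha, beta = st$beta))
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

# doubles as 17-significant-digit strings: bit-exact across a JSON
# round-trip, which plain JSON numbers are not guaranteed to be
encode_array <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       values = sprintf("%.17g", x))
}

decode_array <- function(a) {
  v <- as.numeric(a$values)
  if (length(a$dim) == 2) matrix(v, a$dim[1], a$dim[2]) else v
}

#' Import a detector exported by [export_weights()]
#'
#' @param path path written by [export_weights()].
#' @return a `trained_detector`.
#' @export
import_weights <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  spec <- build_detector(p$arch_id, L_max = p$L_max,
                         widths = utils::head(p$widths, -1))
  weights <- lapply(seq_along(spec$layers), function(i) {
    li <- p$layers[[i]]
    out <- list(W = decode_array(li$W))
    if (!is.null(li$U)) out$U <- decode_array(li$U)
    out$b <- decode_array(li$b)
    out
  })
  states <- lapply(p$layers, function(li) brelu_state(li$alpha, li$beta))
  new_trained_detector(spec, weights, states,
                       history = as.data.frame(p$history), seed = p$seed)
}

new_trained_detector <- function(spec, weights, brelu_states, history, seed,
                                 cfg = NULL) {
  structure(list(spec = spec, weights = weights, brelu = brelu_states,
                 history = history, seed = seed, cfg = cfg),
            class = "trained_detector")
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf("trained_detector '%s': %d layers, %d epochs trained\n",
              x$spec$arch_id, length(x$spec$layers), nrow(x$history)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss %.5f, train acc %.4f, sharpness %.3f\n",
                last$loss, last$train_acc, last$sharpness))
  }
  invisible(x)
}
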