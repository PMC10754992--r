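#' Memristive device model
#'
#' Default settings follow the reference device: on-state resistance 6 kOhm,
#' off/on resistance ratio 150, 0.5 V read voltage, 2-bit conductance
#' precision (4 levels per device), and 128 x 128 crossbar subarrays.
#'
#' @param R_on on-state resistance, Ohm.
#' @param R_off off-state resistance, Ohm; must exceed `R_on`.
#' @param read_voltage read voltage, V.
#' @param precision_bits device precision in bits (>= 1);
#'   `2^precision_bits` uniformly spaced conductance levels.
#' @param subarray integer pair: maximum rows x cols of one crossbar tile.
#' @return an object of class `device_model`.
#' @export
device_model <- function(R_on = 6e3, R_off = 6e3 * 150, read_voltage = 0.5,
                         precision_bits = 2, subarray = c(128, 128)) {
  stopifnot(R_on > 0, R_off > R_on, read_voltage > 0, precision_bits >= 1,
            length(subarray) == 2, all(subarray >= 1))
  structure(list(R_on = R_on, R_off = R_off, read_voltage = read_voltage,
                 precision_bits = as.integer(precision_bits),
                 subarray = as.integer(subarray),
                 g_on = 1 / R_on, g_off = 1 / R_off),
            class = "device_model")
}

#' Analog vector-matrix multiplication on one crossbar
#'
#' `I_j = sum_i V_i * G[i, j]`: input voltages on the word lines, cell
#' conductances, accumulated bit-line currents.
#'
#' @param V input voltage vector, volts (length = `nrow(G)`).
#' @param G conductance matrix, siemens.
#' @return output current vector, amps (length = `ncol(G)`).
#' @export
vmm <- function(V, G) {
  stopifnot(is.numeric(V), is.matrix(G))
  if (length(V) != nrow(G))
    stop(sprintf("shape mismatch: length(V) = %d, nrow(G) = %d",
                 length(V), nrow(G)))
  as.numeric(V %*% G)
}

quantize_g <- function(g, device) {
  n_lev <- 2^device$precision_bits
  step <- (device$g_on - device$g_off) / (n_lev - 1)
  device$g_off + round((g - device$g_off) / step) * step
}

#' Map a signed weight matrix onto a differential crossbar pair
#'
#' Positive weight parts map onto `G_pos`, magnitudes of negative parts
#' onto `G_neg`; `[0, max|W|]` maps linearly onto `[1/R_off, 1/R_on]` and
#' each conductance is rounded to the nearest of the `2^precision_bits`
#' uniform levels. A zero entry sits at the lowest level on both arrays, so
#' the differential current cancels exactly. The weight-per-siemens `scale`
#' is recorded for the inverse map.
#'
#' @param W weight matrix (any sign); an all-zero matrix is valid and maps
#'   to minimum conductance everywhere.
#' @param device a [device_model()].
#' @return an object of class `crossbar_pair`: `G_pos`, `G_neg`, `device`,
#'   `scale`, `offset` (0 for this shared-baseline encoding).
#' @export
weights_to_conductance <- function(W, device = device_model()) {
  stopifnot(is.matrix(W), inherits(device, "device_model"))
  wmax <- max(abs(W))
  span <- device$g_on - device$g_off
  if (wmax == 0) {
    Gp <- Gn <- matrix(device$g_off, nrow(W), ncol(W))
    scale <- 0
  } else {
    Gp <- quantize_g(device$g_off + pmax(W, 0) / wmax * span, device)
    Gn <- quantize_g(device$g_off + pmax(-W, 0) / wmax * span, device)
    scale <- wmax / span
  }
  structure(list(G_pos = Gp, G_neg = Gn, device = device, scale = scale,
                 offset = 0),
            class = "crossbar_pair")
}

#' Reconstruct weights from a crossbar pair
#'
#' Exact inverse of the differential mapping before quantization:
#' `(G_pos - G_neg - offset) * scale`. With quantization, the per-weight
#' reconstruction error is at most half a conductance step times `scale`.
#'
#' @param pair a [weights_to_conductance()] pair.
#' @return weight matrix.
#' @export
conductance_to_weight <- function(pair) {
  stopifnot(inherits(pair, "crossbar_pair"))
  (pair$G_pos - pair$G_neg - pair$offset) * pair$scale
}

#' Tiled differential matrix product through crossbar subarrays
#'
#' Computes `X %*% W_hat` where `W_hat` is the (quantized) weight matrix
#' the pair encodes. Input rows are scaled to read voltages, matrices
#' larger than the device subarray are partitioned into tiles of at most
#' `subarray[1] x subarray[2]`, partial bit-line currents of the positive
#' and negative arrays are accumulated and subtracted, and the result is
#' rescaled by `scale / read_voltage`.
#'
#' @param pair a `crossbar_pair`.
#' @param X input matrix, columns = `nrow(G_pos)`.
#' @return matrix `X %*% W_hat`.
#' @export
tiled_matmul <- function(pair, X) {
  stopifnot(inherits(pair, "crossbar_pair"), is.matrix(X))
  Gp <- pair$G_pos; Gn <- pair$G_neg
  if (ncol(X) != nrow(Gp))
    stop(sprintf("shape mismatch: ncol(X) = %d, crossbar rows = %d",
                 ncol(X), nrow(Gp)))
  v <- pair$device$read_voltage
  sub <- pair$device$subarray
  V <- X * v
  I_diff <- matrix(0, nrow(X), ncol(Gp))
  row_blocks <- split(seq_len(nrow(Gp)), ceiling(seq_len(nrow(Gp)) / sub[1]))
  col_blocks <- split(seq_len(ncol(Gp)), ceiling(seq_len(ncol(Gp)) / sub[2]))
  for (rb in row_blocks) {
    Vb <- V[, rb, drop = FALSE]
    for (cb in col_blocks) {
      I_diff[, cb] <- I_diff[, cb] +
        Vb %*% (Gp[rb, cb, drop = FALSE] - Gn[rb, cb, drop = FALSE])
    }
  }
  I_diff / v * pair$scale
}

#' Run detector inference through simulated crossbars
#'
#' Every dense-layer and recurrent-projection matrix product of the
#' detector is executed through [tiled_matmul()] on differential,
#' quantized conductance pairs built from the trained weights; activations,
#' biases and thresholds stay in software. At fine quantization
#' (`precision_bits` large) this reproduces software [predict()] exactly up
#' to float associativity.
#'
#' @param det a `trained_detector`.
#' @param ds a `spike_dataset`.
#' @param device a [device_model()].
#' @param batch_size inference batch size.
#' @return integer predicted labels.
#' @export
crossbar_predict <- function(det, ds, device = device_model(),
                             batch_size = 1024) {
  stopifnot(inherits(det, "trained_detector"), inherits(ds, "spike_dataset"))
  if (ds$L_max != det$spec$L_max)
    stop("dataset L_max does not match detector")
  pairs <- lapply(det$weights, function(w) {
    out <- list(W = weights_to_conductance(w$W, device))
    if (!is.null(w$U)) out$U <- weights_to_conductance(w$U, device)
    out
  })
  mm <- function(X, li, which) tiled_matmul(pairs[[li]][[which]], X)
  X <- dataset_input(ds)
  n <- nrow(X)
  pre <- matrix(0, n, 2)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    pre[idx, ] <- nn_forward_r(det, X[idx, , drop = FALSE], mm)$out_pre
  }
  as.integer(pre[, 2] > pre[, 1])
}

# Pure-R forward pass mirroring the compiled engine, with a pluggable
# matrix-product backend mm(X, layer_index, "W"|"U") so the crossbar path
# can route every projection through tiled_matmul().
nn_forward_r <- function(det, X, mm = function(X, li, which)
                           X %*% det$weights[[li]][[which]]) {
  spec <- det$spec
  sigm <- function(z) 1 / (1 + exp(-z))
  seq_in <- NULL; flat <- NULL
  if (spec$layers[[1]]$kind == "lstm") {
    L <- ncol(X)
    seq_in <- lapply(seq_len(L), function(t) X[, t, drop = FALSE])
  } else flat <- X
  out_pre <- NULL
  for (li in seq_along(spec$layers)) {
    lay <- spec$layers[[li]]
    st <- det$brelu[[li]]
    if (lay$kind == "lstm") {
      H <- lay$width
      B <- nrow(X)
      h <- matrix(0, B, H); cc <- matrix(0, B, H)
      E <- vector("list", length(seq_in))
      b <- det$weights[[li]]$b
      for (t in seq_along(seq_in)) {
        z <- mm(seq_in[[t]], li, "W") + mm(h, li, "U")
        z <- sweep(z, 2, b, `+`)
        gi <- sigm(z[, 1:H, drop = FALSE])
        gf <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
        gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
        go <- sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
        cc <- gf * cc + gi * gg
        h <- go * tanh(cc)
        E[[t]] <- brelu(0.5 * (h + 1), st)   # [-1,1] -> bRELU domain
      }
      seq_in <- E
    } else {
      if (!is.null(seq_in)) { flat <- seq_in[[length(seq_in)]]; seq_in <- NULL }
      A <- mm(flat, li, "W")
      A <- sweep(A, 2, det$weights[[li]]$b, `+`)
      flat <- brelu(A, st)
      if (lay$kind == "output") out_pre <- A
    }
  }
  list(out_pre = out_pre, out_post = flat)
}
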