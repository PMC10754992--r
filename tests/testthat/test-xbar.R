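test_that("vmm computes bit-line currents as V times G", {
  G <- matrix(2e-4, 5, 4)
  expect_equal(vmm(rep(0.5, 5), G), rep(5 * 0.5 * 2e-4, 4))
  G2 <- matrix(runif(20, 1e-6, 1e-4), 5, 4)
  expect_equal(vmm(c(0, 0, 1, 0, 0), G2), G2[3, ])      # unit vector -> row
  set.seed(2)
  V <- runif(5)
  expect_lt(max(abs(vmm(V, G2) - as.numeric(V %*% G2))) /
              max(abs(V %*% G2)), 1e-12)
  expect_error(vmm(rep(1, 3), G2), "shape mismatch")
})

test_that("vmm is linear (property)", {
  set.seed(3)
  G <- matrix(runif(30, 1e-6, 1e-4), 6, 5)
  v1 <- rnorm(6); v2 <- rnorm(6)
  expect_equal(vmm(2 * v1 - 3 * v2, G),
               2 * vmm(v1, G) - 3 * vmm(v2, G), tolerance = 1e-12)
})

test_that("weight-to-conductance mapping hits the stated endpoints", {
  dev <- device_model()
  W0 <- matrix(0, 3, 3)
  p0 <- weights_to_conductance(W0, dev)
  expect_true(all(p0$G_pos == dev$g_off))
  expect_true(all(p0$G_neg == dev$g_off))
  expect_equal(conductance_to_weight(p0), W0)
  W <- matrix(c(0.8, -0.4, 0, 0.1), 2, 2)
  p <- weights_to_conductance(W, dev)
  expect_equal(p$G_pos[1, 1], dev$g_on)                 # max|W| -> 1/R_on
  expect_true(all(p$G_pos >= dev$g_off & p$G_pos <= dev$g_on))
  expect_true(all(p$G_neg >= dev$g_off & p$G_neg <= dev$g_on))
})

test_that("conductances sit on the quantized grid", {
  dev <- device_model(precision_bits = 2)
  set.seed(4)
  W <- matrix(rnorm(64), 8, 8)
  p <- weights_to_conductance(W, dev)
  levels <- dev$g_off +
    (0:3) * (dev$g_on - dev$g_off) / 3
  expect_true(all(vapply(p$G_pos, function(g)
    min(abs(g - levels)) < 1e-18, TRUE)))
})

test_that("8-bit round-trip error is bounded by half a quantization step", {
  set.seed(5)
  for (i in 1:10) {
    W <- matrix(rnorm(12 * 7), 12, 7)
    dev <- device_model(precision_bits = 8)
    p <- weights_to_conductance(W, dev)
    step <- (dev$g_on - dev$g_off) / (2^8 - 1)
    bound <- step / 2 * p$scale
    expect_lte(max(abs(conductance_to_weight(p) - W)), bound + 1e-15)
  }
})

test_that("tiling is invariant to the subarray partition (up to 512 x 512)", {
  set.seed(6)
  for (dims in list(c(64, 40), c(200, 130), c(512, 512))) {
    W <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    X <- matrix(rnorm(3 * dims[1]), 3, dims[1])
    small <- weights_to_conductance(W, device_model(precision_bits = 8,
                                                    subarray = c(128, 128)))
    whole <- weights_to_conductance(W, device_model(precision_bits = 8,
                                                    subarray = dims))
    expect_equal(tiled_matmul(small, X), tiled_matmul(whole, X),
                 tolerance = 1e-12)
    # and both equal the direct differential product
    direct <- (X * small$device$read_voltage) %*%
      (small$G_pos - small$G_neg) / small$device$read_voltage * small$scale
    expect_equal(tiled_matmul(small, X), direct, tolerance = 1e-12)
  }
})

test_that("crossbar inference tracks software inference as precision grows", {
  fx <- small_snn()
  val <- fx$parts$val
  soft <- predict(fx$det, val)
  agree8 <- mean(crossbar_predict(fx$det, val,
                                  device_model(precision_bits = 8)) == soft)
  expect_gte(agree8, 0.99)
  agree16 <- mean(crossbar_predict(fx$det, val,
                                   device_model(precision_bits = 16)) == soft)
  expect_equal(agree16, 1)
})

test_that("low-contrast and low-precision devices still run", {
  fx <- small_lstm()
  val <- spikesharp:::dataset_subset(fx$parts$val, 1:20)
  for (dev in list(device_model(R_off = 6e3 * 150, precision_bits = 2),
                   device_model(R_off = 6e3 * 10, precision_bits = 2))) {
    pred <- crossbar_predict(fx$det, val, dev)
    expect_true(all(pred %in% c(0L, 1L)))
    expect_length(pred, 20)
  }
})
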