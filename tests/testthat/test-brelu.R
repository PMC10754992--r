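test_that("bounded ReLU branches match the definition", {
  st <- brelu_state(0, 1)
  expect_equal(brelu(1.5, st), 1)          # x >= beta
  expect_equal(brelu(0.75, st), 0.75)      # identity on the linear segment
  expect_equal(brelu(-0.2, st), 0)
  st2 <- brelu_state(0.4, 0.6)
  expect_equal(brelu(0.5, st2), 0.5)
  step <- brelu_state(0.5, 0.5)            # fully sharpened
  expect_equal(brelu(0.49, step), 0)
  expect_equal(brelu(0.51, step), 1)
  expect_equal(brelu(0.5, step), 1)        # value at exactly 0.5 is 1
})

test_that("brelu is monotone, bounded and shape-preserving (property)", {
  set.seed(31)
  for (i in 1:25) {
    w <- runif(1, 0, 0.5)
    st <- brelu_state(0.5 - w, 0.5 + w)
    x <- sort(runif(200, -2, 3))
    y <- brelu(x, st)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= 0 & y <= 1))
  }
  m <- matrix(rnorm(12), 3, 4)
  expect_identical(dim(brelu(m, brelu_state())), dim(m))
})

test_that("the symmetry constraint is enforced", {
  expect_error(brelu_state(0.1, 0.7), "symmetry|0.5")
  expect_silent(brelu_state(0.25, 0.75))
})

test_that("sharpen narrows symmetrically and is idempotent at w = 0", {
  st <- sharpen(brelu_state(0, 1), 0.1)
  expect_equal(c(st$alpha, st$beta), c(0.1, 0.9))
  fixed <- brelu_state(0.5, 0.5)
  expect_equal(sharpen(fixed, 0.3), fixed)
  # exactly 10 steps of 0.05 from the initial ramp reach the threshold
  st <- brelu_state(0, 1)
  for (i in 1:10) st <- sharpen(st, 0.05)
  expect_equal(st$w, 0)
  expect_equal(sharpness(st), 0.5)
})

test_that("adaptive schedule advances on smooth loss and pauses on rough", {
  policy <- list(start_epoch = 3, delta = 0.02, patience = 3, tol = 0.05)
  smooth <- rep(0.4, 10)
  d <- adaptive_schedule(smooth, policy)
  expect_equal(d, c(0, 0, rep(0.02, 8)))   # every eligible epoch advances
  spiky <- c(0.4, 0.4, 0.4, 0.4, 0.8, 0.4, 0.4, 0.4)
  d2 <- adaptive_schedule(spiky, policy)
  expect_equal(d2[5], 0)                    # the spike pauses sharpening
  expect_equal(d2[6], 0)                    # still inside the patience window
  expect_equal(d2[8], 0.02)
})

test_that("a schedule starting at the final epoch leaves the network unsharpened", {
  parts <- small_lstm()$parts
  spec <- build_detector("snn7", widths = c(8, 4, 4, 4, 4, 4))
  cfg <- train_config(epochs = 4, seed = 2, sharpen_start = 4)
  det <- train_detector(spec, parts$train, cfg = cfg)
  expect_true(all(vapply(det$brelu, function(s) s$w, 1) == 0.5))
  expect_equal(det$history$sharpness, rep(0, 4))
})

test_that("total sharpness is monotone non-decreasing during training", {
  parts <- small_lstm()$parts
  spec <- build_detector("snn7", widths = c(8, 4, 4, 4, 4, 4))
  det <- train_detector(spec, parts$train, cfg = train_config(
    epochs = 8, seed = 3, sharpen_start = 2, sharpen_delta = 0.05,
    sharpen_tol = 10))   # loose tolerance so the schedule always advances
  expect_true(all(diff(det$history$sharpness) >= 0))
  expect_gt(max(det$history$sharpness), 0)
})
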