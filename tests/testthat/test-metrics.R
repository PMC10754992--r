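test_that("confusion counts partition the evaluated samples", {
  lab <- c(rep(1, 10), rep(0, 10))
  cc <- confusion(lab, lab)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 10, TN = 10, FP = 0, FN = 0))
  inv <- confusion(lab, 1 - lab)
  expect_equal(inv$TP + inv$TN, 0)
  expect_equal(inv$FP + inv$FN, 20)
})

test_that("metric identities hold for random confusion matrices (property)", {
  for (cc in random_confusions(200)) {
    m <- metrics_from_confusion(cc)
    if (!is.na(m$ACC)) expect_equal(m$ACC + m$MCR, 1)
    if (!is.na(m$recall)) expect_equal(m$recall + m$FNR, 1)
    if (!is.na(m$specificity)) expect_equal(m$specificity + m$FPR, 1)
    if (!is.na(m$MCC)) expect_true(m$MCC >= -1 && m$MCC <= 1)
    for (nm in c("ACC", "precision", "recall", "specificity", "F1"))
      if (!is.na(m[[nm]])) expect_true(m[[nm]] >= 0 && m[[nm]] <= 1)
  }
})

test_that("metrics agree with an independent brute-force implementation", {
  # brute force: expand counts into label/prediction vectors and recount
  brute <- function(cc) {
    lab <- c(rep(1, cc$TP), rep(0, cc$TN), rep(0, cc$FP), rep(1, cc$FN))
    prd <- c(rep(1, cc$TP), rep(0, cc$TN), rep(1, cc$FP), rep(0, cc$FN))
    n <- length(lab)
    list(ACC = sum(lab == prd) / n,
         precision = if (sum(prd) == 0) NA_real_ else
           sum(lab & prd) / sum(prd),
         recall = if (sum(lab) == 0) NA_real_ else
           sum(lab & prd) / sum(lab),
         MCC = {
           num <- cc$TP * cc$TN - cc$FP * cc$FN
           den <- sqrt(cc$TP + cc$FP) * sqrt(cc$TP + cc$FN) *
             sqrt(cc$TN + cc$FP) * sqrt(cc$TN + cc$FN)
           if (den == 0) NA_real_ else num / den
         })
  }
  for (cc in random_confusions(1000, seed = 99)) {
    m <- metrics_from_confusion(cc)
    b <- brute(cc)
    expect_equal(m$ACC, b$ACC)
    expect_equal(m$precision, b$precision)
    expect_equal(m$recall, b$recall)
    expect_equal(m$MCC, b$MCC)
  }
})

test_that("degenerate confusions flag undefined metrics instead of inventing", {
  cc <- confusion(c(0, 0), c(0, 0))    # no positives anywhere
  m <- metrics_from_confusion(cc)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_true("precision" %in% attr(m, "undefined"))
  expect_true(is.na(m$AUC))            # no scores provided, never fabricated
})

test_that("all-correct counts give unit metrics and zero MCR", {
  m <- metrics_from_confusion(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  for (nm in c("ACC", "precision", "recall", "specificity", "F1", "MCC"))
    expect_equal(m[[nm]], 1)
  expect_equal(m$MCR, 0)
  expect_equal(m$FPR, 0)
})

test_that("rank AUC is 1 for a perfect scorer and ~0.5 for a random one", {
  set.seed(21)
  lab <- rep(c(0, 1), each = 500)
  perfect <- lab + runif(1000, 0, 0.5)
  expect_equal(auc_rank(lab, perfect), 1)
  noise <- rnorm(1000)
  expect_lt(abs(auc_rank(lab, noise) - 0.5), 0.05)
})

test_that("rank AUC matches the pROC reference with ties", {
  skip_if_not_installed("pROC")
  set.seed(33)
  lab <- rbinom(200, 1, 0.4)
  sc <- round(rnorm(200), 1)            # rounding forces ties
  ours <- auc_rank(lab, sc)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("evaluate composes predict, confusion and the metric set", {
  fx <- small_snn()
  rep <- evaluate(fx$det, fx$parts$val)
  cc <- rep$counts
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, nrow(fx$parts$val$times))
  expect_equal(rep$ACC, (cc$TP + cc$TN) / nrow(fx$parts$val$times))
  expect_false(is.na(rep$AUC))
})
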