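test_that("unmodulated generator has the nominal Poisson mean count", {
  # refractory-corrected renewal: mean count over [0, 2500] ms at 10 Hz is 25
  set.seed(5)
  p <- pheno_params()
  counts <- replicate(1000,
    sum(generate_sample(p, "healthy")$spike_times != 0))
  expect_lt(abs(mean(counts) - 25), 3 * sd(counts) / sqrt(1000))
})

test_that("zero rate yields a fully padded sample", {
  p <- pheno_params(rate_healthy = 0)
  s <- generate_sample(p, "healthy")
  expect_identical(s$spike_times, numeric(128))
  expect_identical(s$label, 0L)
})

test_that("sample invariants hold for both states", {
  set.seed(8)
  p <- pheno_params()
  for (state in c("healthy", "pd")) {
    for (i in 1:20) {
      s <- generate_sample(p, state, duration = 2000)
      nz <- s$spike_times[s$spike_times != 0]
      expect_true(all(nz > 0 & nz <= 2000))
      expect_true(all(diff(nz) > 0))                     # strictly increasing
      n <- length(nz)
      expect_identical(s$spike_times[seq_len(n)], nz)    # prefix, zeros trail
    }
  }
})

test_that("overflow beyond L_max raises rather than truncates", {
  p <- pheno_params(rate_healthy = 10, rate_pd = 80)
  expect_error(generate_sample(p, "pd", duration = 2500, L_max = 128),
               "exceeds L_max")
  expect_error(generate_sample(p, "pd", duration = 2500, L_max = 64),
               "L_max")
})

test_that("dataset size and class counts are exact", {
  ds <- generate_dataset(pheno_params(seed = 3), 4, 5)
  expect_equal(nrow(ds$times), 2 * 4 * 5)
  expect_equal(unname(class_counts(ds)), c(20L, 20L))
  one <- generate_dataset(pheno_params(seed = 3), 1, 1)
  expect_equal(nrow(one$times), 2L)
  expect_setequal(one$label, c(0L, 1L))
})

test_that("PD samples fire denser than healthy at shipped defaults", {
  ds <- generate_dataset(pheno_params(seed = 77), 20, 10)  # 200 per class
  counts <- rowSums(ds$times != 0)
  expect_gt(mean(counts[ds$label == 1]), mean(counts[ds$label == 0]))
})

test_that("splits partition the dataset with the printed sizes", {
  ds <- small_ds()
  n <- nrow(ds$times)
  for (f in c(0.6, 0.75, 0.9)) {
    parts <- split_dataset(ds, f, seed = 4)
    expect_equal(nrow(parts$train$times), round(f * n))
    expect_equal(nrow(parts$val$times), n - round(f * n))
    ids <- c(parts$train$sample_id, parts$val$sample_id)
    expect_setequal(ids, ds$sample_id)          # union is the dataset
    expect_equal(anyDuplicated(ids), 0L)        # intersection empty
    cc <- class_counts(parts$train)
    expect_lte(abs(cc[["pd"]] - cc[["healthy"]]), 1)  # stratification
  }
})

test_that("stratified splitting fails on a single-class dataset", {
  ds <- generate_dataset(pheno_params(seed = 2), 2, 2,
                         conditions = "healthy")
  expect_error(split_dataset(ds, 0.5, stratified = TRUE, seed = 1),
               "empty class")
})

test_that("dataset generation is reproducible from its seed", {
  a <- generate_dataset(pheno_params(seed = 55), 3, 4)
  b <- generate_dataset(pheno_params(seed = 55), 3, 4)
  expect_identical(a$times, b$times)
  expect_identical(a$label, b$label)
})
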