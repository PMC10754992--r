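# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 600-sample phenomenological dataset at shipped generator defaults
small_ds <- function() fixture("small_ds", function()
  generate_dataset(pheno_params(seed = 101), n_groups = 30,
                   neurons_per_group = 10))

# compact feedforward detector trained to convergence on small_ds
small_snn <- function() fixture("small_snn", function() {
  parts <- split_dataset(small_ds(), 0.75, seed = 11)
  det <- train_detector(build_detector("snn7", widths_scale = 0.5),
                        parts$train, parts$val,
                        train_config(epochs = 25, seed = 5))
  list(det = det, parts = parts)
})

# tiny recurrent detector (short training; used for consistency checks, not
# for accuracy claims)
small_lstm <- function() fixture("small_lstm", function() {
  parts <- split_dataset(small_ds(), 0.75, seed = 12)
  det <- train_detector(build_detector("slstm8",
                                       widths = c(8, 8, 16, 8, 8, 4, 4)),
                        parts$train, NULL,
                        train_config(epochs = 3, seed = 6))
  list(det = det, parts = parts)
})

# random confusion-count tuples for metric property tests
random_confusions <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    counts <- as.integer(rmultinom(1, sample(10:500, 1), runif(4, 0.05, 1)))
    structure(list(TP = counts[1], TN = counts[2], FP = counts[3],
                   FN = counts[4]), class = "confusion_counts")
  })
}
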