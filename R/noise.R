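#' Gaussian spike-timing noise specification
#'
#' Describes the jitter protocol: every nonzero spike-timing entry `v` is
#' replaced by `v + N(mu, sigma)`; padding zeros are untouched. The study's
#' three settings are (mu = 7, sigma = 4), (15, 12) and (30, 25) ms.
#'
#' @param mu mean shift, ms.
#' @param sigma standard deviation, ms (>= 0).
#' @param seed optional seed for the draws.
#' @param applies_to which partition the noise targets when used in a
#'   pipeline: `"train"`, `"val"` or `"both"`.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(mu, sigma, seed = NULL,
                       applies_to = c("both", "train", "val")) {
  stopifnot(is.numeric(mu), is.numeric(sigma), sigma >= 0)
  applies_to <- match.arg(applies_to)
  structure(list(mu = mu, sigma = sigma, seed = seed,
                 applies_to = applies_to),
            class = "noise_spec")
}

#' Add Gaussian timing jitter to a dataset
#'
#' Faithful in-place replacement: one independent `N(mu, sigma)` draw per
#' nonzero entry (assigned in column-major order), zeros untouched, results
#' clipped into `(0, T_max]` (floored at the 0.001-ms resolution) and NOT
#' re-sorted, so sample cardinality and entry positions are preserved.
#' Deterministic under a fixed `spec$seed`. Perturbed samples are marked
#' `source = "file"` since their trains need no longer be increasing.
#'
#' @param ds a `spike_dataset`.
#' @param spec a [noise_spec()].
#' @return a new `spike_dataset` with noise provenance recorded.
#' @export
add_timing_noise <- function(ds, spec) {
  stopifnot(inherits(ds, "spike_dataset"), inherits(spec, "noise_spec"))
  if (spec$mu == 0 && spec$sigma == 0) return(ds)   # degenerate: identity
  tm <- ds$times
  nz <- which(tm != 0)
  draws <- with_seed_(spec$seed,
                      stats::rnorm(length(nz), spec$mu, spec$sigma))
  x <- tm[nz] + draws
  x <- pmin(x, ds$T_max)
  x[x < 0.001] <- 0.001
  tm[nz] <- round(x, 3)
  prov <- ds$provenance
  prov$noise <- list(mu = spec$mu, sigma = spec$sigma, seed = spec$seed)
  new_spike_dataset(tm, ds$label, ds$sample_id,
                    rep("file", length(ds$label)), ds$T_max, ds$L_max, prov)
}

#' Noise-robustness protocol
#'
#' For each seed: generate a fresh dataset at the given generator settings,
#' split it (75/25 stratified by default), and for the clean baseline plus
#' each jitter setting apply the noise to the configured partitions, train a
#' fresh detector, and evaluate on the (possibly noisy) validation
#' partition. Same split fraction and training protocol throughout.
#'
#' @param arch architecture id passed to [build_detector()].
#' @param gen_params a [pheno_params()] object (its seed field is ignored;
#'   per-seed dataset seeds are derived from `seeds`).
#' @param n_groups,neurons_per_group,duration dataset size settings.
#' @param settings list of `c(mu, sigma)` pairs; `c(0, 0)` is the clean
#'   baseline. Defaults to clean plus the three study settings.
#' @param cfg a [train_config()]; its seed is re-derived per run.
#' @param seeds integer vector of replicate seeds.
#' @param train_frac split fraction.
#' @param applies_to partitions receiving noise.
#' @param widths_scale detector width multiplier.
#' @return data.frame: one row per (setting, seed) with mu, sigma, seed and
#'   the ten performance measures.
#' @export
noise_robustness_report <- function(arch = "slstm8",
                                    gen_params = pheno_params(),
                                    n_groups = 100, neurons_per_group = 10,
                                    duration = 2500,
                                    settings = list(c(0, 0), c(7, 4),
                                                    c(15, 12), c(30, 25)),
                                    cfg = train_config(),
                                    seeds = 1:3, train_frac = 0.75,
                                    applies_to = "both", widths_scale = 1) {
  rows <- list()
  for (seed in seeds) {
    gp <- gen_params
    gp$seed <- derive_seed(seed, "noise-gen")
    ds <- generate_dataset(gp, n_groups, neurons_per_group, duration)
    parts <- split_dataset(ds, train_frac, stratified = TRUE,
                           seed = derive_seed(seed, "noise-split"))
    for (si in seq_along(settings)) {
      mu <- settings[[si]][1]; sigma <- settings[[si]][2]
      tr <- parts$train; va <- parts$val
      if (mu != 0 || sigma != 0) {
        if (applies_to %in% c("both", "train"))
          tr <- add_timing_noise(tr, noise_spec(mu, sigma,
                 seed = derive_seed(seed, sprintf("noise-tr-%d", si))))
        if (applies_to %in% c("both", "val"))
          va <- add_timing_noise(va, noise_spec(mu, sigma,
                 seed = derive_seed(seed, sprintf("noise-va-%d", si))))
      }
      run_cfg <- cfg
      run_cfg$seed <- derive_seed(seed, sprintf("noise-train-%d", si))
      det <- train_detector(build_detector(arch, L_max = ds$L_max,
                                           widths_scale = widths_scale),
                            tr, cfg = run_cfg)
      rep_row <- as.data.frame(evaluate(det, va))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(setting = if (mu == 0 && sigma == 0) "clean"
                             else sprintf("mu%g_sd%g", mu, sigma),
                   mu = mu, sigma = sigma, seed = seed),
        rep_row)
    }
  }
  do.call(rbind, rows)
}
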