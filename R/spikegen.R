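#' Parameters of the phenomenological spike-train generator
#'
#' The generator emulates subthalamic-nucleus (STN) single-unit activity in
#' the two clinical states. Healthy trains are refractory-modified Poisson
#' processes at `rate_healthy`. Parkinsonian (PD) trains are inhomogeneous
#' renewal processes whose hazard is modulated at a beta-band frequency,
#' `rate_pd * (1 + mod_depth * sin(2*pi*beta_freq*t + phi))` with a uniform
#' random phase per sample, reproducing the two biomarkers the detector
#' relies on: denser PD firing and elevated PD beta-band (13-30 Hz) power.
#'
#' The refractory period is honoured by construction (inter-spike gaps are
#' `refractory + ` an exponential variate) and the exponential rate is
#' corrected so the long-run mean firing rate equals the nominal rate.
#'
#' @param rate_healthy healthy-state firing rate, Hz.
#' @param rate_pd PD-state firing rate, Hz; must exceed `rate_healthy`.
#' @param beta_freq beta modulation frequency, Hz, within 13-30.
#' @param mod_depth modulation depth in `[0, 1]`.
#' @param refractory absolute refractory period, ms.
#' @param seed optional master seed recorded in dataset provenance and used
#'   by [generate_dataset()].
#' @return an object of class `pheno_params`.
#' @export
pheno_params <- function(rate_healthy = 10, rate_pd = 25, beta_freq = 20,
                         mod_depth = 0.8, refractory = 3, seed = NULL) {
  stopifnot(rate_healthy >= 0, rate_pd > rate_healthy,
            beta_freq >= 13, beta_freq <= 30,
            mod_depth >= 0, mod_depth <= 1, refractory >= 0)
  structure(list(rate_healthy = rate_healthy, rate_pd = rate_pd,
                 beta_freq = beta_freq, mod_depth = mod_depth,
                 refractory = refractory, seed = seed),
            class = "pheno_params")
}

# Renewal / thinning core (compiled): rate in Hz, modulation depth, phase in
# radians. Returns strictly increasing spike times (ms) in (0, duration].
sim_train <- function(rate_hz, mod_depth, beta_freq, phase, refractory,
                      duration) {
  cpp_sim_train(rate_hz, mod_depth, beta_freq, phase, refractory, duration)
}

#' Generate one labeled spike-timing sample
#'
#' Draws a single neuron's spike train for the given state and zero-pads it
#' to length `L_max`. Uses the ambient RNG stream; seed at the dataset level
#' via [generate_dataset()] or `set.seed()`.
#'
#' @param params a [pheno_params()] object.
#' @param state `"healthy"` or `"pd"`.
#' @param duration recording window, ms; spike times lie in `(0, duration]`.
#' @param L_max padded vector length.
#' @param sample_id identifier stored with the sample.
#' @return a `spike_sample` list: `spike_times` (length `L_max`,
#'   zero-padded, 0.001-ms resolution), `label` (0 healthy / 1 PD),
#'   `sample_id`, `source = "pheno"`.
#' @export
generate_sample <- function(params, state = c("healthy", "pd"),
                            duration = 2500, L_max = 128,
                            sample_id = "s_000001") {
  stopifnot(inherits(params, "pheno_params"), duration > 0)
  state <- match.arg(state)
  rate <- if (state == "pd") params$rate_pd else params$rate_healthy
  mod <- if (state == "pd") params$mod_depth else 0
  expected <- rate * duration / 1000
  if (expected > L_max)
    stop(sprintf("expected spike count %.1f exceeds L_max = %d", expected, L_max))
  phase <- if (mod > 0) stats::runif(1, 0, 2 * pi) else 0
  times <- sim_train(rate, mod, params$beta_freq, phase, params$refractory,
                     duration)
  if (length(times) > L_max)
    stop(sprintf("sample overflow: %d spikes exceed L_max = %d (not truncated)",
                 length(times), L_max))
  times <- round(times, 3)
  # 0.001-ms file resolution can tie only when refractory < 0.001 ms
  if (length(times) > 1)
    for (i in 2:length(times))
      if (times[i] <= times[i - 1]) times[i] <- times[i - 1] + 0.001
  times <- pmin(times, duration)
  structure(list(spike_times = c(times, numeric(L_max - length(times))),
                 label = if (state == "pd") 1L else 0L,
                 sample_id = sample_id, source = "pheno"),
            class = "spike_sample")
}

# dataset constructor shared by all generators
new_spike_dataset <- function(times, label, sample_id, source, T_max, L_max,
                              provenance) {
  stopifnot(is.matrix(times), nrow(times) == length(label),
            length(sample_id) == length(label),
            length(source) == length(label), ncol(times) == L_max)
  structure(list(times = times, label = as.integer(label),
                 sample_id = as.character(sample_id),
                 source = as.character(source),
                 T_max = T_max, L_max = as.integer(L_max),
                 provenance = provenance),
            class = "spike_dataset")
}

#' Number of samples per class
#' @param ds a `spike_dataset`.
#' @return named integer vector `c(healthy = , pd = )`.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "spike_dataset"))
  c(healthy = sum(ds$label == 0L), pd = sum(ds$label == 1L))
}

#' @export
print.spike_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf(
    "spike_dataset: %d samples (%d healthy / %d pd), T_max = %g ms, L_max = %d\n",
    nrow(x$times), cc[["healthy"]], cc[["pd"]], x$T_max, x$L_max))
  cat(sprintf("generator: %s\n", x$provenance$generator %||% "unknown"))
  invisible(x)
}

#' Generate a labeled healthy/PD spike-timing dataset
#'
#' Emits `n_groups * neurons_per_group` per-neuron samples per condition
#' (both conditions by default), i.e. `2 * n_groups * neurons_per_group`
#' samples in total. The group index is provenance only; the classifier's
#' unit of input is one neuron's padded spike-time vector.
#'
#' @inheritParams generate_sample
#' @param n_groups number of multi-neuron recording groups per condition.
#' @param neurons_per_group neurons per group.
#' @param conditions which conditions to emit.
#' @return a `spike_dataset`.
#' @export
generate_dataset <- function(params, n_groups, neurons_per_group,
                             duration = 2500, L_max = 128,
                             conditions = c("healthy", "pd")) {
  stopifnot(inherits(params, "pheno_params"),
            n_groups >= 1, neurons_per_group >= 1)
  conditions <- match.arg(conditions, several.ok = TRUE)
  n_per_cond <- n_groups * neurons_per_group
  gen <- function() {
    n_tot <- n_per_cond * length(conditions)
    times <- matrix(0, n_tot, L_max)
    label <- integer(n_tot)
    ids <- character(n_tot)
    k <- 0L
    for (cond in conditions) {
      for (g in seq_len(n_groups)) {
        for (j in seq_len(neurons_per_group)) {
          k <- k + 1L
          s <- generate_sample(params, cond, duration, L_max,
                               sprintf("%s_g%05d_n%03d", cond, g, j))
          times[k, ] <- s$spike_times
          label[k] <- s$label
          ids[k] <- s$sample_id
        }
      }
    }
    list(times = times, label = label, ids = ids)
  }
  out <- with_seed_(params$seed, gen())
  prov <- list(generator = "pheno", params = unclass(params),
               seed = params$seed, n_groups = n_groups,
               neurons_per_group = neurons_per_group)
  new_spike_dataset(out$times, out$label, out$ids,
                    rep("pheno", length(out$label)), duration, L_max, prov)
}

# row subset preserving metadata
dataset_subset <- function(ds, idx, note = NULL) {
  prov <- ds$provenance
  if (!is.null(note)) prov$subset <- note
  new_spike_dataset(ds$times[idx, , drop = FALSE], ds$label[idx],
                    ds$sample_id[idx], ds$source[idx], ds$T_max, ds$L_max,
                    prov)
}

#' Split a dataset into training and validation partitions
#'
#' Sizes are `round(train_frac * N)` and the remainder. With
#' `stratified = TRUE` (default) the per-class proportions are preserved to
#' within one sample. Samples are shuffled with the given seed before the
#' split, so the partition is reproducible.
#'
#' @param ds a `spike_dataset`.
#' @param train_frac training fraction in (0, 1).
#' @param stratified preserve class proportions.
#' @param seed seed for the shuffle; `NULL` uses the ambient RNG.
#' @return `list(train = , val = )` of `spike_dataset`s.
#' @export
split_dataset <- function(ds, train_frac, stratified = TRUE, seed = NULL) {
  stopifnot(inherits(ds, "spike_dataset"),
            train_frac > 0, train_frac < 1)
  n <- nrow(ds$times)
  n_train <- round(train_frac * n)
  pick <- function() {
    if (stratified) {
      cls <- sort(unique(ds$label))
      if (length(cls) < 2)
        stop("empty class under stratified splitting")
      per <- integer(length(cls))
      for (i in seq_along(cls)) per[i] <- round(train_frac * sum(ds$label == cls[i]))
      # reconcile rounding so the total matches round(train_frac * N)
      adj <- n_train - sum(per)
      if (adj != 0) {
        big <- which.max(vapply(cls, function(k) sum(ds$label == k), 1L))
        per[big] <- per[big] + adj
      }
      idx <- integer(0)
      for (i in seq_along(cls)) {
        pool <- which(ds$label == cls[i])
        idx <- c(idx, sample(pool, per[i]))
      }
      idx
    } else {
      sample(seq_len(n), n_train)
    }
  }
  train_idx <- sort(with_seed_(seed, pick()))
  val_idx <- setdiff(seq_len(n), train_idx)
  list(train = dataset_subset(ds, train_idx, "train"),
       val = dataset_subset(ds, val_idx, "val"))
}
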