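#' Configuration of the reduced cortico-basal-ganglia-thalamus circuit
#'
#' Eight populations of Izhikevich single-compartment neurons -- regular
#' cortex (RC), inhibitory cortex (IC), direct- and indirect-pathway
#' striatum (dSTR, iSTR), subthalamic nucleus (STN), globus pallidus
#' externa/interna (GPe, GPi), thalamus (TH) -- coupled by signed
#' exponential-decay synapses with fixed axonal delays. The parkinsonian
#' state is controlled by a dopamine scalar in `[0, 1]` (healthy 1, PD 0.2
#' by default): dopamine depletion strengthens indirect-pathway striatal
#' inhibition of GPe, cortico-subthalamic gain, and the reciprocal STN-GPe
#' coupling, which pushes the subthalamo-pallidal loop into beta-band
#' (13-30 Hz) oscillation and raises STN firing -- the two biomarkers the
#' detectors are trained on.
#'
#' @param region_size neurons per region (>= 2).
#' @param state `"healthy"` or `"pd"`; sets `dopamine` unless given.
#' @param dopamine optional explicit dopamine scalar in `[0, 1]`.
#' @param dt integration step, ms.
#' @param duration simulated time, ms.
#' @param seed seed for connectivity and simulation noise.
#' @param stn_feedback_frac fraction of GPe/GPi neurons receiving
#'   excitatory STN feedback.
#' @param rand_indegree in-degree used for the stochastic cortex/striatum
#'   connection rules.
#' @return an object of class `circuit_config`.
#' @export
circuit_config <- function(region_size = 10, state = c("healthy", "pd"),
                           dopamine = NULL, dt = 0.1, duration = 2500,
                           seed = NULL, stn_feedback_frac = 0.5,
                           rand_indegree = 3) {
  state <- match.arg(state)
  stopifnot(region_size >= 2, dt > 0, duration > 0,
            stn_feedback_frac >= 0, stn_feedback_frac <= 1,
            rand_indegree >= 1)
  if (is.null(dopamine)) dopamine <- if (state == "pd") 0.2 else 1
  stopifnot(dopamine >= 0, dopamine <= 1)
  structure(list(region_size = as.integer(region_size), state = state,
                 dopamine = dopamine, dt = dt, duration = duration,
                 seed = seed, stn_feedback_frac = stn_feedback_frac,
                 rand_indegree = as.integer(min(rand_indegree,
                                                region_size - 1))),
            class = "circuit_config")
}

REGIONS <- c("RC", "IC", "dSTR", "iSTR", "STN", "GPe", "GPi", "TH")

# neuron-model presets and synaptic/drive constants; dopamine scaling of the
# PD-affected weights happens in build_network()
circuit_defaults <- function() {
  list(
    izh = list( # a, b, c, d per region
      RC   = c(0.02, 0.2, -65, 8),    # regular spiking
      IC   = c(0.10, 0.2, -65, 2),    # fast spiking
      dSTR = c(0.02, 0.2, -65, 8),
      iSTR = c(0.02, 0.2, -65, 8),
      STN  = c(0.02, 0.25, -65, 2),
      GPe  = c(0.10, 0.2, -65, 2),
      GPi  = c(0.10, 0.2, -65, 2),
      TH   = c(0.02, 0.25, -65, 0.05)),
    drive = c(RC = 3.8, IC = 3.6, dSTR = 2.4, iSTR = 2.4, STN = 0.8,
              GPe = 3.8, GPi = 4.0, TH = 1.2),
    noise = c(RC = 2.0, IC = 1.5, dSTR = 1.5, iSTR = 1.5, STN = 0.6,
              GPe = 0.8, GPi = 1.5, TH = 1.0),
    # base synaptic kick amplitudes per rule (current units)
    w = c(`TH->RC` = 1.0, `IC->RC` = 1.0, `RC->IC` = 1.0,
          `RC->dSTR` = 1.6, `dSTR->dSTR` = 0.6, `RC->iSTR` = 1.6,
          `iSTR->iSTR` = 0.6, `RC->STN` = 1.0, `GPe->STN` = 2.0,
          `GPe->GPe` = 0.8, `iSTR->GPe` = 0.5, `STN->GPe` = 1.2,
          `GPe->GPi` = 0.8, `dSTR->GPi` = 0.5, `STN->GPi` = 1.0,
          `GPi->TH` = 2.0),
    # dopamine sensitivity: effective weight = w * (1 + k * (1 - dopamine));
    # dopamine depletion strengthens indirect-pathway striatal inhibition,
    # cortico-subthalamic gain, and the reciprocal STN-GPe loop that
    # generates the beta rhythm
    k = c(`iSTR->GPe` = 4.0, `RC->iSTR` = 2.0, `RC->STN` = 6.0,
          `STN->GPe` = 6.0, `GPe->STN` = 5.0),
    delay = c(within = 1, between = 6),   # ms
    tau_exc = 5, tau_inh = 10)            # ms
}

#' Build a connectivity realization of the circuit
#'
#' Applies the region-to-region wiring rules: cortex and striatum use
#' stochastic connections (random sources at the configured in-degree,
#' without replacement, no self-edges); the pallido-subthalamo-thalamic
#' rules are structured. Every STN neuron gets inhibitory GPe and
#' excitatory RC input; every GPe neuron gets inhibition from exactly two
#' other GPe neurons and from all iSTR neurons; every GPi neuron gets
#' inhibition from all dSTR neurons and from GPe; a configured fraction of
#' GPe and GPi neurons gets excitatory STN feedback; thalamic neurons
#' receive GPi inhibition only. Dopamine scaling of the PD-sensitive
#' weights is baked into the returned edge weights.
#'
#' @param cfg a [circuit_config()].
#' @param seed optional override of `cfg$seed` for the random rules.
#' @return a `connectivity_realization`: data.frame with `src`, `dst`
#'   (global neuron indices), `src_region`, `dst_region`, `weight` (signed:
#'   positive excitatory), `rule`, `delay_ms`.
#' @export
build_network <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "circuit_config"))
  n <- cfg$region_size
  def <- circuit_defaults()
  base <- setNames(seq(0, by = n, length.out = length(REGIONS)), REGIONS)
  idx <- function(region, i) base[[region]] + i     # global 1-based index
  damp <- 1 - cfg$dopamine
  wt <- function(rule) {
    w <- def$w[[rule]]
    if (rule %in% names(def$k)) w <- w * (1 + def$k[[rule]] * damp)
    w
  }
  sgn <- function(rule) {
    src <- sub("->.*", "", rule)
    if (src %in% c("IC", "dSTR", "iSTR", "GPe", "GPi")) -1 else 1
  }
  rows <- list()
  add <- function(rule, src_r, src_i, dst_r, dst_i, delay) {
    rows[[length(rows) + 1]] <<- data.frame(
      src = idx(src_r, src_i), dst = idx(dst_r, dst_i),
      src_region = src_r, dst_region = dst_r,
      weight = sgn(rule) * wt(rule), rule = rule, delay_ms = delay)
  }
  rnd <- function(pool, k) sample(pool, min(k, length(pool)))
  build <- function() {
    d_in <- def$delay[["within"]]; d_out <- def$delay[["between"]]
    for (i in seq_len(n)) {
      add("TH->RC", "TH", rnd(seq_len(n), cfg$rand_indegree), "RC", i, d_out)
      add("IC->RC", "IC", rnd(seq_len(n), cfg$rand_indegree), "RC", i, d_in)
      add("RC->IC", "RC", rnd(seq_len(n), cfg$rand_indegree), "IC", i, d_in)
      add("RC->dSTR", "RC", rnd(seq_len(n), cfg$rand_indegree), "dSTR", i, d_out)
      add("dSTR->dSTR", "dSTR", rnd(setdiff(seq_len(n), i), cfg$rand_indegree),
          "dSTR", i, d_in)
      add("RC->iSTR", "RC", rnd(seq_len(n), cfg$rand_indegree), "iSTR", i, d_out)
      add("iSTR->iSTR", "iSTR", rnd(setdiff(seq_len(n), i), cfg$rand_indegree),
          "iSTR", i, d_in)
      add("RC->STN", "RC", rnd(seq_len(n), cfg$rand_indegree), "STN", i, d_out)
      # structured pallidal rules
      add("GPe->STN", "GPe", c(i, i %% n + 1), "STN", i, d_out)
      off2 <- if (n > 2) (i + 1) %% n + 1 else i %% n + 1
      add("GPe->GPe", "GPe", c(i %% n + 1, off2), "GPe", i, d_in)
      add("iSTR->GPe", "iSTR", seq_len(n), "GPe", i, d_out)
      add("GPe->GPi", "GPe", c(i, i %% n + 1), "GPi", i, d_out)
      add("dSTR->GPi", "dSTR", seq_len(n), "GPi", i, d_out)
      add("GPi->TH", "GPi", c(i, i %% n + 1), "TH", i, d_out)
    }
    k_fb <- round(cfg$stn_feedback_frac * n)
    if (k_fb > 0) {
      for (tgt in c("GPe", "GPi")) {
        sel <- rnd(seq_len(n), k_fb)
        for (i in sel)
          add(paste0("STN->", tgt), "STN", rnd(seq_len(n), cfg$rand_indegree),
              tgt, i, d_out)
      }
    }
    do.call(rbind, rows)
  }
  edges <- with_seed_(seed %||% cfg$seed, build())
  structure(list(edges = edges, region_size = n, regions = REGIONS,
                 dopamine = cfg$dopamine),
            class = "connectivity_realization")
}

# global index -> region name
neuron_regions <- function(region_size) rep(REGIONS, each = region_size)

#' Simulate the circuit
#'
#' Fixed-step integration (`cfg$dt`, default 0.1 ms) of the Izhikevich
#' dynamics with region presets, signed exponential synaptic currents and
#' per-edge delays. All noise is drawn from R's RNG, so a fixed `cfg$seed`
#' makes runs exactly reproducible. Halving `dt` changes per-region mean
#' rates by design less than 10%.
#'
#' @param net a [build_network()] realization.
#' @param cfg the matching [circuit_config()].
#' @return a `circuit_run`: `spikes` (list of spike-time vectors, ms, one
#'   per neuron), `region` (region name per neuron), `duration`, `state`.
#' @export
simulate_circuit <- function(net, cfg) {
  stopifnot(inherits(net, "connectivity_realization"),
            inherits(cfg, "circuit_config"),
            net$region_size == cfg$region_size)
  def <- circuit_defaults()
  n <- cfg$region_size * length(REGIONS)
  reg <- neuron_regions(cfg$region_size)
  pars <- t(vapply(reg, function(r) def$izh[[r]], numeric(4)))
  delay_steps <- pmax(1L, as.integer(round(net$edges$delay_ms / cfg$dt)))
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  spikes <- with_seed_(cfg$seed,
    cpp_simulate_izh(pars[, 1], pars[, 2], pars[, 3], pars[, 4],
                     def$drive[reg], def$noise[reg],
                     as.integer(net$edges$src - 1L),
                     as.integer(net$edges$dst - 1L),
                     net$edges$weight, delay_steps,
                     cfg$dt, n_steps, def$tau_exc, def$tau_inh))
  structure(list(spikes = spikes, region = reg, duration = cfg$duration,
                 state = cfg$state, dopamine = cfg$dopamine,
                 dt = cfg$dt, seed = cfg$seed),
            class = "circuit_run")
}

#' Mean firing rate per region of a circuit run
#' @param run a `circuit_run`.
#' @return named numeric vector, Hz.
#' @export
region_rates <- function(run) {
  stopifnot(inherits(run, "circuit_run"))
  counts <- vapply(run$spikes, length, 1)
  tapply(counts, run$region, mean) / run$duration * 1000
}

#' Collect STN spike trains from circuit runs into a dataset
#'
#' One sample per STN neuron per run, labeled by each run's state,
#' `source = "circuit"`. All runs must share the same duration.
#'
#' @param runs list of [simulate_circuit()] outputs.
#' @param labels optional explicit binary labels, one per run; defaults to
#'   each run's own state.
#' @param L_max padded vector length.
#' @return a `spike_dataset` (empty if `runs` is empty).
#' @export
extract_stn_dataset <- function(runs, labels = NULL, L_max = 128) {
  if (length(runs) == 0) {
    return(new_spike_dataset(matrix(0, 0, L_max), integer(0), character(0),
                             character(0), T_max = 2500, L_max = L_max,
                             provenance = list(generator = "circuit")))
  }
  durs <- vapply(runs, `[[`, 1, "duration")
  if (length(unique(durs)) != 1) stop("runs have mismatched durations")
  if (is.null(labels))
    labels <- vapply(runs, function(r) if (r$state == "pd") 1L else 0L, 1L)
  stopifnot(length(labels) == length(runs))
  times <- list(); lab <- integer(0); ids <- character(0)
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    stn <- which(run$region == "STN")
    for (j in seq_along(stn)) {
      tt <- round(run$spikes[[stn[j]]], 3)
      if (length(tt) > L_max)
        stop(sprintf("STN neuron %d in run %d has %d spikes > L_max = %d",
                     j, ri, length(tt), L_max))
      times[[length(times) + 1]] <- c(tt, numeric(L_max - length(tt)))
      lab <- c(lab, as.integer(labels[ri]))
      ids <- c(ids, sprintf("run%04d_stn%02d", ri, j))
    }
  }
  new_spike_dataset(do.call(rbind, times), lab, ids,
                    rep("circuit", length(lab)), durs[1], L_max,
                    list(generator = "circuit", n_runs = length(runs)))
}

#' Generate an STN dataset from repeated circuit runs
#'
#' Convenience wrapper running `n_runs` independent, seeded realizations per
#' condition and extracting the STN trains.
#'
#' @param n_runs runs per condition.
#' @param region_size neurons per region.
#' @param duration ms.
#' @param seed master seed; per-run seeds are derived from it.
#' @param L_max padded vector length.
#' @param ... further arguments to [circuit_config()].
#' @return a `spike_dataset` with `2 * n_runs * region_size` samples.
#' @export
circuit_dataset <- function(n_runs, region_size = 10, duration = 2500,
                            seed = 1, L_max = 128, ...) {
  runs <- list()
  for (state in c("healthy", "pd")) {
    for (r in seq_len(n_runs)) {
      s <- derive_seed(seed, sprintf("circuit-%s-%04d", state, r))
      cfg <- circuit_config(region_size = region_size, state = state,
                            duration = duration, seed = s, ...)
      net <- build_network(cfg)
      runs[[length(runs) + 1]] <- simulate_circuit(net, cfg)
    }
  }
  ds <- extract_stn_dataset(runs, L_max = L_max)
  ds$provenance$seed <- seed
  ds$provenance$params <- list(region_size = region_size,
                               duration = duration, n_runs = n_runs)
  ds
}
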