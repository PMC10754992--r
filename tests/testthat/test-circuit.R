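in_deg <- function(net, src_region, dst_region) {
  e <- net$edges[net$edges$src_region == src_region &
                 net$edges$dst_region == dst_region, ]
  n <- net$region_size
  base <- (match(dst_region, spikesharp:::REGIONS) - 1) * n
  vapply(seq_len(n), function(i) sum(e$dst == base + i), 1)
}

test_that("connectivity degree constraints hold for every seed (property)", {
  for (seed in 1:5) {
    cfg <- circuit_config(seed = seed)
    net <- build_network(cfg)
    expect_true(all(in_deg(net, "GPe", "GPe") == 2))     # any two other GPe
    expect_true(all(in_deg(net, "iSTR", "GPe") == 10))   # all iSTR
    expect_true(all(in_deg(net, "dSTR", "GPi") == 10))   # all dSTR
    expect_true(all(in_deg(net, "GPe", "STN") >= 1))
    expect_true(all(in_deg(net, "RC", "STN") >= 1))
    expect_true(all(in_deg(net, "GPi", "TH") >= 1))
    # thalamus receives GPi inhibition and nothing else
    th <- net$edges[net$edges$dst_region == "TH", ]
    expect_true(all(th$src_region == "GPi"))
    expect_true(all(th$weight < 0))
    # no self-edges anywhere
    expect_true(all(net$edges$src != net$edges$dst))
    # sign conventions: pallidal and striatal sources inhibit, cortex and
    # STN excite
    expect_true(all(net$edges$weight[net$edges$src_region %in%
      c("GPe", "GPi", "dSTR", "iSTR", "IC")] < 0))
    expect_true(all(net$edges$weight[net$edges$src_region %in%
      c("RC", "TH", "STN")] > 0))
  }
})

test_that("builds and simulations are deterministic under a fixed seed", {
  cfg <- circuit_config(state = "pd", seed = 123, duration = 500)
  n1 <- build_network(cfg); n2 <- build_network(cfg)
  expect_identical(n1$edges, n2$edges)
  r1 <- simulate_circuit(n1, cfg); r2 <- simulate_circuit(n2, cfg)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("region_size below 2 is rejected", {
  expect_error(circuit_config(region_size = 1), "region_size")
})

test_that("with silenced synapses STN activity is independent of GPe", {
  cfg <- circuit_config(seed = 9, duration = 800)
  net <- build_network(cfg)
  net$edges$weight <- 0
  r_full <- simulate_circuit(net, cfg)
  cut <- net
  cut$edges <- cut$edges[cut$edges$dst_region != "STN", ]
  r_cut <- simulate_circuit(cut, cfg)
  stn <- which(r_full$region == "STN")
  expect_identical(r_full$spikes[stn], r_cut$spikes[stn])
  # decoupled neurons still fire at their intrinsic baseline
  expect_gt(mean(lengths(r_full$spikes[stn])), 0)
})

test_that("parkinsonian runs fire faster in STN than healthy runs", {
  rates <- sapply(1:3, function(s) {
    vapply(c("healthy", "pd"), function(state) {
      cfg <- circuit_config(state = state, seed = s)
      region_rates(simulate_circuit(build_network(cfg), cfg))[["STN"]]
    }, 1)
  })
  expect_gt(mean(rates["pd", ]), mean(rates["healthy", ]))
})

test_that("halving dt changes per-region mean rates by less than 10%", {
  for (state in c("healthy", "pd")) {
    r1 <- r2 <- NULL
    for (s in 1:3) {
      cfg1 <- circuit_config(state = state, seed = s, dt = 0.1)
      cfg2 <- circuit_config(state = state, seed = s, dt = 0.05)
      net <- build_network(cfg1)
      r1 <- rbind(r1, region_rates(simulate_circuit(net, cfg1)))
      r2 <- rbind(r2, region_rates(simulate_circuit(net, cfg2)))
    }
    m1 <- colMeans(r1); m2 <- colMeans(r2)
    expect_lt(max(abs(m2 - m1) / m1), 0.10)
  }
})

test_that("extract_stn_dataset collects one sample per STN neuron per run", {
  cfg <- circuit_config(state = "pd", seed = 2, duration = 600)
  run <- simulate_circuit(build_network(cfg), cfg)
  ds1 <- extract_stn_dataset(list(run))
  expect_equal(nrow(ds1$times), 10)
  expect_true(all(ds1$source == "circuit"))
  expect_equal(nrow(extract_stn_dataset(list())$times), 0)
  # mixed runs keep class counts equal
  cfg_h <- circuit_config(state = "healthy", seed = 3, duration = 600)
  run_h <- simulate_circuit(build_network(cfg_h), cfg_h)
  ds2 <- extract_stn_dataset(list(run, run_h))
  expect_equal(unname(class_counts(ds2)), c(10L, 10L))
  # duration mismatch is an error
  cfg_short <- circuit_config(state = "pd", seed = 4, duration = 400)
  run_short <- simulate_circuit(build_network(cfg_short), cfg_short)
  expect_error(extract_stn_dataset(list(run, run_short)), "duration")
})
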