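# Neuron semantics (threshold, refractoriness), transduction classes, and
# the pressure-latency curve.

test_that("a stimulus during the absolute refractory period has no effect", {
  nr <- new_neuron()
  r1 <- deliver_stimulus(nr, 1.2, t_ms = 0)
  expect_true(r1$fired)
  # t_relay = 1, ARP = 2: at t = 2 ms the cell is absolutely refractory
  r2 <- deliver_stimulus(nr, 100, t_ms = 2)
  expect_false(r2$fired)
  expect_equal(neuron_phase(nr, 2), "ARP")
})

test_that("a strong stimulus during the RRP fires; a weak one does not", {
  p <- whisk_params()
  nr <- new_neuron(p)
  deliver_stimulus(nr, 1.2, t_ms = 0)
  t_rrp <- 0 + p$neuron$t_relay_ms + p$neuron$arp_ms + 5
  expect_equal(neuron_phase(nr, t_rrp), "RRP")
  weak <- deliver_stimulus(nr, p$neuron$threshold * 1.01, t_ms = t_rrp)
  expect_false(weak$fired)
  nr2 <- new_neuron(p)
  deliver_stimulus(nr2, 1.2, t_ms = 0)
  strong <- deliver_stimulus(nr2, p$neuron$threshold * p$neuron$rrp_factor * 1.05,
                             t_ms = t_rrp)
  expect_true(strong$fired)
})

test_that("sub-threshold stimuli accumulate within the integration window", {
  nr <- new_neuron()
  expect_false(deliver_stimulus(nr, 0.6, t_ms = 0)$fired)
  expect_true(deliver_stimulus(nr, 0.6, t_ms = 2)$fired)  # 1.2 >= 1 in window
  nr2 <- new_neuron()
  deliver_stimulus(nr2, 0.6, t_ms = 0)
  # window lapsed: the earlier contribution is gone
  expect_false(deliver_stimulus(nr2, 0.6, t_ms = 20)$fired)
})

test_that("inhibitory weights deplete the accumulator with a floor at zero", {
  nr <- new_neuron()
  deliver_stimulus(nr, 0.8, t_ms = 0)
  deliver_stimulus(nr, -5, t_ms = 1)
  expect_false(deliver_stimulus(nr, 0.5, t_ms = 2)$fired)  # floored, not negative
  expect_true(deliver_stimulus(nr, 0.6, t_ms = 3)$fired)
})

test_that("minimum inter-spike interval equals relay plus ARP under a dense train", {
  # brute-force: hammer one neuron every 0.25 ms and measure AP spacing
  p <- whisk_params()
  nr <- new_neuron(p)
  aps <- numeric()
  for (t in seq(0, 60, by = 0.25)) {
    r <- deliver_stimulus(nr, 2.5, t_ms = t)  # above both thresholds
    if (r$fired) aps <- c(aps, r$ap_at_ms)
  }
  expect_gt(length(aps), 3)
  expect_gte(min(diff(aps)), p$neuron$t_relay_ms + p$neuron$arp_ms)
})

test_that("pressure latency increases strictly with radial distance", {
  r <- seq(0.1, 1, by = 0.1)
  lat <- pressure_latency(r)
  expect_true(all(diff(lat) > 0))
  expect_gt(pressure_latency(0.6), pressure_latency(0.3))
  expect_error(pressure_latency(0), "0, 1")
  expect_error(pressure_latency(1.2), "0, 1")
})

test_that("transduction maps whisker state to the four afferent classes", {
  p <- whisk_params()
  # pure protraction, no contact: only whisking cells
  sp <- transduce(protraction = c(10, 90), t_end_ms = 100, params = p)
  expect_setequal(unique(sp$subtype), "W")
  # per-protraction spike budget per cell
  expect_lte(max(table(sp$cell)), p$afferent$w_spikes_per_protraction)

  # contact: one C volley at onset, P delayed by the pressure latency,
  # exactly one D volley at offset
  sp <- transduce(protraction = c(10, 90), contact = c(40, 80), r = 0.4,
                  t_end_ms = 150, params = p)
  expect_equal(unique(sp$t_ms[sp$subtype == "C"]),
               40 + p$afferent$sn1_relay_ms)
  first_p <- min(sp$t_ms[sp$subtype == "P"])
  expect_equal(first_p, 40 + pressure_latency(0.4, p))
  expect_equal(sum(sp$subtype == "D"), p$pools$sn1_d)
  expect_equal(unique(sp$t_ms[sp$subtype == "D"]),
               80 + p$afferent$sn1_relay_ms)
  # repeated pressure volleys while contact persists
  expect_gt(sum(sp$subtype == "P"), p$pools$sn1_p)
})

test_that("motoneuron threshold regimes match the wiring configurations", {
  p <- whisk_params()
  # CPG-only: a single CPG burst reaches threshold on its own
  solo <- new_neuron(p, classes = c(cpg = Inf))
  expect_true(deliver_stimulus(solo, p$neuron$w_cpg_solo, 0, "cpg")$fired)
  # coincidence regime: neither source alone can cross, both together can
  co <- new_neuron(p, classes = c(cpg = p$neuron$w_cpg_coinc,
                                  sn2w = p$neuron$cap_sn2w_coinc))
  expect_false(deliver_stimulus(co, p$neuron$w_cpg_coinc, 0, "cpg")$fired)
  for (k in 1:20) {  # saturating cap: sensory drive alone can never cross
    r <- deliver_stimulus(co, p$neuron$w_sn2w_coinc * 10, k * 0.5, "sn2w")
  }
  expect_false(r$fired)
  co2 <- new_neuron(p, classes = c(cpg = p$neuron$w_cpg_coinc,
                                   sn2w = p$neuron$cap_sn2w_coinc))
  deliver_stimulus(co2, p$neuron$w_sn2w_coinc * 10, 0, "sn2w")
  expect_true(deliver_stimulus(co2, p$neuron$w_cpg_coinc, 1, "cpg")$fired)
})

test_that("second-order fan-in draws are half the pool, reproducible by seed", {
  p <- whisk_params()
  net1 <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 11))
  net2 <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 11))
  net3 <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 12))
  for (st in c("W", "C", "P", "D")) {
    fan <- net1$fanin[["C3"]][[st]]
    n_src <- ncol(fan)
    expect_true(all(rowSums(fan) == round(0.5 * n_src)))
  }
  expect_identical(net1$fanin, net2$fanin)
  expect_false(identical(net1$fanin, net3$fanin))
})

test_that("no neuron in a full run fires two APs closer than relay plus ARP", {
  sim <- free_air_sim()
  p <- sim$meta$params
  mn <- sim$spikes[sim$spikes$class == "MN", ]
  isi <- dplyr::summarise(
    dplyr::group_by(mn, .data$pool, .data$cell),
    min_isi = if (dplyr::n() > 1) min(diff(sort(.data$t_ms))) else Inf)
  expect_gte(min(isi$min_isi), p$neuron$t_relay_ms + p$neuron$arp_ms)
})
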