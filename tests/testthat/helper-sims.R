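# Shared, lazily-computed simulations so expensive runs happen once per suite.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

free_air_sim <- function() {
  cached("free_air", run_simulation(
    whisk_configuration("CPG_ONLY", "NONE", seed = 1),
    duration_ms = 2000, record_trace = FALSE))
}

tip_sim <- function(mechanism, duration_ms = 500) {
  cached(mechanism, run_simulation(
    whisk_configuration("CPG_ONLY", mechanism, seed = 1),
    duration_ms = duration_ms,
    obstacle = obstacle("A4", 74.7, 0.4), record_trace = FALSE))
}

first_tips <- function(sim, ...) {
  tips <- detect_tips(sim$trajectories, sim$contacts, ...)
  tips[tips$first_in_cycle & tips$episode > 1, , drop = FALSE]
}

rostral_ce <- function() {
  lay <- pad_layout()
  lay$whisker[lay$rostral_most & lay$group == "CE"]
}
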