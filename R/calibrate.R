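# Calibration of plant, muscle and latency constants against the kinematic
# benchmarks: free-air cycle structure and protraction peaks, and pump delay
# and amplitude at a 40% radial contact. Deterministic coordinate search
# over named parameter knobs; emits a parameter file plus an
# achieved-vs-target report.

#' Kinematic calibration targets
#'
#' The benchmark values the default parameter set is tuned to: whisk-cycle
#' duration 150 ms (protraction 80, retraction 70), protraction peaks
#' 79-81 deg (74.5 for the rostral-most whisker of seven-whisker rows),
#' ~10 deg amplitude, and a 17 ms / 0.6 deg first pump of the touching
#' whisker under retractor-excitation feedback at 40% radial contact.
#'
#' @param include_tip also include the pump targets (needs obstacle runs,
#'   which are slower).
#' @return tibble: `name`, `target`, `tol`, `weight`, `group`.
#' @export
calibration_targets <- function(include_tip = TRUE) {
  free <- tibble::tribble(
    ~name, ~target, ~tol, ~weight, ~group,
    "cycle_ms", 150, 15, 1, "free_air",
    "protraction_ms", 80, 8, 1, "free_air",
    "retraction_ms", 70, 7, 1, "free_air",
    "peak_main", 80, 1, 2, "free_air",
    "peak_rostral_ce", 74.5, 1, 2, "free_air",
    "amplitude", 10, 2, 1, "free_air"
  )
  if (!include_tip) return(free)
  dplyr::bind_rows(free, tibble::tribble(
    ~name, ~target, ~tol, ~weight, ~group,
    "tip_delay_er", 17, 2, 2, "tip_er",
    "tip_amp_er_touching", 0.6, 0.2, 2, "tip_er"
  ))
}

#' Measure the calibration quantities for a parameter set
#'
#' @param overrides parameter overrides applied on top of the defaults.
#' @param seed run seed.
#' @param duration_ms free-air run length (>= 3 cycles recommended).
#' @param groups which target groups to measure (`"free_air"`, `"tip_er"`).
#' @return named numeric vector of achieved values.
#' @export
measure_kinematics <- function(overrides = NULL, seed = 1L,
                               duration_ms = 650,
                               groups = c("free_air", "tip_er")) {
  out <- c()
  if ("free_air" %in% groups) {
    cfg <- whisk_configuration("CPG_ONLY", "NONE", seed = seed,
                               overrides = overrides)
    sim <- run_simulation(cfg, duration_ms = duration_ms, record_trace = FALSE)
    cyc <- tidy.whisk_sim(sim)
    lay <- pad_layout()
    rostral_ce <- lay$whisker[lay$rostral_most & lay$group == "CE"]
    main <- cyc[!cyc$whisker %in% rostral_ce, ]
    rost <- cyc[cyc$whisker %in% rostral_ce, ]
    out <- c(out,
      cycle_ms = mean(main$duration_ms),
      protraction_ms = mean(main$protraction_ms),
      retraction_ms = mean(main$retraction_ms),
      peak_main = mean(main$peak_theta),
      peak_rostral_ce = if (nrow(rost)) mean(rost$peak_theta) else NA_real_,
      amplitude = mean(main$amplitude))
  }
  if ("tip_er" %in% groups) {
    cfg <- whisk_configuration("CPG_ONLY", "E_R", seed = seed,
                               overrides = overrides)
    sim <- run_simulation(cfg, duration_ms = min(duration_ms, 500),
                          obstacle = obstacle("A4", 74.7, 0.4),
                          record_trace = FALSE)
    tips <- detect_tips(sim$trajectories, sim$contacts, whisker = "A4")
    first <- tips[tips$first_in_cycle, ]
    out <- c(out,
      tip_delay_er = if (nrow(first)) mean(first$delay_ms) else NA_real_,
      tip_amp_er_touching = if (nrow(first)) mean(first$amplitude) else NA_real_)
  }
  out
}

#' Calibrate model parameters against kinematic targets
#'
#' Deterministic coordinate search: each knob in turn is swept over its
#' candidate values (all other knobs held at their current best), keeping
#' the value that minimises the weighted sum of squared tolerance-scaled
#' residuals. Re-running with the same arguments reproduces the identical
#' parameter file.
#'
#' @param targets target table from [calibration_targets()].
#' @param knobs named list: dotted parameter name -> numeric candidate
#'   values.
#' @param seed run seed used for every evaluation.
#' @param duration_ms free-air evaluation run length.
#' @param n_sweeps coordinate-descent passes over the knob list.
#' @param base_overrides overrides applied below the searched knobs.
#' @return list: `params` (full parameter list at the optimum), `best`
#'   (named knob values), `report` (achieved vs target tibble), `residual`.
#' @export
calibrate_params <- function(targets = calibration_targets(),
                             knobs,
                             seed = 1L,
                             duration_ms = 650,
                             n_sweeps = 1,
                             base_overrides = NULL) {
  stopifnot(is.list(knobs), length(names(knobs)) == length(knobs))
  groups <- unique(targets$group)
  current <- lapply(knobs, function(v) v[1])
  objective <- function(vals) {
    ov <- merge_params(base_overrides %||% list(), undot_params(vals))
    got <- measure_kinematics(ov, seed = seed, duration_ms = duration_ms,
                              groups = groups)
    res <- (got[targets$name] - targets$target) / targets$tol
    sum(targets$weight * ifelse(is.na(res), 25, res^2))
  }
  best_val <- objective(current)
  for (sweep in seq_len(n_sweeps)) {
    for (nm in names(knobs)) {
      for (v in knobs[[nm]]) {
        cand <- current
        cand[[nm]] <- v
        val <- objective(cand)
        if (val < best_val - 1e-12) {
          best_val <- val
          current <- cand
        }
      }
    }
  }
  ov <- merge_params(base_overrides %||% list(), undot_params(current))
  got <- measure_kinematics(ov, seed = seed, duration_ms = duration_ms,
                            groups = groups)
  report <- targets
  report$achieved <- unname(got[targets$name])
  report$residual <- (report$achieved - report$target) / report$tol
  list(params = whisk_params(ov), best = current, report = report,
       residual = best_val)
}
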