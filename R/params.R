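# Model parameters. The shipped default file (inst/extdata/default-params.json,
# produced by calibrate()) is the single calibrated operating point; all
# simulations start from it and apply overrides on top.

.params_cache <- new.env(parent = emptyenv())

# Built-in fallback used only if the shipped file is absent (bootstrap during
# calibration); the installed package always carries the JSON.
.builtin_params <- function() {
  list(
    time = list(dt_ms = 0.5),
    plant = list(theta_rest = 70, inertia = 8, damping = 8, stiffness = 1,
                 eps_contact_deg = 2, k_contact = 4, b_contact = 5),
    cpg = list(
      cycle_duration_ms = 5,
      ExtP = list(cycles_num = 7, silence_ms = 115, offset_ms = 0),
      Int = list(cycles_num = 12, silence_ms = 90, offset_ms = 25),
      ExtR = list(cycles_num = 13, silence_ms = 85, offset_ms = 83)
    ),
    neuron = list(
      t_relay_ms = 1, arp_ms = 2, rrp_ms = 20, t_integ_ms = 4,
      threshold = 1, rrp_factor = 1.1,
      w_cpg_solo = 1.7, w_cpg_coinc = 0.6,
      rrp_factor_extr = 2.0, rrp_ms_extr = 12,
      w_sn2w_coinc = 0.2, cap_sn2w_coinc = 0.55, w_sn2w_solo = 0.6,
      sn2_volley_frac = 0.4, sn2_arp_ms = 2, sn2_w_min_sources = 2,
      tip_w = 0.12, tip_threshold = 1.5, tip_window_ms = 30,
      tip_burst_n = 1, tip_burst_gap_ms = 2.5,
      veto_direct_ms = 18, veto_indirect_ms = 20, veto_fraction = 1, inhib_extra_delay_ms = 0
    ),
    afferent = list(
      pressure_latency_at_r0_ms = 15.7, pressure_latency_slope_ms = 16,
      pressure_latency_r0 = 0.4, pressure_interval_ms = 13.5,
      sn1_relay_ms = 0.5, sn2_relay_ms = 1,
      w_spikes_per_protraction = 4, w_interval_ms = 18,
      w_spont_hz = 6, omega_min_deg_ms = 0.02
    ),
    pools = list(sn1_w = 73, sn1_c = 33, sn1_p = 28, sn1_d = 28,
                 sn2_per_subtype = 10, mn_per_type = 10, sn2_fanin_frac = 0.5),
    muscle = list(
      share_rostral = 9 / 11,
      intrinsic = list(ca_gain = 1.0, tau_ms = 12, ca0 = 1.25, ca_sat = 0.5,
                       a_max = 5.95),
      pseudo_intrinsic = list(ca_gain = 1.0, tau_ms = 12, ca0 = 1.25,
                              ca_sat = 0.5, a_max = 5.95),
      extP = list(ca_gain = 1.0, tau_ms = 12, ca0 = 0.5, ca_sat = 1.0,
                  a_max = 4.85),
      extR_sup = list(ca_gain = 2.4, tau_ms = 4, ca0 = 0.12, ca_sat = 6,
                      a_max = 18, ca_max = 2.6),
      extR_deep = list(ca_gain = 0.9, tau_ms = 22, ca0 = 0.3, ca_sat = 1.0,
                       a_max = 1.15, ca_max = 4)
    )
  )
}

#' Default model parameters
#'
#' Returns the calibrated default parameter set, optionally with overrides
#' merged in. Overrides use the same nesting as the defaults, e.g.
#' `list(muscle = list(extR_sup = list(a_max = 1.5)))`, or flat dotted names,
#' e.g. `list("muscle.extR_sup.a_max" = 1.5)`.
#'
#' @param overrides named list of parameter overrides (nested or dotted).
#' @return nested named list of parameters.
#' @export
whisk_params <- function(overrides = NULL) {
  if (is.null(.params_cache$base)) {
    path <- system.file("extdata", "default-params.json", package = "whiskloop")
    .params_cache$base <- if (nzchar(path)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
    } else {
      .builtin_params()
    }
  }
  p <- .params_cache$base
  if (!is.null(overrides) && length(overrides)) {
    p <- merge_params(p, undot_params(overrides))
  }
  p
}

undot_params <- function(x) {
  out <- list()
  for (nm in names(x)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    node <- x[[nm]]
    for (p in rev(parts)) node <- stats::setNames(list(node), p)
    out <- merge_params(out, node)
  }
  out
}

merge_params <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Write a parameter set to a JSON file
#'
#' @param params nested parameter list (from [whisk_params()] or
#'   [calibrate_params()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Validate a parameter list; used by run config validation.
validate_params <- function(p) {
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(p$time$dt_ms > 0, "time.dt_ms must be > 0")
  for (ct in c("ExtP", "Int", "ExtR")) {
    need(p$cpg[[ct]]$cycles_num >= 1, paste0("cpg.", ct, ".cycles_num >= 1"))
    need(p$cpg[[ct]]$silence_ms > 0, paste0("cpg.", ct, ".silence_ms > 0"))
  }
  need(p$cpg$cycle_duration_ms > 0, "cpg.cycle_duration_ms > 0")
  need(p$neuron$rrp_factor >= 1, "neuron.rrp_factor >= 1 (RRP threshold is higher)")
  with(p$neuron, {
    need(t_relay_ms > 0 && arp_ms > 0 && rrp_ms > 0,
         "neuron relay/ARP/RRP must be > 0")
  })
  need(p$plant$eps_contact_deg > 0, "plant.eps_contact_deg > 0")
  need(p$muscle$share_rostral > 0 && p$muscle$share_rostral <= 1,
       "muscle.share_rostral in (0, 1]")
  errs
}
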