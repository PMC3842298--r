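# Neural elements: the two-state CPG chart, event-driven threshold neurons
# with relay / absolute / relative refractory dynamics (Rest -> GenerateAP ->
# ARP -> RRP -> Rest), and the transduction of whisker state into the four
# first-order afferent classes (whisking, contact, pressure, detach).
#
# Neurons are implemented as pools (struct-of-arrays over identical cells
# sharing a whisker and subtype) for speed; the per-cell semantics are those
# of the neuron chart and are also exposed through a single-neuron API.

# ---------------------------------------------------------------------------
# CPG chart

#' CPG statechart definition
#'
#' Two states. In `Activate` the CPG emits one stimulation broadcast to every
#' motoneuron of its type each `cycleDuration` ms, `cyclesNum` times (a
#' condition connector on `currentCycle`), then relaxes for
#' `silenceDuration` ms and starts over. An inhibitory touch-feedback volley
#' (indirect I-P wiring) suppresses its broadcasts for a veto window without
#' perturbing its state cycle.
#'
#' @return a [chart_def()] for a CPG instance. Instance params:
#'   `cpg_type`, `cycle_ms`, `cycles_num`, `silence_ms`, `current_cycle`,
#'   `relax_ms` (the pending Relax timeout: the lead-in phase offset on the
#'   first cycle, `silence_ms` afterwards), `targets` (MN pool component
#'   ids), `w` (stimulation weight), plus the touch-gate fields.
#' @export
cpg_chart_def <- function() {
  broadcast <- function(sch, inst, ev) {
    pr <- inst$params
    if (sch$clock < pr$suppressed_until_us) return(invisible(NULL))
    if (!is.null(pr$broadcast_fn)) {
      # network path: deliver to every MN pool of this type in one burst
      pr$broadcast_fn(sch, inst)
    } else {
      for (tgt in pr$targets) {
        post_event(sch, tgt, "stimulate", delay_ms = 0,
                   payload = list(class = "cpg", w = pr$w, n = 1L),
                   source = inst$id)
      }
    }
  }
  chart_def(
    name = "CPG",
    states = c("Activate", "Relax"),
    initial = "Relax",
    transitions = list(
      transition("Activate", tm_trigger("Activate"), "Activate",
                 guard = function(inst, ev) {
                   inst$params$current_cycle < inst$params$cycles_num
                 },
                 actions = function(sch, inst, ev) {
                   broadcast(sch, inst, ev)
                   inst$params$current_cycle <- inst$params$current_cycle + 1L
                 }),
      transition("Activate", tm_trigger("Activate"), "Relax",
                 actions = function(sch, inst, ev) {
                   # the connector evaluation that sends the chart to Relax
                   # consumes one cycleDuration, counted against the silent
                   # period so that the full period is exactly
                   # cyclesNum * cycleDuration + silenceDuration
                   inst$params$relax_ms <-
                     max(inst$params$silence_ms - inst$params$cycle_ms, 0)
                 }),
      transition("Relax", tm_trigger("Relax"), "Activate",
                 actions = function(sch, inst, ev) {
                   inst$params$current_cycle <- 0L
                 }),
      transition("Activate", "tip_input",
                 actions = function(sch, inst, ev) cpg_tip_input(sch, inst, ev)),
      transition("Relax", "tip_input",
                 actions = function(sch, inst, ev) cpg_tip_input(sch, inst, ev))
    ),
    timeouts = list(
      Activate = function(inst) inst$params$cycle_ms,
      Relax = function(inst) inst$params$relax_ms
    )
  )
}

# Touch-gate shared by CPGs and motoneuron pools: pooled contact/pressure
# volleys integrate in a slow window with reset-by-subtraction, so a lone
# contact-onset volley is sub-threshold and the pump is triggered by the
# (radial-distance-delayed) pressure volley.
gate_update <- function(pr, t_us, n_spikes) {
  if ((t_us - pr$gate_last_us) / 1000 > pr$tip_window_ms) pr$gate_accum <- 0
  pr$gate_accum <- pr$gate_accum + n_spikes * pr$tip_w
  pr$gate_last_us <- t_us
  if (pr$gate_accum >= pr$tip_threshold) {
    pr$gate_accum <- pr$gate_accum - pr$tip_threshold
    TRUE
  } else FALSE
}

cpg_tip_input <- function(sch, inst, ev) {
  pr <- inst$params
  if (sch$clock < pr$suppressed_until_us) {
    return(invisible(NULL))  # already suppressed: volleys are shunted
  }
  if (gate_update(pr, sch$clock, ev$payload$n)) {
    pr$gate_accum <- 0
    pr$suppressed_until_us <- sch$clock + pr$veto_ms * 1000
  }
  invisible(NULL)
}

make_cpg <- function(sch, type, p, targets, w, offset_ms, broadcast_fn = NULL) {
  cp <- p$cpg[[type]]
  chart_instance(sch, cpg_chart_def(), paste0("cpg_", type), params = list(
    cpg_type = type,
    cycle_ms = p$cpg$cycle_duration_ms,
    cycles_num = cp$cycles_num,
    silence_ms = cp$silence_ms,
    current_cycle = 0L,
    relax_ms = offset_ms,
    targets = targets,
    w = w,
    broadcast_fn = broadcast_fn,
    suppressed_until_us = -Inf,
    gate_accum = 0, gate_last_us = -Inf,
    tip_w = p$neuron$tip_w, tip_threshold = p$neuron$tip_threshold,
    tip_window_ms = p$neuron$tip_window_ms,
    veto_ms = p$neuron$veto_indirect_ms
  ))
}

# ---------------------------------------------------------------------------
# Neuron pools

#' Create a pool of threshold neurons
#'
#' All cells share parameters; state is vectorised. `classes` names the
#' pre-synaptic source classes the pool integrates, each with a per-spike
#' weight cap (`Inf` for uncapped). Contributions accumulate inside a
#' sliding window of `t_integ_ms` and are cleared when it lapses; firing
#' requires the (capped) total to reach `threshold`, or
#' `rrp_factor * threshold` during the relative refractory period. A fired
#' cell relays its action potential after `t_relay_ms`, is absolutely
#' refractory for `arp_ms`, then relatively refractory for `rrp_ms`.
#'
#' @param id pool id.
#' @param n number of cells.
#' @param p model parameters ([whisk_params()]); neuron section is used.
#' @param classes named numeric vector of per-class contribution caps.
#' @param threshold firing threshold (stimulus units).
#' @param t_relay_ms,arp_ms,rrp_ms optional per-pool overrides.
#' @return a `neuron_pool` environment.
#' @export
new_neuron_pool <- function(id, n, p, classes = c(exc = Inf), threshold = NULL,
                            t_relay_ms = NULL, arp_ms = NULL, rrp_ms = NULL) {
  np <- p$neuron
  pool <- new.env(parent = emptyenv())
  pool$id <- id
  pool$n <- as.integer(n)
  pool$threshold <- threshold %||% np$threshold
  pool$rrp_factor <- np$rrp_factor
  pool$t_relay_us <- (t_relay_ms %||% np$t_relay_ms) * 1000
  pool$arp_us <- (arp_ms %||% np$arp_ms) * 1000
  pool$rrp_us <- (rrp_ms %||% np$rrp_ms) * 1000
  pool$t_integ_us <- np$t_integ_ms * 1000
  pool$caps <- classes
  pool$accum <- matrix(0, nrow = n, ncol = length(classes),
                       dimnames = list(NULL, names(classes)))
  pool$last_stim <- rep(-Inf, n)   # µs of last accumulated input
  pool$t_fired <- rep(-Inf, n)     # µs the last AP was emitted
  pool$ap_due <- rep(Inf, n)       # pending AP emission time (GenerateAP)
  pool$veto_until <- rep(-Inf, n)
  pool$gate_accum <- 0; pool$gate_last_us <- -Inf
  pool$tip_w <- np$tip_w; pool$tip_threshold <- np$tip_threshold
  pool$tip_window_ms <- np$tip_window_ms
  pool$targets <- list()
  class(pool) <- "neuron_pool"
  pool
}

#' Phase of each neuron in a pool at a given time
#'
#' @param pool a neuron pool.
#' @param t_ms query time in ms.
#' @return character vector: `"Rest"`, `"GenerateAP"`, `"ARP"` or `"RRP"`.
#' @export
neuron_phase <- function(pool, t_ms) {
  t <- t_ms * 1000
  # an AP scheduled before t counts as emitted even if not yet collected
  t_f <- ifelse(is.finite(pool$ap_due) & pool$ap_due <= t,
                pool$ap_due, pool$t_fired)
  out <- rep("Rest", pool$n)
  out[t >= t_f & t < t_f + pool$arp_us] <- "ARP"
  out[t >= t_f + pool$arp_us & t < t_f + pool$arp_us + pool$rrp_us] <- "RRP"
  out[is.finite(pool$ap_due) & t < pool$ap_due] <- "GenerateAP"
  out
}

# Core delivery; `add` is a length-n vector of signed stimulus increments for
# class `cls`. Returns integer indices of cells that decided to fire (their
# APs are emitted t_relay later by the caller).
pool_deliver <- function(pool, t_us, add, cls) {
  n <- pool$n
  busy <- (is.finite(pool$ap_due) & t_us < pool$ap_due) |
    (t_us >= pool$t_fired & t_us < pool$t_fired + pool$arp_us) |
    (t_us < pool$veto_until)
  open <- !busy
  if (!any(open)) return(integer(0))
  lapsed <- open & (t_us - pool$last_stim > pool$t_integ_us)
  if (any(lapsed)) pool$accum[lapsed, ] <- 0
  cap <- pool$caps[[cls]]
  acc <- pool$accum[, cls]
  acc[open] <- pmin(pmax(acc[open] + add[open], 0), cap)
  pool$accum[, cls] <- acc
  pool$last_stim[open] <- t_us
  tot <- rowSums(pool$accum)
  in_rrp <- t_us >= pool$t_fired + pool$arp_us &
    t_us < pool$t_fired + pool$arp_us + pool$rrp_us
  thr <- ifelse(in_rrp, pool$threshold * pool$rrp_factor, pool$threshold)
  fired <- which(open & tot >= thr)
  if (length(fired)) {
    pool$ap_due[fired] <- t_us + pool$t_relay_us
    pool$accum[fired, ] <- 0
    pool$last_stim[fired] <- -Inf
  }
  fired
}

pool_emit <- function(pool, t_us, cells) {
  pool$t_fired[cells] <- t_us
  pool$ap_due[cells] <- Inf
  invisible(NULL)
}

pool_veto <- function(pool, t_us, veto_ms, fraction = 1) {
  k <- max(1L, round(fraction * pool$n))
  pool$veto_until[seq_len(k)] <- t_us + veto_ms * 1000
  pool$accum[seq_len(k), ] <- 0
  invisible(NULL)
}

# Forced firing of every eligible cell (E-R touch volley): strong compound
# excitation that respects the absolute refractory period but overrides the
# graded threshold (it lands within the RRP regime by construction).
pool_force_fire <- function(pool, t_us) {
  busy <- (is.finite(pool$ap_due) & t_us < pool$ap_due) |
    (t_us >= pool$t_fired & t_us < pool$t_fired + pool$arp_us) |
    (t_us < pool$veto_until)
  fired <- which(!busy)
  if (length(fired)) {
    pool$ap_due[fired] <- t_us + pool$t_relay_us
    pool$accum[fired, ] <- 0
  }
  fired
}

# ---------------------------------------------------------------------------
# Single-neuron API (the pool machinery at n = 1)

#' Create a single threshold neuron
#'
#' Convenience wrapper around [new_neuron_pool()] with one cell, for direct
#' stimulation experiments and tests.
#'
#' @inheritParams new_neuron_pool
#' @return a `neuron_pool` with `n = 1`.
#' @export
new_neuron <- function(p = whisk_params(), classes = c(exc = Inf),
                       threshold = NULL, t_relay_ms = NULL, arp_ms = NULL,
                       rrp_ms = NULL) {
  new_neuron_pool("neuron", 1L, p, classes = classes, threshold = threshold,
                  t_relay_ms = t_relay_ms, arp_ms = arp_ms, rrp_ms = rrp_ms)
}

#' Deliver a stimulus to a neuron
#'
#' Applies one weighted (signed) stimulus at time `t_ms` and reports the
#' firing decision. In `Rest` the weight joins the windowed accumulator and
#' the cell fires when the sum reaches threshold; during the absolute
#' refractory period the stimulus has no effect; during the relative
#' refractory period the threshold is higher by `rrp_factor`. Inhibitory
#' (negative) weights deplete the accumulator, floored at zero.
#'
#' @param neuron a neuron from [new_neuron()] (or a pool; the stimulus then
#'   reaches every cell).
#' @param weight signed stimulus weight.
#' @param t_ms delivery time in ms (non-decreasing across calls).
#' @param class source class name (must be one of the neuron's classes).
#' @return list with `fired` (logical: any cell fired), `cells` (indices),
#'   and `ap_at_ms` (AP emission time, `t + t_relay`, or `NA`).
#' @export
deliver_stimulus <- function(neuron, weight, t_ms, class = NULL) {
  cls <- class %||% names(neuron$caps)[1]
  if (!cls %in% names(neuron$caps)) {
    stop("unknown stimulus class: ", cls, call. = FALSE)
  }
  t_us <- t_ms * 1000
  # emit any APs that came due before this stimulus
  due <- which(is.finite(neuron$ap_due) & neuron$ap_due <= t_us)
  if (length(due)) pool_emit(neuron, max(neuron$ap_due[due]), due)
  fired <- pool_deliver(neuron, t_us, rep(weight, neuron$n), cls)
  list(fired = length(fired) > 0L, cells = fired,
       ap_at_ms = if (length(fired)) t_ms + neuron$t_relay_us / 1000 else NA_real_)
}

# ---------------------------------------------------------------------------
# Sensory transduction

#' Pressure-cell response latency
#'
#' First-spike latency of the pressure afferents after contact onset,
#' strictly increasing in the radial distance of contact (fraction of
#' whisker length from the base). Affine in `r`; the intercept and slope are
#' calibrated together with the downstream conduction delays so that
#' end-to-end pump delays span 12-30 ms over r in [0.2, 0.7] and equal
#' ~17 ms at r = 0.4.
#'
#' @param r radial contact fraction, in (0, 1].
#' @param params model parameters.
#' @return latency in ms.
#' @export
pressure_latency <- function(r, params = whisk_params()) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) {
    stop("radial fraction r must lie in (0, 1]", call. = FALSE)
  }
  a <- params$afferent
  a$pressure_latency_at_r0_ms +
    a$pressure_latency_slope_ms * (r - a$pressure_latency_r0)
}

#' Transduce a whisker-state episode into first-order afferent spikes
#'
#' Functional form of the model's sensory encoding, on one whisker over one
#' observation window: whisking (W) cells fire periodically (with fixed
#' per-cell jitter and a per-protraction spike budget) while the whisker
#' protracts; contact (C) cells fire once at contact onset; pressure (P)
#' cells fire repetitively while contact persists, the first volley delayed
#' by [pressure_latency()]; detach (D) cells fire once at contact offset.
#'
#' @param protraction optional `c(start, end)` ms of a protraction phase.
#' @param contact optional `c(onset, offset)` ms of a contact episode
#'   (offset may be `NA` for ongoing contact at window end).
#' @param r radial contact fraction (required with `contact`).
#' @param t_end_ms observation window end.
#' @param params model parameters.
#' @param w_offsets per-W-cell jitter offsets in ms (defaults to evenly
#'   spread offsets).
#' @return tibble of spikes: `t_ms`, `subtype` (`W`/`C`/`P`/`D`), `cell`.
#' @export
transduce <- function(protraction = NULL, contact = NULL, r = NULL,
                      t_end_ms = Inf, params = whisk_params(),
                      w_offsets = NULL) {
  p <- params
  a <- p$afferent
  spikes <- list()
  if (!is.null(protraction)) {
    n_w <- p$pools$sn1_w
    offs <- w_offsets %||% (seq_len(n_w) - 1) / n_w * a$w_interval_ms
    ks <- seq_len(a$w_spikes_per_protraction) - 1
    tt <- outer(protraction[1] + offs, ks * a$w_interval_ms, `+`)
    keep <- tt <= min(protraction[2], t_end_ms)
    spikes[[length(spikes) + 1L]] <- tibble::tibble(
      t_ms = tt[keep], subtype = "W", cell = as.integer(row(tt)[keep]))
  }
  if (!is.null(contact)) {
    if (is.null(r)) stop("contact transduction requires r", call. = FALSE)
    onset <- contact[1]; offset <- contact[2]
    t_c <- onset + a$sn1_relay_ms
    if (t_c <= t_end_ms) {
      spikes[[length(spikes) + 1L]] <- tibble::tibble(
        t_ms = t_c, subtype = "C", cell = seq_len(p$pools$sn1_c))
    }
    t_p <- onset + pressure_latency(r, p)
    stop_t <- min(offset, t_end_ms, na.rm = TRUE)
    if (!is.finite(stop_t)) {
      stop("transduce(): ongoing contact needs a finite t_end_ms", call. = FALSE)
    }
    while (t_p <= stop_t) {
      spikes[[length(spikes) + 1L]] <- tibble::tibble(
        t_ms = t_p, subtype = "P", cell = seq_len(p$pools$sn1_p))
      t_p <- t_p + a$pressure_interval_ms
    }
    if (!is.na(offset) && offset + a$sn1_relay_ms <= t_end_ms) {
      spikes[[length(spikes) + 1L]] <- tibble::tibble(
        t_ms = offset + a$sn1_relay_ms, subtype = "D",
        cell = seq_len(p$pools$sn1_d))
    }
  }
  out <- dplyr::bind_rows(spikes)
  if (nrow(out)) out <- dplyr::arrange(out, .data$t_ms, .data$subtype, .data$cell)
  out
}
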