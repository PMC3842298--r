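# Orchestration: assemble a wired network into scheduler components, run the
# discrete-event simulation interleaved with the fixed-step plant, and
# collect trajectories, spike logs, transition traces and contact episodes
# into a tidy result object.

#' Run one whisking simulation
#'
#' Builds the pad network for `configuration`, wires CPGs, motoneuron and
#' afferent pools, muscles and whiskers into a deterministic discrete-event
#' scheduler, and simulates `duration_ms` of behaviour. With an [obstacle()]
#' present, whisker-object contacts are transduced into contact / pressure /
#' detach afferent volleys that feed back onto the circuit selected by the
#' configuration's TIP mechanism.
#'
#' @param configuration a [whisk_configuration()].
#' @param duration_ms simulated duration in ms.
#' @param obstacle an [obstacle()] or `NULL` for free-air whisking. The
#'   obstacle is static and present from t = 0.
#' @param record_trace log chart transitions (CPGs, muscles, whiskers,
#'   obstacle) into the transition trace.
#' @return a `whisk_sim` object: tibbles `trajectories`
#'   (`t_ms, whisker, row, arc, theta, omega, contact`), `spikes`
#'   (`t_ms, pool, class, subtype, whisker, cell`), `transitions`,
#'   `contacts` (episodes), and `meta`.
#' @export
run_simulation <- function(configuration, duration_ms = 2000,
                           obstacle = NULL, record_trace = TRUE) {
  stopifnot(inherits(configuration, "whisk_configuration"))
  if (!is.null(obstacle) && !inherits(obstacle, "whisk_obstacle")) {
    stop("obstacle must be created with obstacle()", call. = FALSE)
  }
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 || duration_ms < 0) {
    stop("duration_ms must be a single non-negative number", call. = FALSE)
  }
  net <- build_network(configuration)
  sim <- sim_assemble(net, duration_ms, obstacle, record_trace)
  if (duration_ms > 0) run_until(sim$sch, duration_ms)
  sim_collect(sim)
}

# ---------------------------------------------------------------------------

sim_assemble <- function(net, duration_ms, obs, record_trace) {
  p <- net$params
  layout <- net$layout
  nw <- nrow(layout)
  sch <- new_scheduler(trace = record_trace)
  sim <- new.env(parent = emptyenv())
  sim$net <- net; sim$p <- p; sim$sch <- sch
  sim$duration_ms <- duration_ms

  # --- spike log -----------------------------------------------------------
  lg <- new.env(parent = emptyenv())
  lg$ptr <- spikelog_new_cpp()
  lg$names <- character(0)
  sim$log <- lg

  # --- plant state ---------------------------------------------------------
  pl <- new.env(parent = emptyenv())
  pl$theta <- rep(p$plant$theta_rest, nw)
  pl$omega <- numeric(nw)
  pl$theta_rest <- p$plant$theta_rest
  pl$inertia <- p$plant$inertia; pl$damping <- p$plant$damping
  pl$stiffness <- p$plant$stiffness
  pl$dt_ms <- p$time$dt_ms
  pl$attach <- net$attach
  pl$eps <- p$plant$eps_contact_deg
  pl$k_contact <- p$plant$k_contact %||% 2
  pl$b_contact <- p$plant$b_contact %||% 8
  pl$obs_idx <- if (!is.null(obs)) match(obs$whisker, layout$whisker) else NA
  if (!is.null(obs) && is.na(pl$obs_idx)) {
    stop("obstacle whisker not in pad layout: ", obs$whisker, call. = FALSE)
  }
  pl$obs <- obs
  pl$in_contact <- FALSE
  pl$contact_ep <- 0L
  pl$protracting_prev <- rep(FALSE, nw)
  pl$episode_last <- rep(-Inf, nw)
  pl$episode_theta0 <- rep(NA_real_, nw)
  pl$moving_prev <- rep(FALSE, nw)
  n_steps <- as.integer(round(duration_ms / pl$dt_ms))
  pl$n_steps <- n_steps
  pl$step_i <- 0L
  pl$rec <- traj_new_cpp(nw)
  sim$pl <- pl

  # --- muscle store + muscle/whisker/obstacle charts -----------------------
  ms <- new_muscle_store(net)
  sim$ms <- ms
  mdef <- muscle_chart_def()
  wdef <- whisker_chart_def()
  sim$whisker_charts <- stats::setNames(paste0("wh_", layout$whisker),
                                        layout$whisker)
  for (i in seq_len(nw)) chart_instance(sch, wdef, sim$whisker_charts[[i]])
  for (j in seq_along(ms$ids)) {
    wids <- rownames(net$attach)[net$attach[, j] != 0]
    chart_instance(sch, mdef, paste0("m_", ms$ids[j]), params = list(
      j = j, store = ms,
      whisker_charts = unname(sim$whisker_charts[wids])))
  }
  chart_instance(sch, obstacle_chart_def(), "obstacle")

  # --- neuron pools --------------------------------------------------------
  wm <- net$config$whisking_mechanism
  tipm <- net$config$tip_mechanism
  mn_classes <- switch(wm,
    CPG_ONLY = c(cpg = Inf),
    SENSORY_ONLY = c(sn2w = Inf),
    CPG_PLUS_SENSORY = c(cpg = p$neuron$w_cpg_coinc,
                         sn2w = p$neuron$cap_sn2w_coinc))
  sim$pools <- new.env(parent = emptyenv())
  # innervation counts per muscle (for pool-size normalisation)
  n_pools_of <- vapply(net$innervation, function(x) length(x$whiskers),
                       numeric(1))
  # pool-size-normalised calcium gain: the slow (ramp-like) muscles scale
  # their per-volley response by the number of innervating pools; the
  # superficial retractor responds per compound volley (twitch-like)
  pool_norm <- vapply(net$muscles$type, function(ty) {
    ty %in% c("intrinsic", "pseudo_intrinsic", "extP", "extR_deep")
  }, logical(1))

  sim$mn_pools_by_type <- stats::setNames(
    lapply(MN_TYPES, function(ty) vector("list", nw)), MN_TYPES)
  for (wi in seq_len(nw)) {
    w <- layout$whisker[wi]
    for (ty in MN_TYPES) {
      id <- paste0("mn_", ty, "_", w)
      # retractor motoneurons fire phasically: a higher relative-refractory
      # threshold and shorter RRP make them respond to strong synchronous
      # volleys rather than follow every CPG burst
      pool <- new_neuron_pool(id, net$n_mn, p, classes = mn_classes,
                              rrp_ms = if (ty == "ExtR") p$neuron$rrp_ms_extr
                                       else NULL)
      if (ty == "ExtR") pool$rrp_factor <- p$neuron$rrp_factor_extr
      pool$meta <- list(class = "MN", subtype = ty, whisker = w)
      pool$code <- sim_pool_code(sim, id)
      pool$veto_ms <- p$neuron$veto_direct_ms
      # muscle targets of this pool: store-index + per-volley gain
      mids <- names(net$innervation)[vapply(net$innervation, function(x) {
        x$mn_type == ty && w %in% x$whiskers
      }, logical(1))]
      tj <- match(mids, ms$ids)
      pool$target_j <- tj
      pool$target_gain <- vapply(seq_along(mids), function(k) {
        j <- tj[k]
        ms$ca_gain[j] / if (pool_norm[j]) n_pools_of[[mids[k]]] else 1
      }, numeric(1))
      sim$mn_pools_by_type[[ty]][[wi]] <- pool
      assign(id, pool, envir = sim$pools)
      register_component(sch, id, pool_component_handler,
                         state = list(sim = sim, pool = pool))
    }
    for (st in SN_SUBTYPES) {
      id <- paste0("sn2_", st, "_", w)
      fan <- net$fanin[[w]][[st]]
      thr <- if (st == "W") p$neuron$sn2_w_min_sources %||% 2 else
        ceiling(p$neuron$sn2_volley_frac * sum(fan[1, ]))
      # the first-to-second-order synaptic delay is folded into the relay
      pool <- new_neuron_pool(id, net$n_sn2, p, classes = c(sn1 = Inf),
                              threshold = thr,
                              t_relay_ms = p$afferent$sn2_relay_ms + 0.5,
                              arp_ms = p$neuron$sn2_arp_ms,
                              rrp_ms = p$neuron$sn2_arp_ms)
      pool$meta <- list(class = "SN2", subtype = st, whisker = w)
      pool$code <- sim_pool_code(sim, id)
      pool$fanin <- fan
      assign(id, pool, envir = sim$pools)
      register_component(sch, id, pool_component_handler,
                         state = list(sim = sim, pool = pool))
    }
  }
  # bus components batch per-volley traffic into single grouped events
  register_component(sch, "mn_bus", mn_bus_handler, state = list(sim = sim))
  register_component(sch, "sn2_bus", sn2_bus_handler, state = list(sim = sim))
  register_component(sch, "muscle_bus", muscle_bus_handler,
                     state = list(sim = sim))
  sim$muscle_comps <- lapply(ms$ids, function(id) {
    get_component(sch, paste0("m_", id))
  })

  # --- TIP feedback routing ------------------------------------------------
  sim$tip_route <- if (tipm == "NONE") NULL else {
    stats::setNames(lapply(layout$whisker, function(w) {
      switch(tipm,
        E_R = list(target = paste0("mn_ExtR_", w), sign = "+",
                   delay = p$afferent$sn2_syn_delay_ms %||% 0.5),
        DIRECT_I_P = list(target = paste0("mn_Int_", w), sign = "-",
                          delay = 0.5 + p$neuron$inhib_extra_delay_ms),
        INDIRECT_I_P = list(target = "cpg_Int", sign = "-",
                            delay = 0.5 + p$neuron$inhib_extra_delay_ms))
    }), layout$whisker)
  }
  sim$sn2w_targets <- if (wm == "CPG_ONLY") NULL else {
    stats::setNames(lapply(layout$whisker, function(w) {
      paste0("mn_", MN_TYPES, "_", w)
    }), layout$whisker)
  }
  sim$w_sn2w <- if (wm == "SENSORY_ONLY") p$neuron$w_sn2w_solo else
    p$neuron$w_sn2w_coinc

  # --- CPGs ----------------------------------------------------------------
  cpg_targets <- if (wm == "SENSORY_ONLY") {
    stats::setNames(rep(list(character(0)), 3), MN_TYPES)
  } else {
    stats::setNames(lapply(MN_TYPES, function(ty) {
      paste0("mn_", ty, "_", layout$whisker)
    }), MN_TYPES)
  }
  w_cpg <- if (wm == "CPG_ONLY") p$neuron$w_cpg_solo else p$neuron$w_cpg_coinc
  for (ty in MN_TYPES) {
    broadcast_fn <- if (wm == "SENSORY_ONLY") NULL else
      local({
        ty0 <- ty
        function(sch, inst) {
          pools <- sim$mn_pools_by_type[[ty0]]
          t <- sch$clock
          w <- inst$params$w
          items <- list()
          for (pool in pools) {
            add <- rep(w, pool$n)
            fired <- pool_deliver(pool, t, add, "cpg")
            if (length(fired)) {
              items[[length(items) + 1L]] <- list(pool = pool, cells = fired)
            }
          }
          if (length(items)) {
            post_event(sch, "mn_bus", "ap_bus",
                       delay_ms = pools[[1]]$t_relay_us / 1000,
                       payload = list(items = items), source = inst$id)
          }
        }
      })
    make_cpg(sch, ty, p, cpg_targets[[ty]], w_cpg, p$cpg[[ty]]$offset_ms,
             broadcast_fn = broadcast_fn)
  }

  # --- afferent driver -----------------------------------------------------
  sim$sn1_codes <- stats::setNames(lapply(layout$whisker, function(w) {
    stats::setNames(vapply(SN_SUBTYPES, function(st) {
      sim_pool_code(sim, paste0("sn1_", st, "_", w))
    }, integer(1)), SN_SUBTYPES)
  }), layout$whisker)
  register_component(sch, "afferents", afferent_handler,
                     state = list(sim = sim))

  # --- plant component -----------------------------------------------------
  register_component(sch, "plant", plant_handler, state = list(sim = sim))
  if (n_steps > 0) {
    traj_add_cpp(pl$rec, pl$theta, pl$omega, 0L)
    post_event(sch, "plant", "plant_step", delay_ms = pl$dt_ms,
               source = "plant")
  }

  # --- spontaneous whisking-afferent background ----------------------------
  if (wm != "CPG_ONLY" && duration_ms > 0) {
    schedule_spontaneous_w(sim, duration_ms)
  }
  sim
}

# integer code per pool id keeps the hot spike-log path free of strings
sim_pool_code <- function(sim, id) {
  lg <- sim$log
  i <- match(id, lg$names)
  if (is.na(i)) {
    lg$names <- c(lg$names, id)
    i <- length(lg$names)
  }
  i
}

log_spikes <- function(sim, t_us, code, cells) {
  if (length(cells)) {
    spikelog_add_cpp(sim$log$ptr, t_us, code, as.integer(cells))
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Pool component handler (motoneuron and second-order afferent pools)

pool_component_handler <- function(sch, comp, ev) {
  sim <- comp$state$sim
  pool <- comp$state$pool
  t <- sch$clock
  kind <- ev$kind
  if (kind == "stimulate") {
    add <- rep(ev$payload$w * ev$payload$n, pool$n)
    fired <- pool_deliver(pool, t, add, ev$payload$class)
    if (length(fired)) {
      post_event(sch, pool$id, "pool_ap", delay_ms = pool$t_relay_us / 1000,
                 payload = list(cells = fired), source = pool$id)
    }
  } else if (kind == "stimulate_vec") {
    fired <- pool_deliver(pool, t, ev$payload$add, ev$payload$class)
    if (length(fired)) {
      post_event(sch, pool$id, "pool_ap", delay_ms = pool$t_relay_us / 1000,
                 payload = list(cells = fired), source = pool$id)
    }
  } else if (kind == "pool_ap") {
    cells <- ev$payload$cells
    pool_emit(pool, t, cells)
    log_spikes(sim, t, pool$code, cells)
  } else if (kind == "tip_input") {
    if (ev$payload$sign == "-" && t < pool$veto_until[1]) {
      # the pool is already silenced: inhibitory volleys are shunted
      return(invisible(NULL))
    }
    if (gate_update(pool, t, ev$payload$n)) {
      if (ev$payload$sign == "+") {
        # a pressure burst drives a short high-frequency burst in the
        # retractor motoneurons (ARP-spaced doublet/triplet)
        nb <- sim$p$neuron$tip_burst_n %||% 1
        gap <- sim$p$neuron$tip_burst_gap_ms %||% 2.5
        for (k in seq_len(nb) - 1L) {
          post_event(sch, pool$id, "tip_fire", delay_ms = k * gap,
                     payload = NULL, source = pool$id)
        }
      } else {
        pool$gate_accum <- 0
        pool_veto(pool, t, pool$veto_ms %||% sim$p$neuron$veto_direct_ms,
                  sim$p$neuron$veto_fraction %||% 1)
      }
    }
  } else if (kind == "tip_fire") {
    fired <- pool_force_fire(pool, t)
    if (length(fired)) {
      post_event(sch, "mn_bus", "ap_bus", delay_ms = pool$t_relay_us / 1000,
                 payload = list(items = list(list(pool = pool,
                                                  cells = fired))),
                 source = pool$id)
    }
  }
  invisible(NULL)
}

# Grouped motoneuron AP volleys: emit + log each pool's spikes, then pass
# the summed calcium increments to the muscles in one bus event.
mn_bus_handler <- function(sch, comp, ev) {
  sim <- comp$state$sim
  t <- sch$clock
  nm <- length(sim$ms$ids)
  inc <- numeric(nm)
  for (it in ev$payload$items) {
    pool <- it$pool
    cells <- it$cells
    pool_emit(pool, t, cells)
    log_spikes(sim, t, pool$code, cells)
    frac <- length(cells) / pool$n
    inc[pool$target_j] <- inc[pool$target_j] + frac * pool$target_gain
  }
  j <- which(inc > 0)
  if (length(j)) {
    post_event(sch, "muscle_bus", "stim_bus", delay_ms = 0.5,
               payload = list(j = j, inc = inc[j]), source = "mn_bus")
  }
  invisible(NULL)
}

# Deliver batched stimuli to the muscle charts (run-to-completion within
# this dispatch, in muscle-index order).
muscle_bus_handler <- function(sch, comp, ev) {
  sim <- comp$state$sim
  jj <- ev$payload$j
  inc <- ev$payload$inc
  for (k in seq_along(jj)) {
    mc <- sim$muscle_comps[[jj[k]]]
    mc$handler(sch, mc, list(kind = "stim", due_time = sch$clock,
                             source_id = "muscle_bus", target_id = mc$id,
                             payload = list(inc = inc[k])))
  }
  invisible(NULL)
}

# Grouped second-order afferent AP volleys: log, then route by subtype -
# whisking cells excite the whisker's motoneuron pools, contact/pressure
# cells reach the configured TIP target.
sn2_bus_handler <- function(sch, comp, ev) {
  sim <- comp$state$sim
  t <- sch$clock
  mn_items <- list()
  for (it in ev$payload$items) {
    pool <- it$pool
    cells <- it$cells
    pool_emit(pool, t, cells)
    log_spikes(sim, t, pool$code, cells)
    st <- pool$meta$subtype
    w <- pool$meta$whisker
    n <- length(cells)
    if (st == "W") {
      if (!is.null(sim$sn2w_targets)) {
        wi <- match(w, sim$net$layout$whisker)
        for (ty in MN_TYPES) {
          mp <- sim$mn_pools_by_type[[ty]][[wi]]
          fired <- pool_deliver(mp, t, rep(sim$w_sn2w * n, mp$n), "sn2w")
          if (length(fired)) {
            mn_items[[length(mn_items) + 1L]] <- list(pool = mp, cells = fired)
          }
        }
      }
    } else if (st %in% c("C", "P")) {
      rt <- sim$tip_route[[w]]
      if (!is.null(rt)) {
        post_event(sch, rt$target, "tip_input", delay_ms = rt$delay,
                   payload = list(n = n, sign = rt$sign), source = pool$id)
      }
    }
  }
  if (length(mn_items)) {
    post_event(sch, "mn_bus", "ap_bus",
               delay_ms = mn_items[[1]]$pool$t_relay_us / 1000,
               payload = list(items = mn_items), source = "sn2_bus")
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Afferent driver: first-order volleys -> spike log + second-order delivery

afferent_handler <- function(sch, comp, ev) {
  sim <- comp$state$sim
  p <- sim$p
  pl <- sim$pl
  t <- sch$clock
  pay <- ev$payload
  w <- pay$whisker
  kind <- ev$kind
  deliver_sn2 <- function(subtype, cells) {
    pool <- get(paste0("sn2_", subtype, "_", w), envir = sim$pools)
    counts <- as.numeric(pool$fanin[, cells, drop = FALSE] %*%
                           rep(1, length(cells)))
    fired <- pool_deliver(pool, t, counts, "sn1")
    if (length(fired)) {
      post_event(sch, "sn2_bus", "ap_bus",
                 delay_ms = pool$t_relay_us / 1000,
                 payload = list(items = list(list(pool = pool, cells = fired))),
                 source = "afferents")
    }
  }
  if (kind == "w_volley") {
    # whisking cells fire only while their whisker still protracts
    wi <- match(w, sim$net$layout$whisker)
    if (pl$omega[wi] <= p$afferent$omega_min_deg_ms &&
        !isTRUE(pay$spontaneous)) {
      return(invisible(NULL))
    }
    log_spikes(sim, t, sim$sn1_codes[[w]][["W"]], pay$cells)
    deliver_sn2("W", pay$cells)
  } else if (kind == "c_volley") {
    cells <- seq_len(sim$net$sn1_n[["C"]])
    log_spikes(sim, t, sim$sn1_codes[[w]][["C"]], cells)
    deliver_sn2("C", cells)
  } else if (kind == "p_volley") {
    if (!pl$in_contact || pl$contact_ep != pay$ep) return(invisible(NULL))
    cells <- seq_len(sim$net$sn1_n[["P"]])
    log_spikes(sim, t, sim$sn1_codes[[w]][["P"]], cells)
    deliver_sn2("P", cells)
    post_event(sch, "afferents", "p_volley",
               delay_ms = p$afferent$pressure_interval_ms,
               payload = list(whisker = w, ep = pay$ep), source = "afferents")
  } else if (kind == "d_volley") {
    cells <- seq_len(sim$net$sn1_n[["D"]])
    log_spikes(sim, t, sim$sn1_codes[[w]][["D"]], cells)
    deliver_sn2("D", cells)
  }
  invisible(NULL)
}

# Protraction-locked whisking-cell volleys for one episode, bucketed to 2 ms.
schedule_w_volleys <- function(sim, w) {
  p <- sim$p$afferent
  offs <- sim$net$w_offsets[[w]]
  ks <- seq_len(p$w_spikes_per_protraction) - 1
  tt <- outer(offs, ks * p$w_interval_ms, `+`)  # relative spike times
  cell <- as.integer(row(tt))
  bucket <- floor(as.numeric(tt) / 3) * 3
  for (b in unique(sort(bucket))) {
    post_event(sim$sch, "afferents", "w_volley", delay_ms = b,
               payload = list(whisker = w, cells = cell[bucket == b]),
               source = "plant")
  }
  invisible(NULL)
}

schedule_spontaneous_w <- function(sim, duration_ms) {
  p <- sim$p$afferent
  period <- 1000 / p$w_spont_hz
  for (w in sim$net$layout$whisker) {
    offs <- sim$net$w_spont_offsets[[w]]
    grid <- seq(0, duration_ms, by = period)
    tt <- as.numeric(outer(offs, grid, `+`))
    cell <- rep(seq_along(offs), times = length(grid))
    keep <- tt <= duration_ms
    tt <- tt[keep]; cell <- cell[keep]
    bucket <- floor(tt / 5) * 5
    for (b in unique(sort(bucket))) {
      post_event(sim$sch, "afferents", "w_volley", delay_ms = b,
                 payload = list(whisker = w, cells = cell[bucket == b],
                                spontaneous = TRUE),
                 source = "plant")
    }
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Plant component: fixed-step integration interleaved with the event queue

plant_handler <- function(sch, comp, ev) {
  sim <- comp$state$sim
  if (ev$kind != "plant_step") return(invisible(NULL))
  p <- sim$p
  pl <- sim$pl
  t_us <- sch$clock
  A <- muscle_forces_at(sim$ms, t_us)
  torque <- as.numeric(pl$attach %*% A)
  # elastic pole contact: while touching, bending into the pole loads a
  # stiff one-sided spring on the base angle (the rigid-whisker stand-in
  # for the bending reserve); the pole pushes back but cannot pull
  damping <- NULL
  if (!is.null(pl$obs) && pl$in_contact) {
    wi <- pl$obs_idx
    over <- pl$theta[wi] - pl$obs$theta_obs_deg
    if (over > 0) torque[wi] <- torque[wi] - pl$k_contact * over
    damping <- rep(pl$damping, length(pl$theta))
    damping[wi] <- pl$damping + pl$b_contact
  }
  st <- plant_step_core(pl, torque, pl$dt_ms, damping)
  th <- st$theta; om <- st$omega
  if (any(!is.finite(th))) {
    stop("non-finite whisker state at t = ", t_us / 1000, " ms", call. = FALSE)
  }
  if (!is.null(pl$obs)) {
    wi <- pl$obs_idx
    thr_obs <- pl$obs$theta_obs_deg
    if (!pl$in_contact) {
      if (th[wi] >= thr_obs) {
        pl$in_contact <- TRUE
        pl$contact_ep <- pl$contact_ep + 1L
        w <- pl$obs$whisker
        post_event(sch, "obstacle", "contact", delay_ms = 0, source = "plant")
        post_event(sch, "afferents", "c_volley",
                   delay_ms = p$afferent$sn1_relay_ms,
                   payload = list(whisker = w), source = "plant")
        post_event(sch, "afferents", "p_volley",
                   delay_ms = pressure_latency(pl$obs$r, p),
                   payload = list(whisker = w, ep = pl$contact_ep),
                   source = "plant")
      }
    } else if (th[wi] < thr_obs - pl$eps) {
      # retracted past the straightening reserve: the whisker leaves the pole
      pl$in_contact <- FALSE
      post_event(sch, "obstacle", "detach", delay_ms = 0, source = "plant")
      post_event(sch, "afferents", "d_volley",
                 delay_ms = p$afferent$sn1_relay_ms,
                 payload = list(whisker = pl$obs$whisker), source = "plant")
    }
  }
  pl$theta <- th; pl$omega <- om
  # whisking-cell protraction episodes (60 ms refractory per whisker)
  protracting <- om > p$afferent$omega_min_deg_ms
  t_ms <- t_us / 1000 + pl$dt_ms
  new_ep <- protracting & !pl$protracting_prev &
    (t_ms - pl$episode_last / 1000 > 60)
  if (any(new_ep)) {
    for (wi in which(new_ep)) {
      pl$episode_last[wi] <- t_ms * 1000
      schedule_w_volleys(sim, sim$net$layout$whisker[wi])
    }
  }
  pl$protracting_prev <- protracting
  # whisker chart settling notifications
  moving <- abs(om) > 0.005 | abs(th - pl$theta_rest) > 0.3
  settled <- pl$moving_prev & !moving
  if (any(settled)) {
    for (wi in which(settled)) {
      post_event(sch, sim$whisker_charts[[wi]], "settled", delay_ms = 0,
                 source = "plant")
    }
  }
  pl$moving_prev <- moving
  # record and continue
  pl$step_i <- pl$step_i + 1L
  traj_add_cpp(pl$rec, th, om, as.integer(pl$in_contact))
  if (pl$step_i < pl$n_steps) {
    post_event(sch, "plant", "plant_step", delay_ms = pl$dt_ms,
               source = "plant")
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Result assembly

sim_collect <- function(sim) {
  pl <- sim$pl
  layout <- sim$net$layout
  nw <- nrow(layout)
  rec <- traj_collect_cpp(pl$rec)
  n_rec <- rec$n
  t_grid <- (seq_len(max(n_rec, 0L)) - 1L) * pl$dt_ms
  traj <- if (n_rec > 0) {
    tibble::tibble(
      t_ms = rep(t_grid, times = nw),
      whisker = rep(layout$whisker, each = n_rec),
      row = rep(layout$row, each = n_rec),
      arc = rep(layout$arc, each = n_rec),
      theta = as.numeric(t(rec$theta)),
      omega = as.numeric(t(rec$omega)),
      contact = if (!is.null(pl$obs)) {
        as.logical(rep(layout$idx == pl$obs_idx, each = n_rec) &
                     rep(as.logical(rec$contact), times = nw))
      } else FALSE
    )
  } else {
    tibble::tibble(t_ms = numeric(), whisker = character(), row = character(),
                   arc = integer(), theta = numeric(), omega = numeric(),
                   contact = logical())
  }
  lg <- sim$log
  raw <- spikelog_collect_cpp(lg$ptr)
  spikes <- if (length(raw$t_us) > 0) {
    nm_parts <- strsplit(lg$names, "_", fixed = TRUE)
    cls <- toupper(vapply(nm_parts, `[[`, "", 1L))
    sty <- vapply(nm_parts, `[[`, "", 2L)
    wsk <- vapply(nm_parts, `[[`, "", 3L)
    tibble::tibble(
      t_ms = raw$t_us / 1000,
      pool = lg$names[raw$code],
      class = cls[raw$code],
      subtype = sty[raw$code],
      whisker = wsk[raw$code],
      cell = raw$cell
    ) |> dplyr::arrange(.data$t_ms, .data$pool, .data$cell)
  } else {
    tibble::tibble(t_ms = numeric(), pool = character(), class = character(),
                   subtype = character(), whisker = character(),
                   cell = integer())
  }
  contacts <- if (!is.null(pl$obs) && n_rec > 0) {
    tr1 <- traj[traj$whisker == pl$obs$whisker, c("t_ms", "theta")]
    contact_events(tr1, pl$obs, pl$eps)
  } else {
    tibble::tibble(onset_ms = numeric(), offset_ms = numeric())
  }
  cfg <- sim$net$config
  meta <- list(
    configuration = list(whisking_mechanism = cfg$whisking_mechanism,
                         tip_mechanism = cfg$tip_mechanism, seed = cfg$seed),
    obstacle = if (!is.null(pl$obs)) unclass(pl$obs) else NULL,
    duration_ms = sim$duration_ms,
    dt_ms = pl$dt_ms,
    params = sim$p,
    config_hash = hash_object(list(cfg = unclass(cfg), obs = pl$obs,
                                   dur = sim$duration_ms, params = sim$p)),
    network_hash = network_hash(sim$net),
    n_events = sim$sch$seq,
    package_version = as.character(utils::packageVersion("whiskloop"))
  )
  res <- list(trajectories = traj, spikes = spikes,
              transitions = scheduler_trace(sim$sch),
              contacts = contacts, meta = meta)
  class(res) <- "whisk_sim"
  res
}

#' @export
print.whisk_sim <- function(x, ...) {
  m <- x$meta
  cat("<whisk_sim> ", m$configuration$whisking_mechanism, " + ",
      m$configuration$tip_mechanism, ", ", m$duration_ms, " ms, seed ",
      m$configuration$seed, "\n", sep = "")
  cat("  trajectories: ", nrow(x$trajectories), " samples over ",
      length(unique(x$trajectories$whisker)), " whiskers; spikes: ",
      nrow(x$spikes), "; contacts: ", nrow(x$contacts), "\n", sep = "")
  invisible(x)
}

# md5 of a canonical JSON rendering; changes iff any effective field changes
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Reproducibility hashes of a simulation result
#'
#' @param sim a `whisk_sim`.
#' @return named character: md5 of the trajectory table and of the spike log.
#'   Identical (configuration, seed) runs give identical hashes.
#' @export
sim_hashes <- function(sim) {
  h <- function(df) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    utils::write.csv(as.data.frame(df), tmp, row.names = FALSE)
    unname(tools::md5sum(tmp))
  }
  c(trajectories = h(sim$trajectories), spikes = h(sim$spikes))
}

# ---------------------------------------------------------------------------
# Serialisation

#' Write a simulation result to a directory
#'
#' Trajectory and spike CSVs, transition trace as JSON lines, and metadata
#' JSON; [read_simulation()] restores an equal object.
#'
#' @param sim a `whisk_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(sim$trajectories),
                   file.path(dir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$spikes),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  write_trace_jsonl(sim$transitions, file.path(dir, "transitions.jsonl"))
  utils::write.csv(as.data.frame(sim$contacts),
                   file.path(dir, "contacts.csv"), row.names = FALSE)
  jsonlite::write_json(sim$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a simulation result written by [write_simulation()]
#'
#' @param dir directory written by [write_simulation()].
#' @return a `whisk_sim`.
#' @export
read_simulation <- function(dir) {
  read_csv0 <- function(f) {
    tibble::as_tibble(utils::read.csv(file.path(dir, f),
                                      stringsAsFactors = FALSE))
  }
  traj <- read_csv0("trajectories.csv")
  spikes <- read_csv0("spikes.csv")
  contacts <- read_csv0("contacts.csv")
  tr_lines <- readLines(file.path(dir, "transitions.jsonl"))
  transitions <- if (length(tr_lines)) {
    recs <- lapply(tr_lines, jsonlite::fromJSON)
    tibble::tibble(
      t_ms = vapply(recs, function(r) r$t_us / 1000, numeric(1)),
      component = vapply(recs, `[[`, "", "component"),
      event = vapply(recs, `[[`, "", "event"),
      from_state = vapply(recs, `[[`, "", "from_state"),
      to_state = vapply(recs, `[[`, "", "to_state")
    )
  } else {
    tibble::tibble(t_ms = numeric(), component = character(),
                   event = character(), from_state = character(),
                   to_state = character())
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  res <- list(trajectories = traj, spikes = spikes, transitions = transitions,
              contacts = contacts, meta = meta)
  class(res) <- "whisk_sim"
  res
}

# ---------------------------------------------------------------------------
# Parameter sweeps

#' Sweep one parameter axis over a set of values
#'
#' Runs one child simulation per value (shared seed and configuration) and
#' emits a per-value kinematic summary: cycle statistics in free air, plus
#' first-pump delay and amplitude of the touching whisker when an obstacle
#' is present.
#'
#' @param configuration a [whisk_configuration()].
#' @param axis dotted parameter name: `"obstacle.r"`,
#'   `"obstacle.theta_obs_deg"`, or any model parameter path accepted by
#'   [whisk_params()] overrides.
#' @param values numeric vector of axis values.
#' @param duration_ms per-run duration.
#' @param obstacle base [obstacle()] (required for `obstacle.*` axes).
#' @return list with `results` (one `whisk_sim` per value) and `summary`
#'   (tibble: one row per value).
#' @export
sweep_simulation <- function(configuration, axis, values, duration_ms = 600,
                             obstacle = NULL) {
  if (!is.character(axis) || length(axis) != 1) {
    stop("axis must be a single parameter name", call. = FALSE)
  }
  if (length(values) == 0) {
    return(list(results = list(),
                summary = tibble::tibble(value = numeric())))
  }
  known_obs <- c("obstacle.r", "obstacle.theta_obs_deg")
  is_obs_axis <- axis %in% known_obs
  if (startsWith(axis, "obstacle.") && !is_obs_axis) {
    stop("unknown obstacle axis: ", axis, call. = FALSE)
  }
  if (is_obs_axis && is.null(obstacle)) {
    stop("axis ", axis, " needs a base obstacle", call. = FALSE)
  }
  if (!is_obs_axis) {
    probe <- try(whisk_params(stats::setNames(list(values[1]), axis)),
                 silent = TRUE)
    if (inherits(probe, "try-error")) stop("unknown axis: ", axis, call. = FALSE)
  }
  results <- purrr::map(values, function(v) {
    if (is_obs_axis) {
      ob <- obstacle
      ob[[sub("^obstacle\\.", "", axis)]] <- v
      run_simulation(configuration, duration_ms, obstacle = ob)
    } else {
      cfg <- configuration
      cfg$overrides <- merge_params(cfg$overrides %||% list(),
                                    undot_params(stats::setNames(list(v), axis)))
      run_simulation(cfg, duration_ms, obstacle = obstacle)
    }
  })
  summary <- purrr::map2_dfr(results, values, function(s, v) {
    out <- tibble::tibble(value = v)
    cyc <- try(segment_cycles(s$trajectories[s$trajectories$whisker ==
      (s$meta$obstacle$whisker %||% s$trajectories$whisker[1]), ]),
      silent = TRUE)
    if (!inherits(cyc, "try-error") && nrow(cyc)) {
      out$cycle_ms <- mean(cyc$duration_ms)
    }
    if (!is.null(s$meta$obstacle)) {
      tips <- detect_tips(s$trajectories, s$contacts,
                          whisker = s$meta$obstacle$whisker)
      first <- dplyr::filter(tips, .data$first_in_cycle)
      out$tip_delay_ms <- if (nrow(first)) mean(first$delay_ms) else NA_real_
      out$tip_amplitude <- if (nrow(first)) mean(first$amplitude) else NA_real_
      out$tips_per_contact <- if (nrow(s$contacts)) {
        nrow(tips) / nrow(s$contacts)
      } else NA_real_
    }
    out
  })
  list(results = results, summary = summary)
}
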