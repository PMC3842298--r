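# Musculoskeletal plant: calcium-gated muscle contraction (two-state chart
# with exponential Ca decay between stimuli and a saturating force), rigid
# whiskers as damped torsional springs integrated with fixed-step
# semi-implicit Euler, and obstacle contact with a clamp at the contact
# azimuth plus a detach tolerance that lets sub-degree pumps keep touching.

# ---------------------------------------------------------------------------
# Muscle chart. Mutable Ca state lives in the shared muscle store (vectors
# indexed by muscle), so the plant can evaluate forces between events.

muscle_ca_at <- function(ms, j, t_us) {
  ms$ca[j] * exp(-(t_us - ms$t_last[j]) / 1000 / ms$tau[j])
}

muscle_commit_stim <- function(ms, j, t_us, inc) {
  ca <- min(muscle_ca_at(ms, j, t_us) + inc, ms$ca_max[j])
  ms$ca[j] <- ca
  ms$t_last[j] <- t_us
  ca
}

#' Muscle statechart definition
#'
#' `Rest` and `Contract`. Each motoneuron volley raises the muscle's calcium
#' activation `Ca` (which otherwise decays exponentially with `tau_ms`); the
#' muscle contracts while `Ca >= Ca_0`, re-entering `Contract` with updated
#' parameters on further stimuli, and relaxes when `Ca` decays below `Ca_0`
#' (a timeout armed at the predicted crossing). Every `Contract` entry posts
#' a `move` event to the attached whisker(s).
#'
#' @return a [chart_def()]. Instance params: `j` (muscle store index),
#'   `store` (shared muscle store), `whisker_charts` (component ids to
#'   notify).
#' @export
muscle_chart_def <- function() {
  above_after <- function(inst, ev) {
    ms <- inst$params$store
    muscle_ca_at(ms, inst$params$j, ev$due_time) + ev$payload$inc >=
      ms$ca0[inst$params$j]
  }
  commit <- function(sch, inst, ev) {
    muscle_commit_stim(inst$params$store, inst$params$j, sch$clock,
                       ev$payload$inc)
  }
  notify <- function(sch, inst) {
    # move events to whiskers already in Move would be discarded no-ops;
    # only resting whiskers are notified
    for (wc in inst$params$whisker_charts) {
      comp <- get_component(sch, wc)
      if (comp$state$current_state == "Rest") {
        post_event(sch, wc, "move", delay_ms = 0, source = inst$id)
      }
    }
  }
  chart_def(
    name = "Muscle",
    states = c("Rest", "Contract"),
    initial = "Rest",
    transitions = list(
      transition("Rest", "stim", "Contract", guard = above_after,
                 actions = function(sch, inst, ev) commit(sch, inst, ev)),
      transition("Rest", "stim",  # sub-threshold: Ca rises, stays at rest
                 actions = function(sch, inst, ev) commit(sch, inst, ev)),
      transition("Contract", "stim", "Contract",
                 actions = function(sch, inst, ev) commit(sch, inst, ev)),
      transition("Contract", tm_trigger("Contract"), "Rest")
    ),
    timeouts = list(
      Contract = function(inst) {
        ms <- inst$params$store
        j <- inst$params$j
        # time for Ca to decay to Ca_0 from now
        max(ms$tau[j] * log(ms$ca[j] / ms$ca0[j]), 0)
      }
    ),
    entry = list(Contract = notify)
  )
}

#' Instantaneous muscle force
#'
#' Zero at rest; in contraction a saturating function of the calcium excess,
#' `A = A_max * (1 - exp(-(Ca - Ca_0) / Ca_sat))`, continuous at the
#' threshold and bounded by `A_max`.
#'
#' @param ca calcium activation (vector).
#' @param ca0 contraction threshold.
#' @param ca_sat saturation scale.
#' @param a_max force ceiling (torque units).
#' @return force magnitudes (same length as `ca`).
#' @export
muscle_force <- function(ca, ca0, ca_sat, a_max) {
  ifelse(ca >= ca0, a_max * (1 - exp(-(ca - ca0) / ca_sat)), 0)
}

# Shared muscle store: Ca state + force constants as vectors over muscles.
new_muscle_store <- function(net) {
  p <- net$params
  tab <- net$muscles
  nm <- nrow(tab)
  ms <- new.env(parent = emptyenv())
  ms$ids <- tab$muscle
  get_par <- function(field) {
    vapply(tab$type, function(ty) p$muscle[[ty]][[field]], numeric(1),
           USE.NAMES = FALSE)
  }
  ms$tau <- get_par("tau_ms")
  ms$ca0 <- get_par("ca0")
  ms$ca_max <- vapply(tab$type, function(ty) {
    p$muscle[[ty]]$ca_max %||% Inf
  }, numeric(1), USE.NAMES = FALSE)
  ms$ca_sat <- get_par("ca_sat")
  ms$a_max <- get_par("a_max")
  ms$ca_gain <- get_par("ca_gain")
  ms$ca <- numeric(nm)
  ms$t_last <- numeric(nm)
  ms
}

muscle_forces_at <- function(ms, t_us) {
  ca <- ms$ca * exp(-(t_us - ms$t_last) / 1000 / ms$tau)
  muscle_force(ca, ms$ca0, ms$ca_sat, ms$a_max)
}

# ---------------------------------------------------------------------------
# Whisker + obstacle charts (state bookkeeping; dynamics are in the plant)

whisker_chart_def <- function() {
  chart_def(
    name = "Whisker",
    states = c("Rest", "Move"),
    initial = "Rest",
    transitions = list(
      transition("Rest", "move", "Move"),
      transition("Move", "move"),          # already moving: no-op
      transition("Move", "settled", "Rest")
    )
  )
}

obstacle_chart_def <- function() {
  chart_def(
    name = "Obstacle",
    states = c("NoContact", "Contact"),
    initial = "NoContact",
    transitions = list(
      transition("NoContact", "contact", "Contact"),
      transition("Contact", "detach", "NoContact")
    )
  )
}

#' Obstacle description
#'
#' A static pole in the sweeping range of one whisker, present for the whole
#' run: contact begins whenever that whisker protracts to the contact
#' azimuth.
#'
#' @param whisker whisker id the pole intersects (e.g. `"A4"`).
#' @param theta_obs_deg azimuth of contact in degrees.
#' @param r radial fraction of the whisker length at the contact point,
#'   in (0, 1].
#' @return an `whisk_obstacle` list.
#' @export
obstacle <- function(whisker = "A4", theta_obs_deg = 74.7, r = 0.4) {
  if (!is.finite(r) || r <= 0 || r > 1) {
    stop("radial fraction r must lie in (0, 1]", call. = FALSE)
  }
  structure(list(whisker = whisker, theta_obs_deg = theta_obs_deg, r = r),
            class = "whisk_obstacle")
}

# ---------------------------------------------------------------------------
# Plant stepping (vectorised over whiskers); called from the plant
# component's recurring step event inside run_simulation().

plant_step_core <- function(pl, torque, dt_ms, damping = NULL) {
  # semi-implicit Euler on I*domega = T - b*omega - k*(theta - rest)
  b <- damping %||% pl$damping
  om <- (pl$omega + dt_ms / pl$inertia *
           (torque - pl$stiffness * (pl$theta - pl$theta_rest))) /
    (1 + dt_ms * b / pl$inertia)
  th <- pl$theta + dt_ms * om
  list(theta = th, omega = om)
}

#' Contact episodes of a whisker trajectory
#'
#' Reconstructs ordered, non-overlapping (onset, offset) contact episodes
#' from a trajectory of one whisker against a static obstacle: onset when
#' the protracting whisker first reaches the contact azimuth, offset when it
#' falls below `theta_obs - eps_contact` (pumps smaller than the tolerance
#' keep touching, by the whisker straightening rather than leaving).
#'
#' @param trajectory data frame with `t_ms` and `theta` for one whisker,
#'   sampled at the plant step.
#' @param obstacle an [obstacle()], or `NULL` for free air.
#' @param eps_contact_deg detach tolerance in degrees.
#' @return tibble of episodes: `onset_ms`, `offset_ms` (`NA` if still in
#'   contact at the end).
#' @export
contact_events <- function(trajectory, obstacle = NULL, eps_contact_deg = 2) {
  if (is.null(obstacle)) {
    return(tibble::tibble(onset_ms = numeric(), offset_ms = numeric()))
  }
  th <- trajectory$theta
  tt <- trajectory$t_ms
  in_contact <- FALSE
  onsets <- numeric(); offsets <- numeric()
  for (i in seq_along(th)) {
    if (!in_contact) {
      if (th[i] >= obstacle$theta_obs_deg - 1e-9) {
        in_contact <- TRUE
        onsets <- c(onsets, tt[i])
      }
    } else if (th[i] < obstacle$theta_obs_deg - eps_contact_deg) {
      in_contact <- FALSE
      offsets <- c(offsets, tt[i])
    }
  }
  if (in_contact) offsets <- c(offsets, NA_real_)
  tibble::tibble(onset_ms = onsets, offset_ms = offsets)
}
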