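# Minimal executable-statechart semantics: flat named states, event-triggered
# transitions with guards and action lists, per-state timeouts, and condition
# connectors expressed as guarded transition alternatives evaluated at
# dispatch time. Exactly the language the component charts (CPG, neuron,
# muscle, whisker, obstacle) need - not full UML.

#' Define a statechart transition
#'
#' @param from source state name.
#' @param trigger event kind that can enable the transition. Use
#'   [tm_trigger()] for the source state's timeout.
#' @param to target state name.
#' @param guard optional predicate `function(inst, ev)`; the transition is
#'   enabled only when it returns `TRUE`. Alternatives sharing
#'   `(from, trigger)` express a condition connector and are evaluated in
#'   declaration order; at most one fires.
#' @param actions optional `function(sch, inst, ev)` run between exiting
#'   `from` and entering `to` (run-to-completion: it may post events but
#'   nothing is dispatched until it returns).
#' @return a transition description (list).
#' @export
transition <- function(from, trigger, to = NULL, guard = NULL, actions = NULL) {
  stopifnot(is.character(from), is.character(trigger),
            is.null(to) || is.character(to))
  list(from = from, trigger = trigger, to = to, guard = guard, actions = actions,
       internal = is.null(to))
}

#' Timeout trigger tag for a state
#'
#' `tm(X)` timeouts in the chart diagrams become events with this kind.
#' @param state state name the timeout is attached to.
#' @return the trigger string.
#' @export
tm_trigger <- function(state) paste0("tm_", state)

#' Define a statechart
#'
#' @param name chart (class) name.
#' @param states character vector of state names; the first is not special.
#' @param initial initial state name.
#' @param transitions list of [transition()] descriptions.
#' @param timeouts named list mapping state name to `function(inst)` returning
#'   the state's timeout in ms (the `tm(X)` annotations); entering the state
#'   arms the timeout, leaving it (or re-entering) cancels the stale one.
#' @param entry optional named list of `function(sch, inst)` entry actions.
#' @return a `chart_def` object.
#' @export
chart_def <- function(name, states, initial, transitions,
                      timeouts = list(), entry = list()) {
  stopifnot(initial %in% states)
  for (tr in transitions) {
    if (!(tr$from %in% states) || (!tr$internal && !(tr$to %in% states))) {
      stop("transition references unknown state in chart ", name, call. = FALSE)
    }
  }
  idx <- split(transitions, vapply(transitions, function(tr) {
    paste(tr$from, tr$trigger, sep = "\r")
  }, character(1)))
  structure(list(name = name, states = states, initial = initial,
                 transitions = transitions, index = idx,
                 timeouts = timeouts, entry = entry),
            class = "chart_def")
}

#' Instantiate a chart as a scheduler component
#'
#' Creates one live copy of the chart (its own current state, parameters and
#' pending timeouts) and registers it with the scheduler. Many copies of each
#' chart are generated in a full network, one per modelled component.
#'
#' @param sch scheduler.
#' @param def a [chart_def()].
#' @param id component id.
#' @param params named list of instance parameters (stored in an environment,
#'   mutable from actions via `inst$params$...`).
#' @return the chart instance (an environment), invisibly.
#' @export
chart_instance <- function(sch, def, id, params = list()) {
  inst <- new.env(parent = emptyenv())
  inst$def <- def
  inst$id <- id
  inst$current_state <- def$initial
  inst$params <- list2env(params, parent = emptyenv())
  inst$epoch <- 0L
  class(inst) <- "chart_instance"
  register_component(sch, id, chart_handler, state = inst)
  chart_enter_state(sch, inst, def$initial, arm_only = TRUE)
  invisible(inst)
}

chart_enter_state <- function(sch, inst, state, arm_only = FALSE) {
  inst$current_state <- state
  inst$epoch <- inst$epoch + 1L  # cancels stale timeouts of the left state
  def <- inst$def
  if (!arm_only) {
    fn <- def$entry[[state]]
    if (!is.null(fn)) fn(sch, inst)
  }
  tmo <- def$timeouts[[state]]
  if (!is.null(tmo)) {
    post_event(sch, inst$id, tm_trigger(state), delay_ms = tmo(inst),
               payload = list(epoch = inst$epoch), source = inst$id)
  }
  invisible(NULL)
}

chart_handler <- function(sch, comp, ev) {
  inst <- comp$state
  # stale timeout: armed for a state instance that has since been left
  if (startsWith(ev$kind, "tm_") && !is.null(ev$payload$epoch) &&
      ev$payload$epoch != inst$epoch) {
    return(invisible(NULL))
  }
  cand <- inst$def$index[[paste(inst$current_state, ev$kind, sep = "\r")]]
  fired <- NULL
  if (!is.null(cand)) {
    for (tr in cand) {
      if (is.null(tr$guard) || isTRUE(tr$guard(inst, ev))) { fired <- tr; break }
    }
  }
  if (is.null(fired)) {
    trace_add(sch, sch$clock, inst$id, ev$kind, inst$current_state, "(discarded)")
    return(invisible(NULL))
  }
  from <- inst$current_state
  if (!is.null(fired$actions)) fired$actions(sch, inst, ev)
  if (fired$internal) {
    # internal transition: actions only, state (and its timeout) untouched
    trace_add(sch, sch$clock, inst$id, ev$kind, from, from)
  } else {
    chart_enter_state(sch, inst, fired$to)
    trace_add(sch, sch$clock, inst$id, ev$kind, from, fired$to)
  }
  invisible(NULL)
}

#' Current state of a chart instance
#' @param inst a chart instance.
#' @return the active leaf state name (always exactly one).
#' @export
chart_state <- function(inst) inst$current_state
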