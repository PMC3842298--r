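# Discrete-event core: a simulated clock in integer microseconds, a binary
# heap of pending events ordered by (due_time, insertion seq), and a registry
# of components that consume events. Equal-due-time ties always break FIFO by
# insertion order, which makes every run reproducible event-for-event.

MICRO_PER_MS <- 1000
.SEQ_MAX <- 1e6  # per-run insertion counter bound; key packs t_us * 1e6 + seq
# The queue, trace and logs live behind external pointers (src/structures.cpp)
# so the per-event path avoids copy-on-write of growing vectors.

#' Create a discrete-event scheduler
#'
#' The scheduler owns the simulated clock (integer microseconds), the pending
#' event queue and the append-only transition trace. Components (statechart
#' instances, neuron pools, the musculoskeletal plant) register themselves
#' with [register_component()] and receive events through their handler.
#'
#' @param trace logical; record a transition trace row for every dispatch of a
#'   chart-instance event. Pool volleys are logged in the spike log instead.
#' @return a `whisk_scheduler` object (an environment).
#' @export
new_scheduler <- function(trace = TRUE) {
  sch <- new.env(parent = emptyenv())
  sch$clock <- 0            # µs
  sch$seq <- 0L
  sch$heap <- heap_new_cpp()
  sch$events <- new.env(hash = TRUE, parent = emptyenv())
  sch$components <- new.env(parent = emptyenv())
  sch$trace_on <- isTRUE(trace)
  sch$trace <- trace_new_cpp()
  sch$dispatching <- FALSE  # run-to-completion guard
  class(sch) <- "whisk_scheduler"
  sch
}

#' @export
print.whisk_scheduler <- function(x, ...) {
  cat("<whisk_scheduler> clock =", x$clock / MICRO_PER_MS, "ms,",
      heap_size_cpp(x$heap), "pending events,", length(ls(x$components)),
      "components\n")
  invisible(x)
}

register_component <- function(sch, id, handler, state = NULL) {
  assign(id, list(id = id, handler = handler, state = state), envir = sch$components)
  invisible(id)
}

get_component <- function(sch, id) {
  if (!exists(id, envir = sch$components, inherits = FALSE)) {
    stop("event addressed to unknown component: ", id, call. = FALSE)
  }
  get(id, envir = sch$components, inherits = FALSE)
}

#' Post an event to the scheduler
#'
#' Enqueues an event for `target` at `clock + delay_ms`. Events with equal due
#' times are dispatched strictly in posting order (FIFO).
#'
#' @param sch a scheduler from [new_scheduler()].
#' @param target component id the event is addressed to.
#' @param kind event kind (e.g. `"stimulate"`, `"move"`, `"contact"`,
#'   `"detach"`, a timeout tag, or any custom symbol).
#' @param delay_ms non-negative delay in milliseconds.
#' @param payload arbitrary payload (a list: synaptic weights, kinematics, ...).
#' @param source posting component id (bookkeeping only).
#' @return invisibly, the scheduled event (a list including `due_time` in µs
#'   and its insertion `seq`).
#' @export
post_event <- function(sch, target, kind, delay_ms = 0, payload = NULL,
                       source = NA_character_) {
  if (!is.numeric(delay_ms) || length(delay_ms) != 1L || is.na(delay_ms) ||
      delay_ms < 0) {
    stop("post_event(): delay must be a single non-negative number of ms",
         call. = FALSE)
  }
  sch$seq <- sch$seq + 1L
  if (sch$seq >= .SEQ_MAX) stop("scheduler seq counter exhausted", call. = FALSE)
  due <- sch$clock + round(delay_ms * MICRO_PER_MS)
  ev <- list(kind = kind, source_id = source, target_id = target,
             payload = payload, due_time = due, seq = sch$seq)
  id <- sch$seq
  assign(as.character(id), ev, envir = sch$events)
  heap_push_cpp(sch$heap, due * .SEQ_MAX + id, id)
  invisible(ev)
}

trace_add <- function(sch, t_us, comp, ev, from, to) {
  if (!sch$trace_on) return(invisible(NULL))
  trace_add_cpp(sch$trace, t_us, comp, ev, from, to)
  invisible(NULL)
}

#' Dispatch the next pending event
#'
#' Advances the clock to the due time of the earliest event and hands it to
#' its target component. A chart instance fires at most one enabled
#' transition, run-to-completion (exit, actions, entry, new timeouts); events
#' that find no enabled transition are discarded and logged. Dispatching with
#' an empty queue is a no-op.
#'
#' @param sch a scheduler.
#' @return invisibly, the dispatched event or `NULL` if the queue was empty.
#' @export
dispatch <- function(sch) {
  id <- heap_pop_cpp(sch$heap)
  if (is.na(id)) return(invisible(NULL))
  key <- as.character(id)
  ev <- get(key, envir = sch$events, inherits = FALSE)
  rm(list = key, envir = sch$events)
  stopifnot(ev$due_time >= sch$clock)  # clock monotonicity
  sch$clock <- ev$due_time
  comp <- get_component(sch, ev$target_id)
  if (sch$dispatching) stop("re-entrant dispatch: run-to-completion violated")
  sch$dispatching <- TRUE
  on.exit(sch$dispatching <- FALSE)
  comp$handler(sch, comp, ev)
  invisible(ev)
}

#' Run the scheduler up to a time horizon
#'
#' Dispatches every event due at or before `t_end_ms`, then sets the clock to
#' `t_end_ms`. Identical configurations and seeds give byte-identical traces.
#'
#' @param sch a scheduler.
#' @param t_end_ms horizon in ms; must not precede the current clock.
#' @return the transition trace up to the horizon, as a tibble
#'   (`t_ms`, `component`, `event`, `from_state`, `to_state`).
#' @export
run_until <- function(sch, t_end_ms) {
  t_end <- round(t_end_ms * MICRO_PER_MS)
  if (t_end < sch$clock) stop("run_until(): horizon precedes current clock")
  repeat {
    nxt_key <- heap_min_key_cpp(sch$heap)
    if (is.na(nxt_key) || nxt_key %/% .SEQ_MAX > t_end) break
    dispatch(sch)
  }
  sch$clock <- max(sch$clock, t_end)
  scheduler_trace(sch)
}

#' Extract the transition trace
#'
#' @param sch a scheduler.
#' @return tibble with one row per logged dispatch: `t_ms`, `component`,
#'   `event`, `from_state`, `to_state`. Discarded events carry
#'   `to_state = "(discarded)"`.
#' @export
scheduler_trace <- function(sch) {
  raw <- trace_collect_cpp(sch$trace)
  tibble::tibble(
    t_ms = raw$t_us / MICRO_PER_MS,
    component = raw$component,
    event = raw$event,
    from_state = raw$from_state,
    to_state = raw$to_state
  )
}

#' Write a transition trace as JSON lines
#'
#' One JSON record per dispatch:
#' `{"t_us":..., "component":..., "event":..., "from_state":..., "to_state":...}`.
#'
#' @param trace a trace tibble from [scheduler_trace()] or [run_until()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  rec <- trace
  rec$t_us <- as.integer(round(rec$t_ms * MICRO_PER_MS))
  rec <- rec[, c("t_us", "component", "event", "from_state", "to_state")]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(rec))) {
    writeLines(jsonlite::toJSON(as.list(rec[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
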