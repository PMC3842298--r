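# Executable-statechart semantics: guards, timeouts, run-to-completion, and
# the CPG chart's condition connector.

test_that("a guarded event with a false guard is discarded and logged", {
  sch <- new_scheduler()
  inst <- chart_instance(sch, chart_def(
    "G", c("A", "B"), "A",
    transitions = list(
      transition("A", "go", "B", guard = function(inst, ev) FALSE))), "g")
  post_event(sch, "g", "go", delay_ms = 1)
  tr <- run_until(sch, 5)
  expect_equal(chart_state(inst), "A")
  expect_true(any(tr$to_state == "(discarded)"))
})

test_that("events with no matching transition are dropped without a state change", {
  sch <- new_scheduler()
  inst <- chart_instance(sch, chart_def(
    "G", c("A", "B"), "A",
    transitions = list(transition("A", "go", "B"))), "g")
  post_event(sch, "g", "unrelated", delay_ms = 1)
  run_until(sch, 5)
  expect_equal(chart_state(inst), "A")
})

test_that("leaving a state cancels its pending timeout", {
  sch <- new_scheduler()
  fired <- new.env(); fired$n <- 0L
  inst <- chart_instance(sch, chart_def(
    "T", c("A", "B"), "A",
    transitions = list(
      transition("A", "go", "B"),
      transition("A", tm_trigger("A"), "B",
                 actions = function(sch, inst, ev) fired$n <- fired$n + 1L)),
    timeouts = list(A = function(i) 10)), "t")
  post_event(sch, "t", "go", delay_ms = 2)  # leaves A before the 10 ms timeout
  run_until(sch, 50)
  expect_equal(chart_state(inst), "B")
  expect_equal(fired$n, 0L)
})

test_that("exactly one leaf state is active after every dispatch", {
  sch <- new_scheduler()
  inst <- chart_instance(sch, chart_def(
    "Blinker", c("On", "Off"), "On",
    transitions = list(
      transition("On", tm_trigger("On"), "Off"),
      transition("Off", tm_trigger("Off"), "On")),
    timeouts = list(On = function(i) 3, Off = function(i) 5)), "b")
  for (k in 1:40) {
    dispatch(sch)
    expect_true(chart_state(inst) %in% c("On", "Off"))
    expect_length(chart_state(inst), 1)
  }
})

test_that("actions run to completion: events posted by an action dispatch later", {
  sch <- new_scheduler()
  order <- new.env(); order$log <- character()
  register_component(sch, "probe", function(sch, comp, ev) {
    order$log <- c(order$log, "probe")
  })
  chart_instance(sch, chart_def(
    "R", c("A", "B"), "A",
    transitions = list(
      transition("A", "go", "B", actions = function(sch, inst, ev) {
        post_event(sch, "probe", "ping", delay_ms = 0)
        order$log <- c(order$log, "action")
      }))), "r")
  post_event(sch, "r", "go", delay_ms = 1)
  run_until(sch, 5)
  expect_identical(order$log, c("action", "probe"))
})

test_that("internal transitions fire actions without re-entering the state", {
  sch <- new_scheduler()
  hits <- new.env(); hits$n <- 0L; hits$timeouts <- 0L
  inst <- chart_instance(sch, chart_def(
    "I", c("A", "B"), "A",
    transitions = list(
      transition("A", "poke", actions = function(sch, inst, ev) {
        hits$n <- hits$n + 1L
      }),
      transition("A", tm_trigger("A"), "B",
                 actions = function(sch, inst, ev) {
                   hits$timeouts <- hits$timeouts + 1L
                 })),
    timeouts = list(A = function(i) 10)), "i")
  post_event(sch, "i", "poke", delay_ms = 2)
  post_event(sch, "i", "poke", delay_ms = 4)
  run_until(sch, 20)
  expect_equal(hits$n, 2L)
  # pokes must not have re-armed A's timeout: it fires once, at 10 ms
  expect_equal(hits$timeouts, 1L)
  expect_equal(chart_state(inst), "B")
})

test_that("CPG alternation has the closed-form period and burst count", {
  # period = cyclesNum * cycleDuration + silenceDuration, independent oracle
  p <- whisk_params(list(
    "cpg.Int.cycles_num" = 10, "cpg.Int.silence_ms" = 50,
    "cpg.cycle_duration_ms" = 5))
  sch <- new_scheduler()
  got <- new.env(); got$t <- numeric()
  register_component(sch, "mn_probe", function(sch, comp, ev) {
    got$t <- c(got$t, sch$clock / 1000)
  })
  whiskloop:::make_cpg(sch, "Int", p, targets = "mn_probe", w = 1,
                       offset_ms = 0)
  run_until(sch, 350)
  period_ms <- 10 * 5 + 50
  # bursts come in volleys of cyclesNum, one volley per period
  expect_equal(sum(got$t < period_ms), 10)
  expect_equal(sum(got$t < 3 * period_ms), 30)
  # successive volleys are exactly one period apart
  expect_equal(got$t[11] - got$t[1], period_ms)
  expect_equal(got$t[21] - got$t[11], period_ms)
})

test_that("the CPG resets currentCycle when re-entering Activate", {
  p <- whisk_params(list("cpg.Int.cycles_num" = 4, "cpg.Int.silence_ms" = 20))
  sch <- new_scheduler()
  register_component(sch, "mn_probe", function(sch, comp, ev) NULL)
  inst <- whiskloop:::make_cpg(sch, "Int", p, targets = "mn_probe", w = 1,
                               offset_ms = 0)
  run_until(sch, 41)  # inside the second Activate phase
  expect_equal(chart_state(inst), "Activate")
  expect_lt(inst$params$current_cycle, 4)
})
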