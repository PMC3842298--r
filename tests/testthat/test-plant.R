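# Muscle calcium/force dynamics and the rigid-whisker plant.

test_that("muscle force is zero at rest, continuous at threshold, bounded", {
  expect_equal(muscle_force(0, 1, 0.5, 6), 0)
  expect_equal(muscle_force(0.99, 1, 0.5, 6), 0)
  expect_equal(muscle_force(1, 1, 0.5, 6), 0)        # A(Ca_0) = 0: continuity
  expect_lt(abs(muscle_force(1e9, 1, 0.5, 6) - 6), 1e-6)  # saturation
  expect_true(all(diff(muscle_force(seq(1, 5, 0.1), 1, 0.5, 6)) > 0))
})

muscle_harness <- function(p = whisk_params(), type = "intrinsic") {
  sch <- new_scheduler()
  net <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 1))
  ms <- whiskloop:::new_muscle_store(net)
  j <- which(net$muscles$type == type)[1]
  wdef <- whiskloop:::whisker_chart_def()
  chart_instance(sch, wdef, "wh_probe")
  inst <- chart_instance(sch, muscle_chart_def(), "m_test", params = list(
    j = j, store = ms, whisker_charts = "wh_probe"))
  list(sch = sch, ms = ms, j = j, inst = inst)
}

test_that("a single sub-threshold stimulus leaves the muscle at rest, no move event", {
  h <- muscle_harness()
  inc <- h$ms$ca0[h$j] * 0.5
  post_event(h$sch, "m_test", "stim", delay_ms = 1,
             payload = list(inc = inc))
  tr <- run_until(h$sch, 10)
  expect_equal(chart_state(h$inst), "Rest")
  expect_false(any(tr$event == "move"))
})

test_that("steady stimulation reaches the geometric-series calcium plateau", {
  # closed-form oracle: jumps J every D ms with decay rho = exp(-D/tau)
  # give plateau J * (1 - rho^k) / (1 - rho) just after the k-th stimulus
  h <- muscle_harness()
  J <- 1.0; D <- 5
  for (k in 0:19) {
    post_event(h$sch, "m_test", "stim", delay_ms = 1 + k * D,
               payload = list(inc = J))
  }
  run_until(h$sch, 1 + 19 * D + 0.01)
  rho <- exp(-D / h$ms$tau[h$j])
  expected <- J * (1 - rho^20) / (1 - rho)
  expect_equal(h$ms$ca[h$j], expected, tolerance = 1e-6)
  expect_equal(chart_state(h$inst), "Contract")
})

test_that("the muscle relaxes when calcium decays below threshold, and move events fire", {
  h <- muscle_harness()
  inc <- h$ms$ca0[h$j] * 2
  post_event(h$sch, "m_test", "stim", delay_ms = 1, payload = list(inc = inc))
  tr <- run_until(h$sch, 200)
  expect_equal(chart_state(h$inst), "Rest")
  # Contract entry notified the whisker chart
  expect_true(any(tr$component == "wh_probe" & tr$event == "move"))
  # relaxation happened at the predicted crossing time tau*log(Ca/Ca0)
  t_relax <- tr$t_ms[tr$component == "m_test" &
                       tr$to_state == "Rest" & tr$from_state == "Contract"]
  expect_equal(t_relax, 1 + h$ms$tau[h$j] * log(2), tolerance = 0.01)
})

test_that("constant torque drives the whisker to the analytic fixed point", {
  p <- whisk_params()
  pl <- new.env()
  pl$theta <- p$plant$theta_rest; pl$omega <- 0
  pl$theta_rest <- p$plant$theta_rest
  pl$inertia <- p$plant$inertia; pl$damping <- p$plant$damping
  pl$stiffness <- p$plant$stiffness
  A <- 5.5
  for (k in 1:400) {
    st <- whiskloop:::plant_step_core(pl, A, 0.5)
    pl$theta <- st$theta; pl$omega <- st$omega
  }
  expect_equal(pl$theta, p$plant$theta_rest + A / p$plant$stiffness,
               tolerance = 1e-3)
  expect_equal(pl$omega, 0, tolerance = 1e-4)
})

test_that("with silent muscles every whisker converges to rest from random states", {
  p <- whisk_params()
  withr::with_seed(42, {
    for (rep in 1:5) {
      pl <- new.env()
      pl$theta <- runif(29, 50, 95); pl$omega <- runif(29, -1, 1)
      pl$theta_rest <- p$plant$theta_rest
      pl$inertia <- p$plant$inertia; pl$damping <- p$plant$damping
      pl$stiffness <- p$plant$stiffness
      for (k in 1:600) {
        st <- whiskloop:::plant_step_core(pl, 0, 0.5)
        pl$theta <- st$theta; pl$omega <- st$omega
      }
      expect_true(all(abs(pl$theta - p$plant$theta_rest) < 0.01))
      expect_true(all(abs(pl$omega) < 0.001))
    }
  })
})

test_that("contact episodes pair onsets and offsets with the detach tolerance", {
  obs <- obstacle("A4", 74.7, 0.4)
  t <- seq(0, 300, by = 0.5)
  # no obstacle: empty
  expect_equal(nrow(contact_events(
    tibble::tibble(t_ms = t, theta = 70 + 5 * sin(t / 20)), NULL)), 0)
  # single protraction past the pole then full retraction: one episode
  th <- 70 + 8 * sin(pi * t / 300)
  ep <- contact_events(tibble::tibble(t_ms = t, theta = th), obs)
  expect_equal(nrow(ep), 1)
  expect_false(is.na(ep$offset_ms))
  # a pump smaller than the tolerance keeps contact (no offset)
  th2 <- rep(76, length(t))
  th2[t > 100 & t < 120] <- 74  # 2 deg dip, within eps of 74.7
  th2[t < 50] <- 70
  ep2 <- contact_events(tibble::tibble(t_ms = t, theta = th2), obs)
  expect_equal(nrow(ep2), 1)
  expect_true(is.na(ep2$offset_ms))
})

test_that("free-air whisking amplitude sits in the calibrated band", {
  sim <- free_air_sim()
  cyc <- segment_cycles(sim$trajectories[sim$trajectories$whisker == "C2", ])
  amp <- mean(cyc$amplitude)
  expect_gt(amp, 8)
  expect_lt(amp, 12.5)
})
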