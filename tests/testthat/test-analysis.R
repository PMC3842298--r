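# Cycle segmentation, pump detection, spread classification and the exact
# binomial test.

test_that("a pure 8 Hz sinusoid segments into symmetric 125 ms cycles", {
  t <- seq(0, 1000, by = 0.5)
  tr <- tibble::tibble(t_ms = t, theta = 75 + 5 * sin(2 * pi * 8 * t / 1000))
  cyc <- segment_cycles(tr)
  expect_gt(nrow(cyc), 4)
  expect_equal(mean(cyc$duration_ms), 125, tolerance = 0.02)
  expect_equal(mean(cyc$protraction_ms), 62.5, tolerance = 0.04)
  expect_equal(mean(cyc$retraction_ms), 62.5, tolerance = 0.04)
  expect_equal(mean(cyc$set_point), 75, tolerance = 0.01)
})

test_that("asymmetric fixture cycles are recovered with their exact durations", {
  fx <- generate_whisk_fixture(whiskers = "C1", n_cycles = 5,
                               period_ms = 150, protraction_ms = 80)
  cyc <- segment_cycles(fx$trajectories)
  expect_gte(nrow(cyc), 3)  # interior cycles are complete
  expect_equal(mean(cyc$duration_ms), 150, tolerance = 0.02)
  expect_equal(mean(cyc$protraction_ms), 80, tolerance = 0.04)
  expect_equal(mean(cyc$retraction_ms), 70, tolerance = 0.04)
  expect_equal(mean(cyc$amplitude), 10, tolerance = 0.05)
})

test_that("a flat trace yields no cycles", {
  tr <- tibble::tibble(t_ms = seq(0, 500, 0.5), theta = 70)
  expect_equal(nrow(segment_cycles(tr)), 0)
})

test_that("an injected pump is recovered with its delay and amplitude", {
  fx <- generate_whisk_fixture(
    whiskers = c("C1", "C2"), touching = "C2",
    pumps = data.frame(whisker = "C2", cycle = 2, delay_ms = 17,
                       amplitude = 0.6),
    n_cycles = 4)
  tips <- detect_tips(fx$trajectories, fx$contacts)
  hit <- tips[tips$whisker == "C2" & tips$episode == 2, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$delay_ms, 17, tolerance = 0.1)      # within ~1 sample
  expect_equal(hit$amplitude, 0.6, tolerance = 0.25)   # filtered estimate
  # the untouched whisker and pump-free cycles carry no events
  expect_equal(sum(tips$whisker == "C1"), 0)
  expect_equal(sum(tips$whisker == "C2" & tips$episode != 2), 0)
})

test_that("a noiseless pump-free fixture yields no detections", {
  fx <- generate_whisk_fixture(whiskers = paste0("C", 1:3), touching = "C2",
                               n_cycles = 3)
  expect_equal(nrow(detect_tips(fx$trajectories, fx$contacts)), 0)
})

test_that("pump recovery rate is at least 95% across noisy seeded fixtures", {
  hits <- vapply(1:100, function(s) {
    fx <- generate_whisk_fixture(
      whiskers = "C2", touching = "C2",
      pumps = data.frame(whisker = "C2", cycle = 2, delay_ms = 17,
                         amplitude = 1.0),
      n_cycles = 3, noise_sd = 0.1, seed = s)
    tips <- detect_tips(fx$trajectories, fx$contacts, whisker = "C2")
    any(tips$episode == 2 & abs(tips$delay_ms - 17) < 5 &
          abs(tips$amplitude - 1.0) < 0.5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pumps outside a protraction phase are rejected by the generator", {
  expect_error(generate_whisk_fixture(
    whiskers = "C1", touching = "C1",
    pumps = data.frame(whisker = "C1", cycle = 1, delay_ms = 60,
                       amplitude = 1)), "protraction")
})

test_that("every detected pump lies inside its contact episode's window", {
  sim <- tip_sim("E_R")
  tips <- detect_tips(sim$trajectories, sim$contacts)
  expect_gt(nrow(tips), 0)
  for (k in seq_len(nrow(tips))) {
    on <- sim$contacts$onset_ms[tips$episode[k]]
    expect_gte(tips$onset_ms[k], on)
    expect_lte(tips$onset_ms[k], on + 45)
    expect_gte(tips$delay_ms[k], 0)
  }
})

test_that("pump spread classification names the three spatial patterns", {
  lay <- pad_layout()
  mk <- function(wh) tibble::tibble(whisker = wh, episode = 1L)
  expect_equal(tip_spread(mk(c("C2", "C3", "C4")), "C3")$identity,
               "touching_plus_neighbors")
  expect_equal(tip_spread(mk(lay$whisker), "C3")$identity, "all_ipsilateral")
  expect_equal(tip_spread(mk(character(0)), "C3")$identity, "none")
  expect_equal(tip_spread(mk(c("C3", "E1")), "C3")$identity, "other")
  # edge whisker: only the caudal neighbour exists
  expect_equal(tip_spread(mk(c("A3", "A4")), "A4")$identity,
               "touching_plus_neighbors")
  expect_error(tip_spread(mk("C2"), "Z9"), "unknown")
})

test_that("slowed-but-not-pumping whiskers are reported separately", {
  fx <- generate_whisk_fixture(whiskers = c("C1", "C2"), touching = "C2",
                               n_cycles = 3)
  sl <- detect_slowdowns(fx$trajectories, fx$contacts)
  expect_true(all(c("whisker", "episode", "slowed") %in% names(sl)))
  # the clamped touching whisker stalls after contact: a velocity drop
  expect_true(all(sl$slowed[sl$whisker == "C2"]))
})

test_that("exact binomial tail matches published example and single-trial case", {
  expect_equal(binom_test_exact(2, 61, 0.07, "lower"), 0.19, tolerance = 0.01)
  expect_equal(binom_test_exact(1, 1, 0.5, "upper"), 0.5)
  expect_error(binom_test_exact(-1, 5, 0.5), "0 <= k")
  expect_error(binom_test_exact(2, 5, 1.2), "between 0 and 1")
  expect_error(detect_tips(tibble::tibble(), tibble::tibble(onset_ms = 1),
                           delta_tip = 0), "delta_tip")
})

test_that("binomial tails equal the exhaustive enumeration oracle", {
  # independent oracle: enumerate all 2^n outcomes
  enum_tail <- function(k, n, p0, tail) {
    outcomes <- expand.grid(rep(list(0:1), n))
    ks <- rowSums(outcomes)
    pr <- p0^ks * (1 - p0)^(n - ks)
    if (tail == "lower") sum(pr[ks <= k]) else sum(pr[ks >= k])
  }
  for (n in c(5, 9, 12)) {
    for (p0 in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      for (k in c(0, 1, n %/% 2, n)) {
        expect_equal(binom_test_exact(k, n, p0, "lower"),
                     enum_tail(k, n, p0, "lower"), tolerance = 1e-12)
        expect_equal(binom_test_exact(k, n, p0, "upper"),
                     enum_tail(k, n, p0, "upper"), tolerance = 1e-12)
      }
    }
  }
  # and against the base-R distribution function on a larger case
  expect_equal(binom_test_exact(7, 40, 0.2, "lower"), pbinom(7, 40, 0.2))
})
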