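# Kinematic analysis of whisker-angle traces: zero-phase low-pass filtering,
# whisk-cycle segmentation at retraction minima, detection and
# characterisation of touch-induced pumps (TIPs), classification of which
# whiskers pump, and the exact binomial occurrence test.

#' Zero-phase low-pass filter for whisker traces
#'
#' Fourth-order Butterworth applied forward and backward
#' (`signal::filtfilt`), matching the smoothing used on tracked-whisker data
#' before kinematic analysis.
#'
#' @param theta numeric trace, uniformly sampled.
#' @param dt_ms sample interval in ms.
#' @param cutoff_hz cutoff frequency (rat traces are typically filtered at
#'   40-80 Hz).
#' @return filtered trace, same length.
#' @export
lowpass_trace <- function(theta, dt_ms, cutoff_hz = 40) {
  if (length(theta) < 12) return(theta)
  fs <- 1000 / dt_ms
  wc <- min(cutoff_hz / (fs / 2), 0.99)
  bf <- signal::butter(2, wc)
  as.numeric(signal::filtfilt(bf, theta))
}

infer_dt <- function(t_ms) {
  dt <- stats::median(diff(sort(unique(t_ms))))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling step", call. = FALSE)
  dt
}

# Alternating extrema of a trace with small oscillations pruned: returns a
# data frame (idx, type) with strict max/min alternation, dropping any
# adjacent extrema pair whose angular span is below min_amp.
alternating_extrema <- function(z, min_amp) {
  dz <- diff(z)
  s <- sign(dz)
  # carry the previous sign through flat stretches
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  turns <- which(diff(s) != 0) + 1L
  if (!length(turns)) return(data.frame(idx = integer(), type = character()))
  type <- ifelse(s[turns] < s[turns - 1L], "max", "min")
  idx <- turns
  repeat {
    if (length(idx) < 2) break
    spans <- abs(z[idx[-1]] - z[idx[-length(idx)]])
    bad <- which(spans < min_amp)
    if (!length(bad)) break
    drop <- bad[which.min(spans[bad])]
    keep <- setdiff(seq_along(idx), c(drop, drop + 1L))
    idx <- idx[keep]; type <- type[keep]
    # merge same-type neighbours, keeping the more extreme one
    j <- 1L
    while (j < length(idx)) {
      if (type[j] == type[j + 1L]) {
        pick <- if (type[j] == "max") {
          if (z[idx[j]] >= z[idx[j + 1L]]) j else j + 1L
        } else {
          if (z[idx[j]] <= z[idx[j + 1L]]) j else j + 1L
        }
        rm_i <- if (pick == j) j + 1L else j
        idx <- idx[-rm_i]; type <- type[-rm_i]
      } else j <- j + 1L
    }
  }
  data.frame(idx = idx, type = type)
}

#' Segment a whisker trace into whisk cycles
#'
#' Cycles are delimited at retraction minima of the low-pass-filtered trace:
#' protraction runs trough to peak, retraction peak to trough. Oscillations
#' smaller than `min_amplitude` (e.g. sub-degree pumps and numerical ripple)
#' do not split cycles.
#'
#' @param trace data frame with `t_ms` and `theta`; a `whisker` column may
#'   hold several whiskers, which are segmented independently.
#' @param cutoff_hz low-pass cutoff before segmentation.
#' @param min_amplitude minimum peak-to-trough span of a genuine cycle, deg.
#' @return tibble with one row per complete cycle: `whisker` (if present),
#'   `start_ms`, `peak_ms`, `end_ms`, `duration_ms`, `protraction_ms`,
#'   `retraction_ms`, `amplitude` (trough-to-peak, deg) and `set_point`
#'   (cycle-mean angle, deg). A flat trace gives zero rows.
#' @export
segment_cycles <- function(trace, cutoff_hz = 40, min_amplitude = 3) {
  if (!all(c("t_ms", "theta") %in% names(trace))) {
    stop("trace needs t_ms and theta columns", call. = FALSE)
  }
  groups <- if ("whisker" %in% names(trace)) {
    split(trace, trace$whisker)
  } else list(trace)
  out <- purrr::map_dfr(groups, function(tr) {
    tr <- tr[order(tr$t_ms), ]
    if (nrow(tr) < 16 || diff(range(tr$theta)) < min_amplitude) {
      return(tibble::tibble())
    }
    dt <- infer_dt(tr$t_ms)
    z <- lowpass_trace(tr$theta, dt, cutoff_hz)
    ext <- alternating_extrema(z, min_amplitude)
    mins <- ext$idx[ext$type == "min"]
    res <- list()
    for (k in seq_len(length(mins) - 1)) {
      i0 <- mins[k]; i1 <- mins[k + 1]
      between <- ext$idx[ext$type == "max" & ext$idx > i0 & ext$idx < i1]
      if (length(between) != 1) next
      ip <- between
      res[[length(res) + 1L]] <- tibble::tibble(
        whisker = if ("whisker" %in% names(tr)) tr$whisker[1] else NA_character_,
        start_ms = tr$t_ms[i0], peak_ms = tr$t_ms[ip], end_ms = tr$t_ms[i1],
        duration_ms = tr$t_ms[i1] - tr$t_ms[i0],
        protraction_ms = tr$t_ms[ip] - tr$t_ms[i0],
        retraction_ms = tr$t_ms[i1] - tr$t_ms[ip],
        amplitude = z[ip] - z[i0],
        set_point = mean(z[i0:i1])
      )
    }
    dplyr::bind_rows(res)
  })
  out
}

#' Detect touch-induced pumps
#'
#' Scans each whisker's (filtered) trace after every contact onset for a
#' local protraction maximum followed, within `w_max_ms`, by a retraction of
#' at least `delta_tip` degrees and a subsequent re-protraction - the pump
#' signature - all before the cycle's terminal retraction (enforced by the
#' pump window and the re-protraction requirement). The pump onset is the
#' end of the pre-drop plateau, so the touching whisker's delay is measured
#' from contact onset to the start of its retraction.
#'
#' @param trace trajectory data frame (`t_ms`, `whisker`, `theta`), any
#'   number of whiskers.
#' @param contacts contact episodes of the touching whisker
#'   (`onset_ms`, `offset_ms`), e.g. a `whisk_sim$contacts` table.
#' @param whisker optional subset of whisker ids to scan.
#' @param delta_tip minimum pump retraction, degrees (> 0).
#' @param w_max_ms pump search window after contact onset, ms.
#' @param drop_max_ms maximum onset-to-trough duration of a pump, ms.
#' @param min_rate_deg_ms minimum peak retraction velocity inside the drop,
#'   deg/ms: pumps are brisk; slow free-air sags are not counted.
#' @param reprot_min minimum re-protraction rise after the pump trough, deg.
#' @param reprot_window_ms how soon after the trough the rise must appear.
#' @param cutoff_hz low-pass cutoff before detection.
#' @return tibble of pump events: `whisker`, `episode` (contact index, a
#'   cycle counter for per-cycle contacts), `onset_ms`, `trough_ms`,
#'   `delay_ms` (onset minus contact onset), `amplitude` (peak-to-trough,
#'   deg), `first_in_cycle`, `contact_maintained` (for the touching whisker:
#'   did contact persist through the pump).
#' @export
detect_tips <- function(trace, contacts, whisker = NULL, delta_tip = 0.3,
                        w_max_ms = 45, drop_max_ms = 35, min_rate_deg_ms = 0.08,
                        reprot_min = 0.1,
                        reprot_window_ms = 25, cutoff_hz = 80) {
  if (delta_tip <= 0) stop("delta_tip must be > 0", call. = FALSE)
  if (!nrow(contacts)) {
    return(tibble::tibble(whisker = character(), episode = integer(),
                          onset_ms = numeric(), trough_ms = numeric(),
                          delay_ms = numeric(), amplitude = numeric(),
                          first_in_cycle = logical(),
                          contact_maintained = logical()))
  }
  wids <- whisker %||% unique(trace$whisker)
  out <- list()
  for (w in wids) {
    tr <- trace[trace$whisker == w, ]
    tr <- tr[order(tr$t_ms), ]
    if (nrow(tr) < 16) next
    dt <- infer_dt(tr$t_ms)
    z <- lowpass_trace(tr$theta, dt, cutoff_hz)
    for (e in seq_len(nrow(contacts))) {
      t_on <- contacts$onset_ms[e]
      t_off <- contacts$offset_ms[e]
      i0 <- which(tr$t_ms >= t_on)[1]
      if (is.na(i0)) next
      # a pump cannot be judged if its search or re-protraction window is
      # truncated by the end of the record (filter edge effects, unfinished
      # re-protraction)
      if (i0 + round((w_max_ms + reprot_window_ms + 5) / dt) > length(z)) next
      i1 <- i0 + round(w_max_ms / dt)
      ev <- scan_pumps(z, tr$t_ms, i0, i1, delta_tip, reprot_min,
                       round(reprot_window_ms / dt))
      if (nrow(ev)) {
        dur <- ev$trough_ms - ev$onset_ms
        ev <- ev[dur <= drop_max_ms & ev$peak_rate >= min_rate_deg_ms, ]
      }
      if (!nrow(ev)) next
      ev$whisker <- w
      ev$episode <- e
      ev$delay_ms <- ev$onset_ms - t_on
      ev$first_in_cycle <- seq_len(nrow(ev)) == 1L
      ev$contact_maintained <- if (!is.null(t_off)) {
        is.na(t_off) | ev$trough_ms < t_off
      } else NA
      out[[length(out) + 1L]] <- ev
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble::tibble(whisker = character(), episode = integer(),
                          onset_ms = numeric(), trough_ms = numeric(),
                          delay_ms = numeric(), amplitude = numeric(),
                          first_in_cycle = logical(),
                          contact_maintained = logical()))
  }
  res[, c("whisker", "episode", "onset_ms", "trough_ms", "delay_ms",
          "amplitude", "first_in_cycle", "contact_maintained")]
}

# Single forward scan for pump signatures between indices i0..i1:
# a drop of >= delta from the running maximum, then a rise of >= reprot
# within reprot_n samples of the running minimum. The pump onset is the
# last sample still within a small band of the pre-drop maximum, so slow
# ripple on a contact plateau does not pull the onset forward.
scan_pumps <- function(z, t, i0, i1, delta, reprot, reprot_n) {
  events <- list()
  i <- i0
  run_max <- z[i]; run_max_i <- i
  while (i < i1) {
    i <- i + 1L
    if (z[i] > run_max) { run_max <- z[i]; run_max_i <- i }
    if (run_max - z[i] >= delta) {
      # inside a candidate drop: find its trough, then check re-protraction
      j <- i
      min_v <- z[i]; min_i <- i
      while (j < min(i1 + reprot_n, length(z))) {
        j <- j + 1L
        if (z[j] < min_v) { min_v <- z[j]; min_i <- j }
        if (z[j] - min_v >= reprot) break
        if (j - min_i > reprot_n) break
      }
      if (j <= length(z) && z[j] - min_v >= reprot) {
        # onset: walking back from the trough, the last sample still within
        # a small band of the pre-drop maximum (start of the pump
        # retraction; tolerant of sub-0.1 deg ripple on a contact plateau)
        onset_i <- min_i
        while (onset_i > run_max_i && z[onset_i] < run_max - 0.1) {
          onset_i <- onset_i - 1L
        }
        span <- onset_i:min_i
        peak_rate <- if (length(span) > 2) {
          dtt <- t[2] - t[1]
          max(-diff(z[span], lag = 2) / (2 * dtt))
        } else 0
        events[[length(events) + 1L]] <- tibble::tibble(
          onset_ms = t[onset_i], trough_ms = t[min_i],
          amplitude = run_max - min_v, peak_rate = peak_rate)
        i <- j
        run_max <- z[i]; run_max_i <- i
      } else {
        break  # drop without re-protraction: terminal retraction
      }
    }
  }
  dplyr::bind_rows(events)
}

#' Classify which whiskers pump after a single-whisker contact
#'
#' Summarises, per contact episode, the set of whiskers with a detected
#' pump, and names it: the touching whisker plus its in-row neighbours
#' (the direct intrinsic-inhibition signature), all ipsilateral whiskers
#' (the retractor-excitation and CPG-inhibition signature), none, or other.
#'
#' @param tips pump table from [detect_tips()] over all whiskers.
#' @param touching the touching whisker id.
#' @param layout pad layout, by default [pad_layout()].
#' @return tibble per episode: `episode`, `n_pumping`, `identity`
#'   (`"touching_plus_neighbors"`, `"all_ipsilateral"`, `"none"` or
#'   `"other"`), and `whiskers` (list column).
#' @export
tip_spread <- function(tips, touching, layout = pad_layout()) {
  all_w <- layout$whisker
  lt <- layout[layout$whisker == touching, ]
  if (!nrow(lt)) stop("unknown touching whisker: ", touching, call. = FALSE)
  neigh <- layout$whisker[layout$row == lt$row & abs(layout$arc - lt$arc) == 1]
  expected_neigh <- sort(c(touching, neigh))
  eps <- sort(unique(tips$episode))
  if (!length(eps)) {
    return(tibble::tibble(episode = 1L, n_pumping = 0L, identity = "none",
                          whiskers = list(character())))
  }
  purrr::map_dfr(eps, function(e) {
    set <- sort(unique(tips$whisker[tips$episode == e]))
    identity <- if (!length(set)) "none"
      else if (setequal(set, all_w)) "all_ipsilateral"
      else if (setequal(set, expected_neigh)) "touching_plus_neighbors"
      else "other"
    tibble::tibble(episode = e, n_pumping = length(set), identity = identity,
                   whiskers = list(set))
  })
}

#' Whiskers that slow down without a detectable pump
#'
#' Companion classification to [detect_tips()]: whiskers whose protraction
#' velocity drops by at least `drop_frac` after contact onset without a
#' retraction of `delta_tip` degrees are reported as "slowed", the
#' intermediate response class seen in tracked rats.
#'
#' @inheritParams detect_tips
#' @param drop_frac minimum fractional velocity drop.
#' @return tibble: `whisker`, `episode`, `v_before`, `v_after` (deg/ms),
#'   `slowed`.
#' @export
detect_slowdowns <- function(trace, contacts, whisker = NULL,
                             delta_tip = 0.3, drop_frac = 0.5,
                             window_ms = 15, cutoff_hz = 80) {
  wids <- whisker %||% unique(trace$whisker)
  tips <- detect_tips(trace, contacts, whisker = wids, delta_tip = delta_tip,
                      cutoff_hz = cutoff_hz)
  out <- list()
  for (w in wids) {
    tr <- trace[trace$whisker == w, ]
    tr <- tr[order(tr$t_ms), ]
    if (nrow(tr) < 16) next
    dt <- infer_dt(tr$t_ms)
    z <- lowpass_trace(tr$theta, dt, cutoff_hz)
    nwin <- round(window_ms / dt)
    for (e in seq_len(nrow(contacts))) {
      if (any(tips$whisker == w & tips$episode == e)) next
      t_on <- contacts$onset_ms[e]
      i <- which(tr$t_ms >= t_on)[1]
      if (is.na(i) || i - nwin < 1 || i + 2 * nwin > length(z)) next
      v_before <- (z[i] - z[i - nwin]) / (nwin * dt)
      v_after <- (z[min(i + 2 * nwin, length(z))] - z[i + nwin]) / (nwin * dt)
      if (v_before <= 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        whisker = w, episode = e, v_before = v_before, v_after = v_after,
        slowed = v_after <= (1 - drop_frac) * v_before)
    }
  }
  dplyr::bind_rows(out)
}

#' Exact binomial tail test
#'
#' Exact tail sums of the binomial pmf, as used for pump-occurrence
#' comparisons (e.g. 2 pumps in 61 touches against a 7% spontaneous rate
#' gives a lower-tail p of about 0.19).
#'
#' @param k observed successes, `0 <= k <= n`.
#' @param n number of trials.
#' @param p0 null success probability, in (0, 1).
#' @param tail `"lower"` (P[X <= k]), `"upper"` (P[X >= k]), or `"two"`
#'   (sum of outcome probabilities no larger than the observed one).
#' @return the exact p-value.
#' @export
binom_test_exact <- function(k, n, p0, tail = c("lower", "upper", "two")) {
  tail <- match.arg(tail)
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1 || length(n) != 1 ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    stop("need integers 0 <= k <= n", call. = FALSE)
  }
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly between 0 and 1", call. = FALSE)
  }
  switch(tail,
    lower = sum(stats::dbinom(0:k, n, p0)),
    upper = sum(stats::dbinom(k:n, n, p0)),
    two = {
      pk <- stats::dbinom(k, n, p0)
      probs <- stats::dbinom(0:n, n, p0)
      sum(probs[probs <= pk * (1 + 1e-7)])
    })
}
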