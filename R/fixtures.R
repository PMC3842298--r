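# Synthetic tracked-whisker traces with ground truth: smooth asymmetric
# whisk cycles, optional per-cycle contact plateaus, injected pumps of known
# delay and amplitude, and additive noise. Stands in for video-tracked
# whisker data when exercising the cycle segmentation and pump detection.

#' Generate synthetic whisker traces with known pumps
#'
#' Each whisker sweeps `n_cycles` smooth whisk cycles (half-cosine
#' protraction of `protraction_ms`, half-cosine retraction of
#' `retraction_ms`) between `theta_min` and `theta_min + amplitude`.
#' Touching whiskers are clamped at the contact angle from contact onset
#' until the cycle peak time (the contact plateau of a whisker pressed
#' against a pole). Pumps are injected as a fast drop (one third of
#' `pump_dur_ms`) followed by a slower recovery, starting `delay_ms` after
#' the cycle's contact onset; ground truth is returned alongside.
#'
#' @param whiskers character vector of whisker ids.
#' @param touching subset of `whiskers` that contact the pole (their cycles
#'   carry a contact plateau; contact onsets are shared by all whiskers, as
#'   with a single pole in the whisking field).
#' @param pumps tibble/data.frame with columns `whisker`, `cycle`,
#'   `delay_ms`, `amplitude`; or `NULL` for none.
#' @param n_cycles number of whisk cycles.
#' @param period_ms,protraction_ms cycle period and protraction duration
#'   (retraction is the difference).
#' @param amplitude cycle amplitude in degrees.
#' @param theta_min retraction trough angle, degrees.
#' @param contact_frac where in the protraction the contact angle sits
#'   (fraction of the amplitude).
#' @param pump_dur_ms total pump duration (drop + recovery).
#' @param noise_sd additive white noise SD, degrees.
#' @param dt_ms sampling step.
#' @param seed RNG seed for the noise.
#' @return list with `trajectories` (tibble `t_ms`, `whisker`, `theta`),
#'   `contacts` (tibble `onset_ms`, `offset_ms`), and `truth` (tibble
#'   `whisker`, `cycle`, `onset_ms`, `delay_ms`, `amplitude`).
#' @export
generate_whisk_fixture <- function(whiskers = paste0("C", 1:4),
                                   touching = character(),
                                   pumps = NULL,
                                   n_cycles = 4,
                                   period_ms = 150,
                                   protraction_ms = 80,
                                   amplitude = 10,
                                   theta_min = 68.5,
                                   contact_frac = 0.6,
                                   pump_dur_ms = 15,
                                   noise_sd = 0,
                                   dt_ms = 0.5,
                                   seed = 1L) {
  retraction_ms <- period_ms - protraction_ms
  stopifnot(retraction_ms > 0, amplitude > 0, n_cycles >= 1)
  if (!all(touching %in% whiskers)) {
    stop("touching whiskers must be listed in whiskers", call. = FALSE)
  }
  tt <- seq(0, n_cycles * period_ms, by = dt_ms)
  phase <- tt %% period_ms
  cycle_of <- pmin(floor(tt / period_ms) + 1L, n_cycles)
  base <- ifelse(
    phase <= protraction_ms,
    theta_min + amplitude * (1 - cos(pi * phase / protraction_ms)) / 2,
    theta_min + amplitude *
      (1 + cos(pi * (phase - protraction_ms) / retraction_ms)) / 2
  )
  theta_c <- theta_min + contact_frac * amplitude
  # contact onset within each cycle: when the rising base crosses theta_c
  t_on_phase <- protraction_ms * acos(1 - 2 * contact_frac) / pi
  contacts <- tibble::tibble(
    onset_ms = (seq_len(n_cycles) - 1) * period_ms + t_on_phase,
    offset_ms = (seq_len(n_cycles) - 1) * period_ms + protraction_ms +
      0.4 * retraction_ms
  )
  if (!is.null(pumps)) {
    pumps <- tibble::as_tibble(pumps)
    need <- c("whisker", "cycle", "delay_ms", "amplitude")
    if (!all(need %in% names(pumps))) {
      stop("pumps needs columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    bad <- pumps$delay_ms < 0 |
      (t_on_phase + pumps$delay_ms + pump_dur_ms) > protraction_ms
    if (any(bad)) {
      stop("pump outside a protraction phase (cycle ",
           paste(pumps$cycle[bad], collapse = ", "), ")", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    traj <- purrr::map_dfr(whiskers, function(w) {
      th <- base
      if (w %in% touching) {
        # clamp at the contact angle until the peak time of each cycle
        plateau <- phase >= t_on_phase & phase <= protraction_ms
        th[plateau] <- theta_c
      }
      if (!is.null(pumps)) {
        pw <- pumps[pumps$whisker == w, ]
        for (q in seq_len(nrow(pw))) {
          t0 <- contacts$onset_ms[pw$cycle[q]] + pw$delay_ms[q]
          drop_ms <- pump_dur_ms / 3
          rel <- tt - t0
          dip <- numeric(length(tt))
          in_drop <- rel >= 0 & rel < drop_ms
          in_rec <- rel >= drop_ms & rel <= pump_dur_ms
          dip[in_drop] <- pw$amplitude[q] *
            (1 - cos(pi * rel[in_drop] / drop_ms)) / 2
          dip[in_rec] <- pw$amplitude[q] *
            (1 + cos(pi * (rel[in_rec] - drop_ms) /
                       (pump_dur_ms - drop_ms))) / 2
          th <- th - dip
        }
      }
      if (noise_sd > 0) th <- th + stats::rnorm(length(th), 0, noise_sd)
      tibble::tibble(t_ms = tt, whisker = w, theta = th)
    })
  })
  truth <- if (is.null(pumps)) {
    tibble::tibble(whisker = character(), cycle = integer(),
                   onset_ms = numeric(), delay_ms = numeric(),
                   amplitude = numeric())
  } else {
    tibble::tibble(whisker = pumps$whisker, cycle = as.integer(pumps$cycle),
                   onset_ms = contacts$onset_ms[pumps$cycle] + pumps$delay_ms,
                   delay_ms = pumps$delay_ms, amplitude = pumps$amplitude)
  }
  list(trajectories = traj, contacts = contacts, truth = truth)
}
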