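# Broom-style summaries and ggplot2 graphics for simulation results.

#' Tidy a simulation into per-cycle kinematics
#'
#' One row per whisker per complete whisk cycle, from [segment_cycles()].
#'
#' @param x a `whisk_sim`.
#' @param cutoff_hz low-pass cutoff before segmentation.
#' @param ... unused.
#' @return tibble: `whisker`, `start_ms`, `peak_ms`, `end_ms`,
#'   `duration_ms`, `protraction_ms`, `retraction_ms`, `amplitude`,
#'   `set_point`, and `peak_theta` (cycle maximum angle).
#' @method tidy whisk_sim
#' @export
tidy.whisk_sim <- function(x, cutoff_hz = 40, ...) {
  cyc <- segment_cycles(x$trajectories, cutoff_hz = cutoff_hz)
  if (!nrow(cyc)) return(cyc)
  peaks <- purrr::map_dbl(seq_len(nrow(cyc)), function(i) {
    tr <- x$trajectories
    sel <- tr$whisker == cyc$whisker[i] & tr$t_ms >= cyc$start_ms[i] &
      tr$t_ms <= cyc$end_ms[i]
    max(tr$theta[sel])
  })
  cyc$peak_theta <- peaks
  cyc
}

#' One-row summary of a simulation
#'
#' @param x a `whisk_sim`.
#' @param ... unused.
#' @return tibble with mean cycle kinematics, spike and event counts.
#' @method glance whisk_sim
#' @export
glance.whisk_sim <- function(x, ...) {
  cyc <- segment_cycles(x$trajectories)
  tibble::tibble(
    whisking_mechanism = x$meta$configuration$whisking_mechanism,
    tip_mechanism = x$meta$configuration$tip_mechanism,
    duration_ms = x$meta$duration_ms,
    n_whiskers = length(unique(x$trajectories$whisker)),
    n_cycles = if (nrow(cyc)) nrow(cyc) / max(length(unique(cyc$whisker)), 1)
      else 0,
    cycle_ms = if (nrow(cyc)) mean(cyc$duration_ms) else NA_real_,
    protraction_ms = if (nrow(cyc)) mean(cyc$protraction_ms) else NA_real_,
    retraction_ms = if (nrow(cyc)) mean(cyc$retraction_ms) else NA_real_,
    amplitude = if (nrow(cyc)) mean(cyc$amplitude) else NA_real_,
    n_spikes = nrow(x$spikes),
    n_contacts = nrow(x$contacts),
    n_events = x$meta$n_events
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot whisker trajectories
#'
#' Angle against time for a selection of whiskers, with contact spans
#' shaded.
#'
#' @param object a `whisk_sim`.
#' @param whiskers whisker ids to show (default: the touching whisker's row,
#'   or row C in free air).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot whisk_sim
#' @export
autoplot.whisk_sim <- function(object, whiskers = NULL, ...) {
  tr <- object$trajectories
  if (is.null(whiskers)) {
    rw <- if (!is.null(object$meta$obstacle)) {
      substr(object$meta$obstacle$whisker, 1, 1)
    } else "C"
    whiskers <- unique(tr$whisker[tr$row == rw])
  }
  tr <- tr[tr$whisker %in% whiskers, ]
  gg <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$t_ms, y = .data$theta,
                                         colour = .data$whisker)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (ms)", y = "azimuth (deg)",
                  colour = "whisker") +
    ggplot2::theme_minimal()
  if (nrow(object$contacts)) {
    shade <- object$contacts
    shade$offset_ms[is.na(shade$offset_ms)] <- max(tr$t_ms)
    gg <- gg + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$onset_ms, xmax = .data$offset_ms),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "grey40",
      inherit.aes = FALSE)
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot detected pumps on their traces
#'
#' @param sim a `whisk_sim` run against an obstacle.
#' @param tips pump table from [detect_tips()]; computed if missing.
#' @param whiskers whiskers to display.
#' @return a ggplot with pump onsets and troughs marked.
#' @export
plot_tips <- function(sim, tips = NULL, whiskers = NULL) {
  if (is.null(tips)) tips <- detect_tips(sim$trajectories, sim$contacts)
  gg <- autoplot.whisk_sim(sim, whiskers = whiskers)
  if (nrow(tips)) {
    if (!is.null(whiskers)) tips <- tips[tips$whisker %in% whiskers, ]
    tr <- sim$trajectories
    pts <- dplyr::left_join(
      tips, tr, by = dplyr::join_by("whisker", "trough_ms" == "t_ms"))
    gg <- gg + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$trough_ms, y = .data$theta),
      shape = 25, size = 1.8, fill = "black", inherit.aes = FALSE)
  }
  gg
}
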