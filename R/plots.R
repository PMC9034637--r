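#' Render a lattice snapshot
#'
#' Draws the cortex as oriented segments in the conventional colours:
#' green for G-actin, blue for crosslinkers, red for myosin.  Reservoir
#' occupancy is shown as a caption.
#'
#' @param state A [cortex_state()].
#' @param segment Half-length of a monomer segment in lattice units.
#' @return A ggplot object.
#' @export
plot_frame <- function(state, segment = 0.38) {
  slots <- slot_table(state)
  p <- ggplot2::ggplot() +
    ggplot2::coord_fixed(xlim = c(0.5, state$width + 0.5),
                         ylim = c(0.5, state$height + 0.5), expand = FALSE) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      caption = sprintf("reservoir: actin %g, AC %g, myosin %g (iteration %g)",
                        state$reservoir[1], state$reservoir[2],
                        state$reservoir[3], state$iteration))
  if (nrow(slots) > 0) {
    st <- ori_step(slots$orientation)
    seg <- tibble::tibble(
      x = slots$x - st[, "dx"] * segment, y = slots$y - st[, "dy"] * segment,
      xend = slots$x + st[, "dx"] * segment,
      yend = slots$y + st[, "dy"] * segment)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "forestgreen", linewidth = 0.7,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.05, "inches")))
  }
  edge_df <- function(links) {
    if (nrow(links) == 0) return(NULL)
    # draw at the edge midpoint, shortest-image on periodic lattices
    dx <- links$xb - links$xa; dy <- links$yb - links$ya
    if (state$periodic) {
      dx <- ifelse(dx > 1, dx - state$width, ifelse(dx < -1, dx + state$width, dx))
      dy <- ifelse(dy > 1, dy - state$height, ifelse(dy < -1, dy + state$height, dy))
    }
    tibble::tibble(x = links$xa + dx / 2, y = links$ya + dy / 2)
  }
  ac <- edge_df(state$acs)
  if (!is.null(ac)) {
    p <- p + ggplot2::geom_point(data = ac,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 colour = "blue", shape = 15, size = 1.6)
  }
  my <- edge_df(state$myosins)
  if (!is.null(my)) {
    p <- p + ggplot2::geom_point(data = my,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 colour = "red", shape = 17, size = 1.8)
  }
  p
}

#' Plot the simulation time courses
#'
#' Facetted time series of the cortical counts, occupancy, tension and
#' network statistics.
#'
#' @param object A `cortex_sim`.
#' @param vars Trajectory columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cortex_sim <- function(object,
                                vars = c("n_actin_cortex", "n_ac",
                                         "n_myosin", "n_filaments",
                                         "n_networks", "tension_RT"),
                                ...) {
  tr <- object$trajectory
  vars <- intersect(vars, names(tr))
  long <- tidyr::pivot_longer(tr[, c("time_min", vars)],
                              cols = -"time_min",
                              names_to = "observable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the Fourier power spectrum of a trajectory series
#'
#' @param trajectory A trajectory tibble or `cortex_sim`.
#' @param var Column to analyse.
#' @param discard_fraction Initial fraction dropped as transient.
#' @return A ggplot object with the dominant period annotated.
#' @export
plot_spectrum <- function(trajectory, var = "n_actin_cortex",
                          discard_fraction = 0.15) {
  tr <- if (inherits(trajectory, "cortex_sim")) trajectory$trajectory
        else trajectory
  tr <- tr[tr$time_min >= discard_fraction * max(tr$time_min), ]
  osc <- oscillation_period(tr[[var]], dt = diff(tr$time_min)[1])
  ggplot2::ggplot(osc$spectrum,
                  ggplot2::aes(x = .data$frequency_per_min, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (1/min)", y = "power",
                  subtitle = sprintf("dominant period %.2f min (peak/median %.1f)",
                                     osc$period_min, osc$peak_ratio)) +
    ggplot2::theme_bw()
}
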