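#' Parameter sweeps
#'
#' Runs a grid of simulations over one or more parameter axes and
#' returns a tidy results table suitable for phase-diagram style
#' summaries (occupancy, mean filament length, network size as functions
#' of potentials and link energies).
#'
#' Axes address parameters with the [update_params()] naming scheme,
#' e.g. `E_link1` (actin membrane energy E1), `mu0_1`, `N0_2`, `W3`.
#' Replicate seeds are derived from the master seed by a fixed counter
#' scheme (`seed + 1000 * replicate + cell index`), so a sweep is fully
#' reproducible.
#'
#' @param params Base [cortex_params()].
#' @param axes Named list of value vectors, e.g.
#'   `list(E_link1 = c(3, 4, 5), mu0_1 = c(-3, -2))`.
#' @param n_iterations Iterations per run.
#' @param replicates Runs per grid cell.
#' @param seed Master seed.
#' @param summarise Function mapping a `cortex_sim` to a one-row data
#'   frame; defaults to [glance()] plus oscillation diagnostics when the
#'   trajectory is long enough.
#' @param discard_fraction Initial fraction of each trajectory dropped
#'   before summarising.
#' @return A tibble with one row per (cell, replicate): the axis values,
#'   `replicate`, `seed`, and the summary columns.
#' @export
sweep_cortex <- function(params, axes, n_iterations, replicates = 1,
                         seed = 1, summarise = NULL,
                         discard_fraction = 0.5) {
  if (!is.list(axes) || length(axes) == 0 || is.null(names(axes)) ||
      !all(nzchar(names(axes)))) {
    stop("at least one named sweep axis is required")
  }
  if (any(vapply(axes, length, integer(1)) == 0)) {
    stop("every sweep axis needs at least one value")
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (is.null(summarise)) {
    summarise <- function(sim) {
      g <- glance(sim)
      tr <- sim$trajectory
      keep <- tr$time_min >= discard_fraction * max(tr$time_min)
      g$mean_filament_length <- {
        sel <- tr$n_filaments[keep] > 0
        if (any(sel)) mean(tr$n_actin_filaments[keep][sel] /
                             tr$n_filaments[keep][sel]) else NA_real_
      }
      g$sd_filament_length <- NA_real_
      fl <- find_filaments(sim$state)
      if (nrow(fl) > 1) g$sd_filament_length <- stats::sd(fl$length)
      g$mean_largest_network <- mean(tr$largest_network[keep])
      g$mean_second_network <- mean(tr$second_network[keep])
      g$mean_network_size <- {
        sel <- tr$n_networks[keep] > 0
        if (any(sel)) mean(tr$largest_network[keep][sel]) else 0
      }
      g
    }
  }
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    p <- params
    for (ax in names(axes)) {
      p <- do.call(update_params, c(list(p), stats::setNames(
        list(grid[[ax]][cell]), ax)))
    }
    for (rep in seq_len(replicates)) {
      run_seed <- seed + 1000L * rep + cell
      sim <- simulate_cortex(p, n_iterations, seed = run_seed)
      out <- summarise(sim)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::as_tibble(grid[cell, , drop = FALSE]),
        tibble::tibble(replicate = rep, seed = run_seed),
        tibble::as_tibble(out))
    }
  }
  dplyr::bind_rows(rows)
}
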