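#' Run the cortex Monte Carlo simulation
#'
#' Executes the Metropolis sampling loop: each iteration draws one
#' lattice position and evaluates, in the fixed order actin, crosslinker,
#' myosin, an insertion (if the relevant slot or edge is free and
#' eligible) or a removal (if occupied), followed by the tension rule
#' (threshold detachment with load redistribution).  Molecule totals are
#' conserved against the finite reservoir throughout.
#'
#' One *sweep-unit* is `2 * width * height` iterations (the slot
#' capacity of the lattice); the time axis of the trajectory is
#' `iterations / (2 * width * height) * kappa` minutes (see
#' [calibrate_kappa()]).
#'
#' Runs are reproducible: the same `seed`, parameters and initial state
#' give identical trajectories.
#'
#' @param params A [cortex_params()] object.
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Optional integer seed (`set.seed()` is called when
#'   supplied).
#' @param record_every Trajectory recording stride in iterations;
#'   defaults to one sweep-unit.
#' @param snapshot_every Full-state snapshot stride in iterations
#'   (0 = no snapshots).
#' @param state Optional initial [cortex_state()]; defaults to an empty
#'   lattice with all molecules in the reservoir.
#' @return An object of class `cortex_sim` with components
#'   `trajectory` (tibble, one row per recording stride), `events`
#'   (tibble of detachment cascades), `snapshots` (list of
#'   `cortex_state`, possibly empty), `state` (final state), `params`,
#'   and `seed`.
#' @examples
#' sim <- simulate_cortex(cortex_preset("fig1", width = 10, height = 10),
#'                        n_iterations = 2e4, seed = 1)
#' tidy(sim)
#' @export
simulate_cortex <- function(params, n_iterations, seed = NULL,
                            record_every = NULL, snapshot_every = 0,
                            state = NULL) {
  stopifnot(inherits(params, "cortex_params"), n_iterations >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_every)) record_every <- 2L * params$width * params$height
  if (is.null(state)) state <- cortex_state(params)
  stopifnot(inherits(state, "cortex_state"),
            state$width == params$width, state$height == params$height)
  out <- cpp_run(unclass(state), unclass(params), n_iterations,
                 as.integer(record_every), as.integer(snapshot_every))
  traj <- tibble::as_tibble(as.data.frame(out$trajectory))
  names(traj) <- c("iteration", "time_min", "n_actin_cortex",
                   "n_actin_filaments", "n_free_monomers", "n_ac",
                   "n_myosin", "n_filaments", "occupancy_pct",
                   "n_networks", "largest_network", "second_network",
                   "tension_RT")
  ev <- tibble::as_tibble(as.data.frame(out$events))
  names(ev) <- c("iteration", "n_detached", "monomers_released",
                 "load_redistributed", "load_discarded")
  ev$time_min <- ev$iteration / (2 * params$width * params$height) *
    params$kappa
  snaps <- list()
  if (!is.null(out$snapshots)) {
    snaps <- lapply(out$snapshots, as_cortex_state)
  }
  structure(list(trajectory = traj, events = ev, snapshots = snaps,
                 state = as_cortex_state(out$state), params = params,
                 n_iterations = n_iterations, seed = seed),
            class = "cortex_sim")
}

#' Advance a state by a single Monte Carlo iteration
#'
#' @param state A [cortex_state()].
#' @param params A [cortex_params()].
#' @return The updated `cortex_state`.
#' @export
mc_step <- function(state, params) {
  out <- cpp_run(unclass(state), unclass(params), 1, 1L, 0L)
  as_cortex_state(out$state)
}

#' @export
print.cortex_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<cortex_sim> %g iterations (%.1f sweep-units, %.1f min) on a %dx%d lattice\n",
              x$n_iterations,
              x$n_iterations / (2 * x$params$width * x$params$height),
              max(tr$time_min, 0), x$params$width, x$params$height))
  if (nrow(tr) > 0) {
    last <- tr[nrow(tr), ]
    cat(sprintf("  final: %d monomers (%.1f%% occupancy), %d filaments, %d ACs, %d myosins, tension %.2f RT\n",
                last$n_actin_cortex, last$occupancy_pct, last$n_filaments,
                last$n_ac, last$n_myosin, last$tension_RT))
  }
  cat(sprintf("  %d detachment cascade(s) recorded; %d snapshot(s)\n",
              nrow(x$events), length(x$snapshots)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the simulation trajectory
#'
#' @param x A `cortex_sim`.
#' @param ... Unused.
#' @return The trajectory tibble (one row per recording stride).
#' @export
tidy.cortex_sim <- function(x, ...) x$trajectory

#' One-row summary of a simulation
#'
#' Means are taken over the final half of the trajectory.
#'
#' @param x A `cortex_sim`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cortex_sim <- function(x, ...) {
  tr <- x$trajectory
  half <- tr[tr$time_min >= max(tr$time_min) / 2, ]
  tibble::tibble(
    n_iterations = x$n_iterations,
    time_span_min = max(tr$time_min) - min(tr$time_min),
    mean_occupancy_pct = mean(half$occupancy_pct),
    mean_n_filaments = mean(half$n_filaments),
    mean_n_actin_cortex = mean(half$n_actin_cortex),
    mean_free_monomers = mean(half$n_free_monomers),
    mean_tension_RT = mean(half$tension_RT),
    n_detachment_events = sum(x$events$n_detached),
    final_occupancy_pct = tr$occupancy_pct[nrow(tr)]
  )
}
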