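#' Map Monte Carlo iterations to physical time
#'
#' The simulation clock advances by one sweep-unit every
#' `2 * width * height` iterations (each node holds two monomer slots),
#' and the calibration factor `kappa` converts sweep-units to minutes:
#' `time_min = it / (2 * area) * kappa`.
#'
#' @param it Iteration count (>= 0).
#' @param area Number of lattice nodes (`width * height`).
#' @param kappa Minutes per sweep-unit.
#' @return Time in minutes.
#' @examples
#' time_from_iterations(5000, area = 2500, kappa = 1) # 1 sweep-unit = 1 min
#' @export
time_from_iterations <- function(it, area, kappa = 1) {
  stopifnot(all(it >= 0), area > 0, kappa > 0)
  it / (2 * area) * kappa
}

#' Detect the equilibration point of a series
#'
#' The plateau level is the mean of the (smoothed) series over its final
#' 20%; the equilibration point is the first time from which the
#' smoothed series stays within `tol` of the plateau continuously for at
#' least `persist` of the run.
#'
#' @param time Time axis (any monotone unit).
#' @param x The observable series.
#' @param tol Relative tolerance around the plateau (default 5%).
#' @param persist Fraction of the run the series must remain inside the
#'   band (default 20%).
#' @param smooth_window Moving-average window used before detection;
#'   defaults to 1/50 of the series length.
#' @return The equilibration time, or `NA` if the series never settles.
#' @export
detect_equilibration <- function(time, x, tol = 0.05, persist = 0.2,
                                 smooth_window = NULL) {
  stopifnot(length(time) == length(x), length(x) >= 10)
  if (is.null(smooth_window)) smooth_window <- max(3, length(x) %/% 50)
  xs <- smooth_series(x, smooth_window)
  plateau <- mean(xs[time >= min(time) + 0.8 * (max(time) - min(time))])
  if (!is.finite(plateau) || plateau == 0) return(NA_real_)
  inside <- abs(xs - plateau) <= tol * abs(plateau)
  need <- persist * (max(time) - min(time))
  run_end <- time[length(time)]
  for (i in seq_along(time)) {
    if (!inside[i]) next
    j <- which(time >= time[i] + need)
    j <- if (length(j) == 0) length(time) else j[1]
    if (all(inside[i:j])) return(time[i])
  }
  NA_real_
}

#' Calibrate the sweep-unit to minutes conversion
#'
#' Runs the actin-only reference condition (by default the `"fig1"`
#' preset), detects the equilibration point of the cortex occupancy in
#' sweep-units with [detect_equilibration()], and sets `kappa` so that
#' this point maps to the in-vivo reference equilibration time of 18
#' minutes.  The detected point is averaged over several seeds.
#'
#' @param params A [cortex_params()] for an actin-only configuration;
#'   its `kappa` is ignored during the calibration runs.
#' @param seeds Integer seeds to average over (at least 3 recommended).
#' @param n_iterations Length of each calibration run.
#' @param reference_min The reference equilibration time in minutes.
#' @param observable Trajectory column used for detection.
#' @param tol,persist Passed to [detect_equilibration()].
#' @return A list with `kappa` (minutes per sweep-unit),
#'   `equilibration_su` (per-seed plateau times in sweep-units), and
#'   `reference_min`.
#' @examples
#' \donttest{
#' cal <- calibrate_kappa(cortex_preset("fig1"), seeds = 1:3,
#'                        n_iterations = 1e6)
#' cal$kappa
#' }
#' @export
calibrate_kappa <- function(params, seeds = 1:3, n_iterations = 1.5e6,
                            reference_min = 18,
                            observable = "occupancy_pct",
                            tol = 0.05, persist = 0.2) {
  stopifnot(inherits(params, "cortex_params"))
  if (params$N0[2] > 0 || params$N0[3] > 0) {
    stop("calibration requires an actin-only configuration")
  }
  run_params <- update_params(params, kappa = 1)
  eq <- vapply(seeds, function(s) {
    sim <- simulate_cortex(run_params, n_iterations, seed = s)
    tr <- sim$trajectory
    detect_equilibration(tr$time_min, tr[[observable]], tol = tol,
                         persist = persist)
  }, numeric(1))
  if (all(is.na(eq))) {
    stop("no equilibration plateau detected on any seed; cannot calibrate")
  }
  list(kappa = reference_min / mean(eq, na.rm = TRUE),
       equilibration_su = eq,
       reference_min = reference_min)
}
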