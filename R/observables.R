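#' Cortex occupancy
#'
#' Percentage of monomer slots occupied: each node accommodates one
#' vertical and one horizontal monomer, so the denominator is
#' `2 * width * height`.
#'
#' @param state A [cortex_state()].
#' @return Occupancy in percent, in `[0, 100]`.
#' @export
occupancy <- function(state) {
  100 * (sum(state$vert_ori > 0) + sum(state$horiz_ori > 0)) /
    (2 * state$width * state$height)
}

#' Size distribution of chains
#'
#' Normalized histogram of chain sizes in monomer units.  With
#' `weighted = TRUE` each size class is weighted by the monomers it
#' contains (the fraction of cortical actin held in chains of that
#' size).
#'
#' @param x A [cortex_state()], or an integer vector of chain lengths.
#' @param weighted Weight classes by monomer count.
#' @param min_length Smallest chain length to include (1 includes free
#'   monomers and oligomers; 3 restricts to filaments).
#' @return A tibble with columns `size`, `count`, `prob`.
#' @export
size_distribution <- function(x, weighted = FALSE, min_length = 1) {
  lengths <- if (inherits(x, "cortex_state")) find_chains(x)$length else x
  lengths <- lengths[lengths >= min_length]
  if (length(lengths) == 0) {
    return(tibble::tibble(size = integer(), count = integer(),
                          prob = numeric()))
  }
  tab <- table(lengths)
  out <- tibble::tibble(size = as.integer(names(tab)),
                        count = as.integer(tab))
  w <- if (weighted) out$count * out$size else out$count
  out$prob <- w / sum(w)
  out
}

#' Second-order moving-average smoothing
#'
#' Applies a centred moving average twice.  The window shrinks at the
#' series edges so the output has the same length as the input;
#' `window = 1` is the identity.
#'
#' @param x Numeric series.
#' @param window Window width in samples (`>= 1`).
#' @return The smoothed series.
#' @export
smooth_series <- function(x, window) {
  stopifnot(window >= 1)
  ma <- function(v) {
    h <- window %/% 2
    if (h == 0) return(v)
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(1, seq_len(n) - h)
    hi <- pmin(n, seq_len(n) + h)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  ma(ma(x))
}

#' Oscillation period by Fourier analysis
#'
#' Removes the mean, computes the discrete Fourier power spectrum, and
#' returns the period of the strongest non-zero-frequency component
#' together with its ratio to the median spectral power (a flat spectrum
#' gives a ratio near 1; a clear periodicity gives a large ratio).
#'
#' @param series Uniformly sampled numeric series (length >= 8).
#' @param dt Sampling interval in minutes.
#' @return A list with `period_min`, `peak_ratio`, and the spectrum as a
#'   tibble (`frequency_per_min`, `power`).
#' @examples
#' t <- seq(0, 63) * 0.1
#' oscillation_period(sin(2 * pi * t / 6.4), dt = 0.1)$period_min # 6.4
#' @export
oscillation_period <- function(series, dt) {
  if (length(series) < 8) stop("series must contain at least 8 samples")
  stopifnot(dt > 0)
  x <- series - mean(series)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  spec <- tibble::tibble(frequency_per_min = (half - 1) / (n * dt),
                         power = p[half])
  peak <- which.max(spec$power)
  med <- stats::median(spec$power)
  ratio <- if (stats::var(series) == 0) 1
           else if (med > 0) spec$power[peak] / med else Inf
  list(period_min = 1 / spec$frequency_per_min[peak],
       peak_ratio = ratio,
       spectrum = spec)
}

#' Track filaments across snapshots and measure treadmilling velocity
#'
#' Filament identity between consecutive snapshots is assigned by
#' maximal overlap of occupied positions among filaments of the same
#' orientation, ties broken by pointed-end proximity.  Centroid
#' displacements are computed with minimum-image convention on periodic
#' lattices.
#'
#' `treadmilling_velocity()` summarises each track's mean speed in
#' lattice units per minute.
#'
#' @param sim A `cortex_sim` run with `snapshot_every > 0`, or a list of
#'   [cortex_state()] snapshots.
#' @param dt_min Time between snapshots in minutes (derived from the sim
#'   when omitted).
#' @return `track_filaments()`: a tibble with one row per filament per
#'   snapshot (`snapshot`, `time_min`, `track`, `orientation`, `length`,
#'   `cx`, `cy`, `dx`, `dy`).  `treadmilling_velocity()`: one row per
#'   track with `n_obs`, `mean_length`, `mean_speed` (lattice units per
#'   minute) and `net_displacement`.
#' @export
track_filaments <- function(sim, dt_min = NULL) {
  snaps <- if (inherits(sim, "cortex_sim")) sim$snapshots else sim
  if (length(snaps) < 2) stop("need at least two snapshots to track filaments")
  if (is.null(dt_min)) {
    if (inherits(sim, "cortex_sim")) {
      its <- vapply(snaps, function(s) s$iteration, numeric(1))
      dt_min <- diff(its)[1] / (2 * sim$params$width * sim$params$height) *
        sim$params$kappa
    } else {
      dt_min <- 1
    }
  }
  W <- snaps[[1]]$width; H <- snaps[[1]]$height
  periodic <- snaps[[1]]$periodic
  cells_of <- function(state, fil) {
    code <- ori_code(fil$orientation)
    x <- fil$x_pointed; y <- fil$y_pointed
    out <- matrix(0L, fil$length, 2)
    for (k in seq_len(fil$length)) {
      out[k, ] <- c(x, y)
      if (k < fil$length) {
        nxt <- step_pos(state, x, y, code)
        x <- nxt["x"]; y <- nxt["y"]
      }
    }
    out
  }
  wrap_delta <- function(d, L) {
    if (!periodic) return(d)
    ((d + L / 2) %% L) - L / 2
  }
  centroid <- function(cells, code) {
    # unwrap along the filament axis from the pointed end
    n <- nrow(cells)
    dx <- wrap_delta(cells[, 1] - cells[1, 1], W)
    dy <- wrap_delta(cells[, 2] - cells[1, 2], H)
    c(cells[1, 1] + mean(dx), cells[1, 2] + mean(dy))
  }
  rows <- list()
  next_track <- 0L
  prev <- NULL
  for (s in seq_along(snaps)) {
    st <- snaps[[s]]
    fils <- find_filaments(st)
    cur <- NULL
    if (nrow(fils) > 0) {
      cells <- lapply(seq_len(nrow(fils)), function(i) cells_of(st, fils[i, ]))
      keys <- lapply(cells, function(cc) paste(cc[, 1], cc[, 2]))
      cen <- t(vapply(seq_len(nrow(fils)),
                      function(i) centroid(cells[[i]], ori_code(fils$orientation[i])),
                      numeric(2)))
      track <- integer(nrow(fils))
      if (!is.null(prev)) {
        for (i in seq_len(nrow(fils))) {
          cand <- which(prev$fils$orientation == fils$orientation[i])
          if (length(cand) > 0) {
            ov <- vapply(cand, function(j)
              length(intersect(keys[[i]], prev$keys[[j]])), integer(1))
            best <- which(ov == max(ov) & ov > 0)
            if (length(best) > 1) {
              dpx <- abs(wrap_delta(prev$fils$x_pointed[cand[best]] - fils$x_pointed[i], W)) +
                abs(wrap_delta(prev$fils$y_pointed[cand[best]] - fils$y_pointed[i], H))
              best <- best[which.min(dpx)]
            }
            if (length(best) == 1 && max(ov) > 0) {
              track[i] <- prev$track[cand[best]]
            }
          }
        }
      }
      # avoid two filaments claiming one track: keep the longer
      if (any(duplicated(track[track > 0]))) {
        for (tr in unique(track[duplicated(track) & track > 0])) {
          claim <- which(track == tr)
          keep <- claim[which.max(fils$length[claim])]
          track[setdiff(claim, keep)] <- 0L
        }
      }
      for (i in seq_len(nrow(fils))) {
        if (track[i] == 0L) { next_track <- next_track + 1L; track[i] <- next_track }
      }
      cur <- list(fils = fils, keys = keys, track = track, cen = cen)
      for (i in seq_len(nrow(fils))) {
        d <- c(NA_real_, NA_real_)
        if (!is.null(prev)) {
          j <- match(track[i], prev$track)
          if (!is.na(j)) {
            d <- c(wrap_delta(cen[i, 1] - prev$cen[j, 1], W),
                   wrap_delta(cen[i, 2] - prev$cen[j, 2], H))
          }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          snapshot = s, time_min = (s - 1) * dt_min, track = track[i],
          orientation = fils$orientation[i], length = fils$length[i],
          cx = cen[i, 1], cy = cen[i, 2], dx = d[1], dy = d[2])
      }
    }
    prev <- cur
  }
  if (length(rows) == 0) {
    return(tibble::tibble(snapshot = integer(), time_min = numeric(),
                          track = integer(), orientation = character(),
                          length = integer(), cx = numeric(), cy = numeric(),
                          dx = numeric(), dy = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' @rdname track_filaments
#' @param min_obs Minimum number of observations for a track to be
#'   summarised.
#' @export
treadmilling_velocity <- function(sim, dt_min = NULL, min_obs = 2) {
  tracks <- if (is.data.frame(sim)) sim else track_filaments(sim, dt_min)
  if (nrow(tracks) == 0) {
    return(tibble::tibble(track = integer(), orientation = character(),
                          n_obs = integer(), mean_length = numeric(),
                          mean_speed = numeric(),
                          net_displacement = numeric()))
  }
  dt <- diff(sort(unique(tracks$time_min)))[1]
  tracks |>
    dplyr::group_by(.data$track, .data$orientation) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      mean_length = mean(.data$length),
      mean_speed = mean(sqrt(.data$dx^2 + .data$dy^2), na.rm = TRUE) / dt,
      net_displacement = sqrt(sum(.data$dx, na.rm = TRUE)^2 +
                                sum(.data$dy, na.rm = TRUE)^2),
      .groups = "drop") |>
    dplyr::filter(.data$n_obs >= min_obs)
}

#' Summary analysis of a trajectory
#'
#' Computes the oscillation diagnostics reported for the oscillatory
#' regime: dominant Fourier period and peak significance of the cortical
#' actin series, relative amplitude, and the zero-lag correlation
#' between total tension and the number of networks (negative when the
#' two are in anti-phase).
#'
#' @param trajectory A trajectory tibble (from [simulate_cortex()] /
#'   [tidy()]), or a `cortex_sim`.
#' @param discard_fraction Initial fraction of the series dropped as
#'   transient.
#' @param min_peak_ratio Spectral peak-to-median ratio above which the
#'   series is flagged as oscillating.
#' @return A one-row tibble with `period_min`, `peak_ratio`,
#'   `amplitude_rel`, `tension_network_cor`, `oscillating`.
#' @export
analyze_trajectory <- function(trajectory, discard_fraction = 0.15,
                               min_peak_ratio = 5) {
  tr <- if (inherits(trajectory, "cortex_sim")) trajectory$trajectory else trajectory
  stopifnot(nrow(tr) >= 16)
  tr <- tr[tr$time_min >= discard_fraction * max(tr$time_min), ]
  dt <- diff(tr$time_min)[1]
  x <- tr$n_actin_cortex
  osc <- oscillation_period(x, dt)
  amp <- if (mean(x) > 0) {
    (stats::quantile(x, 0.975) - stats::quantile(x, 0.025)) / mean(x)
  } else 0
  tn_cor <- if (stats::sd(tr$tension_RT) > 0 && stats::sd(tr$n_networks) > 0) {
    stats::cor(tr$tension_RT, tr$n_networks)
  } else NA_real_
  tibble::tibble(period_min = osc$period_min,
                 peak_ratio = osc$peak_ratio,
                 amplitude_rel = unname(amp),
                 tension_network_cor = tn_cor,
                 oscillating = osc$peak_ratio >= min_peak_ratio)
}
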