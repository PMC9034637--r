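test_that("occupancy counts both slots per node", {
  p <- actin_only(W = 2, H = 2, N0 = 10)
  st <- cortex_state(p)
  expect_equal(occupancy(st), 0)
  st <- place_monomer(st, 1, 1, "north")
  st <- place_monomer(st, 1, 1, "east")
  st <- place_monomer(st, 2, 2, "south")
  st <- place_monomer(st, 2, 1, "west")
  expect_equal(occupancy(st), 50)  # 4 of 8 slots
  for (xy in list(c(1, 2), c(2, 1), c(2, 2))) {
    st <- tryCatch(place_monomer(st, xy[1], xy[2], "north"), error = function(e) st)
    st <- tryCatch(place_monomer(st, xy[1], xy[2], "east"), error = function(e) st)
  }
  expect_equal(occupancy(st), 100)
})

test_that("size distributions count and weight chain sizes", {
  d <- size_distribution(c(3L, 3L, 5L))
  expect_equal(d$size, c(3L, 5L))
  expect_equal(d$prob, c(2 / 3, 1 / 3))
  dw <- size_distribution(c(3L, 3L, 5L), weighted = TRUE)
  expect_equal(dw$prob, c(6 / 11, 5 / 11))
  expect_equal(nrow(size_distribution(integer(0))), 0)
})

test_that("the moving-average filter is a second-order low-pass with identity at window 1", {
  x <- rnorm(50)
  expect_equal(smooth_series(x, 1), x)
  const <- rep(4.2, 30)
  expect_equal(smooth_series(const, 7), const)
  alt <- rep(c(1, -1), 50)
  expect_lt(max(abs(smooth_series(alt, 11))), 0.2)
  expect_length(smooth_series(x, 8), length(x))
})

test_that("the Fourier period of a sampled sinusoid is exact to within a bin", {
  t <- seq(0, 255)
  x <- sin(2 * pi * t / 64)
  res <- oscillation_period(x, dt = 0.1)
  expect_equal(res$period_min, 6.4, tolerance = 1e-9)
  expect_gt(res$peak_ratio, 100)
  # a constant series has no significant peak
  resc <- oscillation_period(rep(3, 64), dt = 0.1)
  expect_true(!is.finite(resc$peak_ratio) || resc$peak_ratio < 5 ||
                is.nan(resc$peak_ratio))
  expect_error(oscillation_period(1:5, dt = 1), "at least 8")
  # noisy sinusoid: period recovered within one frequency bin
  set.seed(8)
  xn <- sin(2 * pi * t / 32) + rnorm(length(t), sd = 0.3)
  pn <- oscillation_period(xn, dt = 1)$period_min
  f0 <- 1 / 32
  bin <- 1 / length(t)
  expect_lt(abs(1 / pn - f0), bin + 1e-12)
})

test_that("constructed filament motion yields the constructed treadmilling speed", {
  # a 4-monomer filament moving north one lattice unit per snapshot
  p <- actin_only(W = 6, H = 12, N0 = 50)
  snaps <- lapply(0:5, function(k) {
    st <- cortex_state(p)
    st <- place_run(st, 3, 1 + k, "north", 4)
    st$iteration <- k
    st
  })
  tracks <- track_filaments(snaps, dt_min = 2)
  expect_equal(length(unique(tracks$track)), 1)
  tv <- treadmilling_velocity(tracks)
  expect_equal(tv$mean_speed, 0.5)        # 1 unit / 2 min
  expect_equal(tv$net_displacement, 5)
  # a stationary filament has speed zero
  snaps2 <- lapply(0:3, function(k) {
    st <- cortex_state(p)
    place_run(st, 2, 3, "east", 3)
  })
  tv2 <- treadmilling_velocity(track_filaments(snaps2, dt_min = 1))
  expect_equal(tv2$mean_speed, 0)
  # periodic wrap: motion across the boundary is still one unit per step
  snaps3 <- lapply(0:4, function(k) {
    st <- cortex_state(p)
    y <- (9 + k - 1) %% 12 + 1
    place_run(st, 4, y, "north", 3)
  })
  tv3 <- treadmilling_velocity(track_filaments(snaps3, dt_min = 1))
  expect_equal(tv3$mean_speed, 1)
})

test_that("trajectory analysis flags oscillations and reports anti-phase correlation", {
  t <- seq(0, 400)
  tr <- tibble::tibble(
    time_min = t,
    n_actin_cortex = 500 + 200 * sin(2 * pi * t / 50),
    tension_RT = 100 - 90 * sin(2 * pi * t / 50),
    n_networks = 2 + round(sin(2 * pi * t / 50)))
  a <- analyze_trajectory(tr, discard_fraction = 0)
  expect_true(a$oscillating)
  expect_equal(a$period_min, 50, tolerance = 0.05)
  expect_lt(a$tension_network_cor, -0.9)
  trc <- tibble::tibble(time_min = t, n_actin_cortex = rep(100, length(t)),
                        tension_RT = rep(1, length(t)),
                        n_networks = rep(1L, length(t)))
  expect_false(analyze_trajectory(trc, discard_fraction = 0)$oscillating)
})
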