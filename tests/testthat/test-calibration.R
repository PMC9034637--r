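test_that("iteration-to-time mapping is linear in iterations and inverse in area", {
  expect_equal(time_from_iterations(0, 2500), 0)
  expect_equal(time_from_iterations(5000, 2500, kappa = 1), 1)
  expect_equal(time_from_iterations(5000, 5000, kappa = 1), 0.5)
  expect_equal(time_from_iterations(10000, 2500, kappa = 0.5), 1)
  it <- seq(0, 1e5, by = 1e4)
  expect_true(all(diff(time_from_iterations(it, 625)) > 0))
})

test_that("the plateau detector reads synthetic equilibration times", {
  t <- seq(0, 100, by = 0.5)
  x <- 100 * pmin(1, t / 36)              # plateau entered at t = 36
  eq <- detect_equilibration(t, x, smooth_window = 1)
  expect_equal(eq, 36, tolerance = 0.05)
  # kappa from an 18-minute reference: plateau at 36 sweep-units -> 0.5
  expect_equal(18 / eq, 0.5, tolerance = 0.05)
  x2 <- 100 * pmin(1, t / 18)
  expect_equal(18 / detect_equilibration(t, x2, smooth_window = 1), 1,
               tolerance = 0.05)
  # a monotone non-equilibrating trace is rejected
  expect_true(is.na(detect_equilibration(t, t^1.5, smooth_window = 1)))
  expect_error(calibrate_kappa(three_species()), "actin-only")
})

test_that("presets reproduce the tabulated parameter rows", {
  p1 <- cortex_preset("fig1")
  expect_equal(p1$mu0[1], -5)
  expect_equal(p1$N0[1], 3000)
  expect_equal(p1$gamma[1], 2)
  expect_equal(p1$E_link[1], 4)
  expect_equal(p1$N0[2], 0)               # actin-only row
  expect_equal(p1$E0, 12)
  p5 <- cortex_preset("fig5bcd")
  expect_equal(p5$mu0, c(-3, -5, -5))
  expect_equal(p5$N0, c(5000, 3000, 500))
  expect_equal(p5$gamma, c(1, 1, 1))
  expect_equal(p5$E_link, c(1, 3, 3))
  s4 <- cortex_preset("s4")
  expect_equal(s4$N0, c(2500, 1250, 200))
  expect_equal(s4$E_link[1], 5)
  expect_error(cortex_preset("nonexistent"), "valid presets")
  # overrides pass through
  expect_equal(cortex_preset("fig1", width = 16)$width, 16L)
  # presets are plain values: repeated calls are identical
  expect_identical(cortex_preset("fig4b"), cortex_preset("fig4b"))
})

test_that("config files round-trip the full parameter set", {
  p <- cortex_preset("fig5bcd", W3 = 2e-3, kappa = 0.4, width = 20,
                     height = 18)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(p, path, run = list(n_iterations = 1e5, seed = 7))
  back <- read_config(path)
  expect_equal(back$params, p)
  expect_equal(back$run$seed, 7)
  # a preset name expands to the same schema
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(preset = "fig1"), path2)
  expect_equal(read_config(path2)$params, cortex_preset("fig1"))
})
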