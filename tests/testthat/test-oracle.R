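# exact stationary distributions of miniature systems, solved from the
# enumerated transition matrix, against the sampling kernel's long-run
# state frequencies

test_that("state enumeration matches hand counts", {
  expect_length(enumerate_states(oracle_params(-1, 1, 1)), 5)
  expect_length(enumerate_states(oracle_params(-1, 1, 0)), 1)
  expect_length(enumerate_states(oracle_params(-1, 1, 1, W = 1, H = 2)), 9)
  # 1x1 with N0 = 2: both slots occupied in 2x2 orientation combinations
  expect_length(enumerate_states(oracle_params(-1, 1, 2)), 9)
})

test_that("the stationary vector solves the two-state chains in closed form", {
  # independent slots: occupancy odds are exp(mu + E1)
  for (cfg in list(c(-1, 1), c(-2, 1), c(0, 0))) {
    p <- oracle_params(cfg[1], cfg[2], 2)
    sd <- stationary_distribution(p)
    expect_equal(sum(sd$pi), 1, tolerance = 1e-12)
    expect_true(all(abs(rowSums(sd$transition) - 1) < 1e-12))
    odds <- exp(cfg[1] + cfg[2])
    expect_equal(sd$expected_monomers, 2 * odds / (1 + odds),
                 tolerance = 1e-10)
  }
  # mu = -2, E = 1: slot occupancy e^-1 / (1 + e^-1)
  sd <- stationary_distribution(oracle_params(-2, 1, 2))
  expect_equal(sd$expected_monomers / 2, exp(-1) / (1 + exp(-1)),
               tolerance = 1e-10)
})

test_that("kernel occupancy matches the oracle within three standard errors", {
  settings <- list(
    oracle_params(-1, 1, 1),                      # reservoir-limited slot
    oracle_params(-2, 1, 2),                      # two independent slots
    oracle_params(-1, 0.5, 2, W = 1, H = 2),      # four slots, adjacency
    oracle_params(-1, 1, 3, W = 1, H = 3, E0 = 2),# bonded chains up to 3
    oracle_params(-1, 1, 2, W = 1, H = 2, N2 = 1, ac_any = TRUE)
  )
  for (i in seq_along(settings)) {
    p <- settings[[i]]
    sd <- stationary_distribution(p)
    sim <- simulate_cortex(p, 4e5, seed = 500 + i, record_every = 1L)
    n1 <- sim$trajectory$n_actin_cortex[-seq_len(5e4)]
    se <- batch_se(n1)
    expect_lt(abs(mean(n1) - sd$expected_monomers), 3 * se + 1e-4)
  }
  # crosslinker occupancy is checked on the AC-bearing system as well
  p <- settings[[5]]
  sd <- stationary_distribution(p)
  nac_exp <- sum(sd$pi * vapply(sd$states, function(s) sum(s$ac > 0),
                                numeric(1)))
  sim <- simulate_cortex(p, 4e5, seed = 777, record_every = 1L)
  nac <- sim$trajectory$n_ac[-seq_len(5e4)]
  expect_lt(abs(mean(nac) - nac_exp), 3 * batch_se(nac) + 1e-4)
})

test_that("the stationary distribution is invariant to the shared-position option", {
  # drawing independent positions per species leaves the actin-only
  # chain unchanged
  p <- oracle_params(-1.5, 1, 2, W = 1, H = 2)
  p_ind <- update_params(p, independent_positions = TRUE)
  sd <- stationary_distribution(p)
  sim <- simulate_cortex(p_ind, 3e5, seed = 902, record_every = 1L)
  n1 <- sim$trajectory$n_actin_cortex[-seq_len(4e4)]
  expect_lt(abs(mean(n1) - sd$expected_monomers), 3 * batch_se(n1) + 1e-4)
})
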