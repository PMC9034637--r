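test_that("actin insertion respects blocking, certain acceptance and bonding", {
  p <- actin_only(mu0 = 0, N0 = 50, gamma = 0, E1 = 3, W = 6, H = 6)
  st <- cortex_state(p)
  set.seed(1)
  # mu = 0 gives P+ = 1: certain acceptance
  r <- attempt_actin_insert(st, 3, 3, p, orientation = "north")
  expect_identical(r$result, "accepted")
  # drawing the occupied axis reports blocked
  r2 <- attempt_actin_insert(r$state, 3, 3, p, orientation = "south")
  expect_identical(r2$result, "blocked")
  # perpendicular insertion is allowed
  r3 <- attempt_actin_insert(r$state, 3, 3, p, orientation = "east")
  expect_identical(r3$result, "accepted")
  # insertion in front of a run bonds and extends the filament
  st4 <- cortex_state(p)
  st4 <- place_run(st4, 2, 2, "north", 3)
  r4 <- attempt_actin_insert(st4, 2, 5, p, orientation = "north")
  expect_identical(r4$result, "accepted")
  expect_equal(find_filaments(r4$state)$length, 4)
  # exhausted reservoir blocks insertion
  p0 <- actin_only(mu0 = 5, N0 = 1, gamma = 0, W = 4, H = 4)
  st5 <- place_monomer(cortex_state(p0), 1, 1, "north")
  expect_identical(attempt_actin_insert(st5, 2, 2, p0, "north")$result,
                   "blocked")
})

test_that("actin removal frequencies match the link-energy weights", {
  set.seed(7)
  p <- actin_only(mu0 = -5, N0 = 50, gamma = 0, E1 = 1, W = 6, H = 6)
  trials <- 3000
  # terminal pointed monomer of a filament: P- = exp(-E1)
  st <- place_run(cortex_state(p), 2, 2, "north", 4)
  acc <- mean(replicate(trials, {
    attempt_actin_remove(st, 2, 2, "vertical", p)$result == "accepted"
  }))
  expect_lt(abs(acc - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / trials))
  # free monomer at E1 = 3: P- = exp(-3)
  p3 <- update_params(p, E_link1 = 3)
  stf <- place_monomer(cortex_state(p3), 4, 4, "east")
  accf <- mean(replicate(trials, {
    attempt_actin_remove(stf, 4, 4, "horizontal", p3)$result == "accepted"
  }))
  expect_lt(abs(accf - exp(-3)),
            3 * sqrt(exp(-3) * (1 - exp(-3)) / trials) + 1e-3)
  # interior monomer: forbidden outright by default
  expect_identical(attempt_actin_remove(st, 2, 3, "vertical", p)$result,
                   "rejected")
  # with the suppression made soft, acceptance is exp(-(E0 + E1)), tiny
  psoft <- update_params(p, forbid_interior_removal = FALSE, E0 = 12)
  accs <- replicate(300, attempt_actin_remove(st, 2, 3, "vertical",
                                              psoft)$result)
  expect_false(any(accs == "accepted"))
})

test_that("removing a monomer dissolves its links and returns them to the reservoir", {
  p <- three_species(W = 8, H = 8, N1 = 60, N2 = 10, N3 = 10, E1 = 0)
  st <- cortex_state(p)
  st <- place_run(st, 2, 2, "north", 3)
  st <- place_run(st, 3, 2, "north", 3)
  st <- place_run(st, 4, 4, "south", 3)
  st <- place_crosslinker(st, 2, 2, "vertical", 3, 2, "vertical")
  st <- place_myosin(st, 3, 3, "vertical", 4, 3, "vertical")
  # E1 = 0 and the pointed terminal carries an AC: P- = exp(-E2)
  set.seed(3)
  repeat {
    r <- attempt_actin_remove(st, 2, 2, "vertical", p)
    if (r$result == "accepted") break
  }
  expect_equal(nrow(r$state$acs), 0)
  expect_equal(unname(r$state$reservoir["crosslinker"]), 10)
  expect_true(check_conservation(r$state, p))
  # the myosin elsewhere is untouched
  expect_equal(nrow(r$state$myosins), 1)
})

test_that("crosslinker moves have the printed acceptance weights", {
  set.seed(5)
  p <- three_species(W = 8, H = 8, N1 = 100, N2 = 20, N3 = 0,
                     E2 = 3)
  p <- update_params(p, mu0_2 = log(0.25), gamma_2 = 0)
  st <- cortex_state(p)
  st <- place_run(st, 2, 2, "north", 3)
  st <- place_run(st, 3, 2, "north", 3)
  trials <- 3000
  acc <- mean(replicate(trials, {
    attempt_ac_insert(st, 2, 3, 3, 3, p)$result == "accepted"
  }))
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / trials))
  # ineligible edge is blocked regardless of mu2
  expect_identical(attempt_ac_insert(st, 5, 5, 6, 5, p)$result, "blocked")
  # removal: P- = exp(-2 E2)
  stl <- place_crosslinker(st, 2, 3, "vertical", 3, 3, "vertical")
  accr <- mean(replicate(trials, {
    attempt_ac_remove(stl, 2, 3, 3, 3, p)$result == "accepted"
  }))
  pe <- exp(-6)
  expect_lt(abs(accr - pe), 3 * sqrt(pe * (1 - pe) / trials) + 2e-3)
  # E2 = 0 removes with certainty
  p0 <- update_params(p, E_link2 = 0)
  expect_identical(attempt_ac_remove(stl, 2, 3, 3, 3, p0)$result, "accepted")
  expect_error(attempt_ac_remove(st, 2, 3, 3, 3, p), "carry")
})

test_that("myosin insertion starts the timer and removal banks the load", {
  p <- three_species(W = 8, H = 8, N1 = 100, N2 = 0, N3 = 5,
                     E1 = 2, E3 = 3)
  p <- update_params(p, mu0_3 = 1, gamma_3 = 0, W3 = 0.2, kappa = 1)
  st <- cortex_state(p)
  st <- place_run(st, 2, 2, "north", 4)
  st <- place_run(st, 3, 5, "south", 4)
  st$iteration <- 0
  set.seed(9)
  r <- attempt_myosin_insert(st, 2, 3, 3, 3, p)
  expect_identical(r$result, "accepted")   # mu3 = 1 -> certain
  expect_equal(r$state$myosins$attach_sec, 0)
  # advance the clock ten calibrated seconds and remove the myosin
  st2 <- r$state
  st2$iteration <- 10 / 60 / p$kappa * (2 * p$width * p$height)
  repeat {
    rr <- attempt_myosin_remove(st2, 2, 3, 3, 3, p)
    if (rr$result == "accepted") break
  }
  # each bridged filament banked W3 * t = 0.2 * 10 = 2 RT
  expect_equal(sort(rr$state$loads$accrued), c(2, 2))
  expect_equal(total_tension(rr$state, p), 4)
})
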