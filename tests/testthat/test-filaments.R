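test_that("a filament needs three contiguous bonded monomers", {
  st <- cortex_state(actin_only(W = 6, H = 6, N0 = 50))
  st <- place_run(st, 2, 2, "north", 2)
  expect_equal(nrow(find_filaments(st)), 0)   # a dimer is only an oligomer
  ch <- find_chains(st)
  expect_equal(ch$length, 2)
  st <- place_monomer(st, 2, 4, "north")      # extends the run to three
  fil <- find_filaments(st)
  expect_equal(nrow(fil), 1)
  expect_equal(fil$length, 3)
  expect_equal(c(fil$x_pointed, fil$y_pointed), c(2, 2))
  expect_equal(c(fil$x_barbed, fil$y_barbed), c(2, 4))
})

test_that("perpendicular runs crossing at a node stay distinct filaments", {
  st <- cortex_state(actin_only(W = 7, H = 7, N0 = 50))
  st <- place_run(st, 4, 3, "north", 3)  # occupies (4,3)-(4,5) vertical
  st <- place_run(st, 3, 4, "east", 3)   # occupies (3,4)-(5,4) horizontal
  fil <- find_filaments(st)
  expect_equal(nrow(fil), 2)
  expect_setequal(fil$length, c(3L, 3L))
})

test_that("a monomer in front of a barbed end bonds; behind a pointed end it does not fuse", {
  st <- cortex_state(actin_only(W = 8, H = 8, N0 = 50))
  st <- place_run(st, 2, 2, "north", 3)   # pointed (2,2), barbed (2,4)
  st <- place_monomer(st, 2, 5, "north")  # in front of the barbed end
  fil <- find_filaments(st)
  expect_equal(fil$length, 4)
  # a monomer placed behind the pointed end starts its own chain
  st <- place_monomer(st, 2, 1, "north")
  ch <- find_chains(st)
  expect_setequal(ch$length, c(4L, 1L))
  # two collinear filaments separated by a gap; filling the gap extends
  # the rear filament's barbed end but does not fuse the two
  st2 <- cortex_state(actin_only(W = 10, H = 10, N0 = 50))
  st2 <- place_run(st2, 5, 1, "north", 3)  # barbed at (5,3)
  st2 <- place_run(st2, 5, 5, "north", 3)  # pointed at (5,5)
  st2 <- place_monomer(st2, 5, 4, "north") # gap cell
  ch2 <- find_chains(st2)
  expect_setequal(ch2$length, c(4L, 3L))
})

test_that("monomer link energies itemize membrane, bond, AC and myosin terms", {
  p <- three_species(W = 8, H = 8, N1 = 60, N2 = 10, N3 = 10,
                     E1 = 1, E2 = 3, E3 = 5)
  p$E0 <- 12
  st <- cortex_state(p)
  st <- place_monomer(st, 7, 7, "west")    # isolated monomer
  e <- monomer_link_energy(st, 7, 7, "horizontal", p)
  expect_equal(e$total, 1)                 # membrane link only
  st <- place_run(st, 2, 2, "north", 4)
  # pointed terminal: destabilised bond, membrane only
  expect_equal(monomer_link_energy(st, 2, 2, "vertical", p)$total, 1)
  # interior monomer: E0 + E1
  expect_equal(monomer_link_energy(st, 2, 3, "vertical", p)$total, 13)
  # barbed terminal also carries its bond
  expect_equal(monomer_link_energy(st, 2, 5, "vertical", p)$total, 13)
  # an AC adds E2 on its endpoint monomer
  st <- place_run(st, 3, 2, "north", 4)
  st <- place_crosslinker(st, 2, 3, "vertical", 3, 3, "vertical")
  expect_equal(monomer_link_energy(st, 2, 3, "vertical", p)$total, 16)
  expect_equal(monomer_link_energy(st, 3, 3, "vertical", p)$total, 16)
  # a myosin adds E3 (anti-parallel partner filament)
  st <- place_run(st, 4, 5, "south", 4)    # pointed (4,5) growing south
  st <- place_myosin(st, 3, 4, "vertical", 4, 4, "vertical")
  expect_equal(monomer_link_energy(st, 3, 4, "vertical", p)$total, 18)
  e2 <- monomer_link_energy(st, 3, 4, "vertical", p)
  expect_equal(e2$E_membrane + e2$E_bond + e2$E_ac + e2$E_myosin, e2$total)
  expect_error(monomer_link_energy(st, 1, 1, "vertical", p), "empty")
})

test_that("filament threshold is E1 times current length", {
  expect_equal(filament_threshold(10, 3), 30)
  expect_equal(filament_threshold(0, 3), 0)
  expect_equal(filament_threshold(5, 1), 5)
})

test_that("network detection matches a brute-force union oracle on random states", {
  set.seed(99)
  for (rep in 1:8) {
    p <- three_species(W = 10, H = 10, N1 = 400, N2 = 60, N3 = 60,
                       E1 = 2)
    sim <- simulate_cortex(p, 3e4, seed = 100 + rep)
    st <- sim$state
    nets <- find_networks(st)
    expect_identical(sort(nets$n_monomers, decreasing = TRUE),
                     as.integer(brute_networks(st)))
  }
})

test_that("chained links make one transitive network", {
  p <- three_species(W = 10, H = 10, N1 = 100, N2 = 10, N3 = 10)
  st <- cortex_state(p)
  st <- place_run(st, 2, 2, "north", 3)
  st <- place_run(st, 3, 2, "north", 3)
  st <- place_run(st, 4, 2, "north", 3)
  expect_equal(nrow(find_networks(st)), 0)  # unlinked filaments: no network
  st <- place_crosslinker(st, 2, 3, "vertical", 3, 3, "vertical")
  st1 <- st
  expect_equal(find_networks(st1)$n_filaments, 2)
  st <- place_crosslinker(st, 3, 2, "vertical", 4, 2, "vertical")
  nets <- find_networks(st)
  expect_equal(nets$n_filaments, 3)         # A-B, B-C chains into one
  expect_equal(nets$n_monomers, 9)
})
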