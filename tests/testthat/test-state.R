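test_that("slots are axis-resolved and queries are pure", {
  st <- cortex_state(actin_only(W = 4, H = 4))
  expect_identical(site_state(st, 2, 2, "vertical"), "empty")
  expect_identical(site_state(st, 2, 2, "horizontal"), "empty")
  st <- place_monomer(st, 2, 2, "north")
  occ <- site_state(st, 2, 2, "vertical")
  expect_identical(as.character(occ), "occupied")
  expect_identical(attr(occ, "orientation"), "north")
  # axes are independent: the horizontal slot stays empty
  expect_identical(site_state(st, 2, 2, "horizontal"), "empty")
  # a perpendicular monomer can share the node
  st <- place_monomer(st, 2, 2, "east")
  expect_identical(as.character(site_state(st, 2, 2, "horizontal")), "occupied")
  # same-axis double occupancy is refused
  expect_error(place_monomer(st, 2, 2, "south"), "occupied")
  expect_error(site_state(st, 9, 1, "vertical"), "out of range")
})

test_that("conservation bookkeeping tracks every placement", {
  p <- three_species(W = 5, H = 5, N1 = 30, N2 = 5, N3 = 5)
  st <- cortex_state(p)
  expect_true(check_conservation(st, p))
  st <- place_run(st, 2, 1, "north", 4)
  st <- place_run(st, 3, 1, "north", 3)
  expect_true(check_conservation(st, p))
  expect_equal(unname(st$reservoir["actin"]), 23)
  st <- place_crosslinker(st, 2, 2, "vertical", 3, 2, "vertical")
  expect_true(check_conservation(st, p))
  # a constructed violation is detected
  broken <- st
  broken$vert_ori[2, 1] <- 0L
  expect_false(check_conservation(broken, p))
})

test_that("snapshot serialization round-trips bit-exactly", {
  p <- three_species(W = 6, H = 6, N1 = 40, N2 = 6, N3 = 6)
  st <- cortex_state(p)
  st <- place_run(st, 2, 1, "north", 4)
  st <- place_run(st, 3, 4, "south", 3)   # occupies (3,4)..(3,2)
  st <- place_run(st, 1, 5, "east", 3)
  st <- place_crosslinker(st, 2, 2, "vertical", 3, 2, "vertical")
  st <- place_myosin(st, 2, 3, "vertical", 3, 3, "vertical", attach_sec = 2.5)
  st$loads <- tibble::tibble(ori = 1L, px = 2L, py = 1L, accrued = 0.75)
  st$iteration <- 123
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_snapshots(list(st, st), path)
  back <- read_snapshots(path)
  expect_length(back, 2)
  for (b in back) {
    expect_equal(unclass(b)[sort(names(b))],
                 unclass(st)[sort(names(st))])
  }
})

test_that("kernel states survive the serialization round-trip", {
  p <- three_species(W = 8, H = 8, N1 = 80, N2 = 20, N3 = 20,
                     check_every = 100)
  sim <- simulate_cortex(p, 3e4, seed = 11)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_snapshots(sim$state, path)
  back <- read_snapshots(path)[[1]]
  expect_equal(unclass(back)[sort(names(back))],
               unclass(sim$state)[sort(names(sim$state))])
  # the revived state is a valid kernel input that can be advanced
  expect_error(cortexmc:::cpp_check_state(unclass(back), unclass(p)), NA)
  sim2 <- simulate_cortex(p, 1000, seed = 12, state = back)
  expect_true(check_conservation(sim2$state, p))
})
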