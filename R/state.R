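#' Create an empty cortex lattice state
#'
#' A `cortex_state` holds the full configuration of the system: per-node
#' monomer slots (one vertical, one horizontal, each with orientation,
#' insertion-time stamp and a bonded-behind flag), the crosslinker and
#' myosin edge records, the persisted per-filament loads, and the
#' reservoir counts.  All molecules start in the reservoir.
#'
#' Coordinates are 1-based; `x` runs along width, `y` along height.
#' North points towards increasing `y`, east towards increasing `x`.
#'
#' @param params A [cortex_params()] object; geometry and total molecule
#'   counts are taken from it.
#' @return A list of class `cortex_state`.
#' @export
cortex_state <- function(params) {
  stopifnot(inherits(params, "cortex_params"))
  W <- params$width; H <- params$height
  m <- matrix(0L, W, H)
  structure(list(
    vert_ori = m, vert_time = m, vert_bond = m,
    horiz_ori = m, horiz_time = m, horiz_bond = m,
    acs = empty_links(FALSE),
    myosins = empty_links(TRUE),
    loads = tibble::tibble(ori = integer(), px = integer(), py = integer(),
                           accrued = numeric()),
    reservoir = stats::setNames(params$N0, c("actin", "crosslinker", "myosin")),
    iteration = 0,
    width = W, height = H, periodic = params$periodic
  ), class = "cortex_state")
}

empty_links <- function(myosin) {
  df <- tibble::tibble(xa = integer(), ya = integer(), axa = integer(),
                       xb = integer(), yb = integer(), axb = integer())
  if (myosin) {
    df$attach_sec <- numeric()
    df$active <- integer()
  }
  df
}

# normalize whatever the kernel returned into a cortex_state
as_cortex_state <- function(raw) {
  raw$acs <- tibble::as_tibble(raw$acs)
  raw$myosins <- tibble::as_tibble(raw$myosins)
  raw$loads <- tibble::as_tibble(raw$loads)
  raw$reservoir <- stats::setNames(raw$reservoir,
                                   c("actin", "crosslinker", "myosin"))
  structure(raw[c("vert_ori", "vert_time", "vert_bond",
                  "horiz_ori", "horiz_time", "horiz_bond",
                  "acs", "myosins", "loads", "reservoir", "iteration",
                  "width", "height", "periodic")],
            class = "cortex_state")
}

#' @export
print.cortex_state <- function(x, ...) {
  n1 <- sum(x$vert_ori > 0) + sum(x$horiz_ori > 0)
  cat(sprintf("<cortex_state> %dx%d %s lattice, iteration %g\n",
              x$width, x$height,
              if (x$periodic) "periodic" else "closed", x$iteration))
  cat(sprintf("  monomers on grid: %d (occupancy %.1f%%), ACs: %d, myosins: %d\n",
              n1, occupancy(x), nrow(x$acs), nrow(x$myosins)))
  cat(sprintf("  reservoir: actin %g, crosslinker %g, myosin %g\n",
              x$reservoir[1], x$reservoir[2], x$reservoir[3]))
  invisible(x)
}

check_coords <- function(state, x, y) {
  if (any(x < 1 | x > state$width | y < 1 | y > state$height)) {
    stop("coordinates out of range for a ", state$width, "x", state$height,
         " lattice")
  }
}

slot_mats <- function(axis) {
  if (axis == 1) c(ori = "vert_ori", time = "vert_time", bond = "vert_bond")
  else c(ori = "horiz_ori", time = "horiz_time", bond = "horiz_bond")
}

# neighbor in the direction of orientation `code` (barbed growth
# direction); returns NULL outside a closed lattice
step_pos <- function(state, x, y, code) {
  s <- ori_step(code)
  nx <- unname(x + s[1, "dx"]); ny <- unname(y + s[1, "dy"])
  if (state$periodic) {
    nx <- (nx - 1L) %% state$width + 1L
    ny <- (ny - 1L) %% state$height + 1L
  } else if (nx < 1 || nx > state$width || ny < 1 || ny > state$height) {
    return(NULL)
  }
  c(x = nx, y = ny)
}

flip_ori <- function(code) c(2L, 1L, 4L, 3L)[code]

#' Query the content of a lattice slot
#'
#' @param state A [cortex_state()].
#' @param x,y Node coordinates (1-based).
#' @param axis `"vertical"` or `"horizontal"`.
#' @return `"empty"` or `"occupied"`, with the orientation as attribute
#'   `"orientation"` when occupied.
#' @examples
#' st <- cortex_state(cortex_params(actin = species_params(0, 10), width = 4, height = 4))
#' site_state(st, 2, 2, "vertical")
#' @export
site_state <- function(state, x, y, axis = c("vertical", "horizontal")) {
  stopifnot(inherits(state, "cortex_state"))
  axis <- match.arg(axis)
  check_coords(state, x, y)
  mat <- if (axis == "vertical") state$vert_ori else state$horiz_ori
  code <- mat[x, y]
  if (code == 0L) return("empty")
  structure("occupied", orientation = ori_name(code))
}

#' Verify molecule conservation
#'
#' Checks that for each species the number of molecules on the lattice
#' plus the reservoir count equals the species total `N0`.
#'
#' @param state A [cortex_state()].
#' @param params The matching [cortex_params()].
#' @return `TRUE` or `FALSE`.
#' @export
check_conservation <- function(state, params) {
  on_grid <- c(sum(state$vert_ori > 0) + sum(state$horiz_ori > 0),
               nrow(state$acs), nrow(state$myosins))
  isTRUE(all(abs(on_grid + state$reservoir - params$N0) < 1e-9))
}

#' Place a monomer on the lattice (state construction helper)
#'
#' Inserts a G-actin monomer with the given orientation, taking it from
#' the reservoir.  The polymer bond to the monomer behind (towards the
#' pointed end) is formed exactly when that neighbouring slot holds a
#' monomer of identical orientation, mirroring the insertion rule of the
#' simulation kernel.
#'
#' @param state A [cortex_state()].
#' @param x,y Node coordinates.
#' @param orientation `"north"`, `"south"`, `"east"` or `"west"`.
#' @param time Insertion-time stamp (iteration number).
#' @return The modified state.
#' @export
place_monomer <- function(state, x, y, orientation, time = state$iteration) {
  stopifnot(inherits(state, "cortex_state"))
  check_coords(state, x, y)
  code <- ori_code(orientation)
  mats <- slot_mats(ori_axis(code))
  if (state[[mats["ori"]]][x, y] != 0L) {
    stop("slot (", x, ",", y, ") on that axis is already occupied")
  }
  if (state$reservoir["actin"] < 1) stop("actin reservoir is empty")
  bonded <- 0L
  behind <- step_pos(state, x, y, flip_ori(code))
  if (!is.null(behind) && state[[mats["ori"]]][behind["x"], behind["y"]] == code) {
    bonded <- 1L
  }
  state[[mats["ori"]]][x, y] <- code
  state[[mats["time"]]][x, y] <- as.integer(time)
  state[[mats["bond"]]][x, y] <- bonded
  state$reservoir["actin"] <- state$reservoir["actin"] - 1
  state
}

# remove a monomer and dissolve any links it carries; chain/load
# bookkeeping is NOT updated here (used by the attempt_* operations,
# which handle it)
drop_monomer <- function(state, x, y, axis) {
  mats <- slot_mats(axis)
  state[[mats["ori"]]][x, y] <- 0L
  state[[mats["time"]]][x, y] <- 0L
  state[[mats["bond"]]][x, y] <- 0L
  state$reservoir["actin"] <- state$reservoir["actin"] + 1
  # dissolve AC / myosin links touching this slot
  hit_a <- state$acs$xa == x & state$acs$ya == y & state$acs$axa == axis - 1L
  hit_b <- state$acs$xb == x & state$acs$yb == y & state$acs$axb == axis - 1L
  ndrop <- sum(hit_a | hit_b)
  if (ndrop > 0) {
    state$acs <- state$acs[!(hit_a | hit_b), ]
    state$reservoir["crosslinker"] <- state$reservoir["crosslinker"] + ndrop
  }
  hit_a <- state$myosins$xa == x & state$myosins$ya == y & state$myosins$axa == axis - 1L
  hit_b <- state$myosins$xb == x & state$myosins$yb == y & state$myosins$axb == axis - 1L
  ndrop <- sum(hit_a | hit_b)
  if (ndrop > 0) {
    state$myosins <- state$myosins[!(hit_a | hit_b), ]
    state$reservoir["myosin"] <- state$reservoir["myosin"] + ndrop
  }
  state
}

#' Place a crosslinker or myosin link on a lattice edge
#'
#' Construction helpers for building test states by hand.  The two
#' endpoint slots must be occupied and lie on adjacent nodes.
#' Eligibility (distinct filaments, anti-parallel orientations for
#' myosin) is checked unless `check = FALSE`.
#'
#' @param state A [cortex_state()].
#' @param xa,ya,axa First endpoint: node and axis (`"vertical"` /
#'   `"horizontal"`).
#' @param xb,yb,axb Second endpoint.
#' @param check Validate eligibility.
#' @param attach_sec For myosin, the attachment-time stamp in calibrated
#'   seconds.
#' @return The modified state.
#' @export
place_crosslinker <- function(state, xa, ya, axa, xb, yb, axb, check = TRUE) {
  edge <- normalize_edge(state, xa, ya, axa, xb, yb, axb)
  if (check) {
    pairs <- eligible_axis_pairs(state, edge$xa, edge$ya, edge$xb, edge$yb,
                                 antiparallel = FALSE, ac_any = FALSE)
    ok <- any(vapply(pairs, function(pr)
      pr["axa"] == edge$axa && pr["axb"] == edge$axb, logical(1)))
    if (!ok) stop("edge endpoints are not two monomers of distinct filaments")
  }
  if (state$reservoir["crosslinker"] < 1) stop("crosslinker reservoir is empty")
  if (edge_occupied(state$acs, edge)) stop("edge already carries a crosslinker")
  state$acs <- dplyr::bind_rows(state$acs, edge)
  state$reservoir["crosslinker"] <- state$reservoir["crosslinker"] - 1
  state
}

#' @rdname place_crosslinker
#' @export
place_myosin <- function(state, xa, ya, axa, xb, yb, axb, attach_sec = 0,
                         check = TRUE) {
  edge <- normalize_edge(state, xa, ya, axa, xb, yb, axb)
  if (check) {
    pairs <- eligible_axis_pairs(state, edge$xa, edge$ya, edge$xb, edge$yb,
                                 antiparallel = TRUE, ac_any = FALSE)
    ok <- any(vapply(pairs, function(pr)
      pr["axa"] == edge$axa && pr["axb"] == edge$axb, logical(1)))
    if (!ok) stop("edge endpoints are not two anti-parallel filaments")
  }
  if (state$reservoir["myosin"] < 1) stop("myosin reservoir is empty")
  if (edge_occupied(state$myosins, edge)) stop("edge already carries a myosin")
  edge$attach_sec <- attach_sec
  edge$active <- 1L
  state$myosins <- dplyr::bind_rows(state$myosins, edge)
  state$reservoir["myosin"] <- state$reservoir["myosin"] - 1
  state
}

axis_code <- function(axis) {
  if (is.numeric(axis)) return(as.integer(axis))
  match(match.arg(axis, c("vertical", "horizontal")), c("vertical", "horizontal"))
}

# canonical edge record (0-based axis codes, endpoints as given)
normalize_edge <- function(state, xa, ya, axa, xb, yb, axb) {
  axa <- axis_code(axa); axb <- axis_code(axb)
  check_coords(state, xa, ya); check_coords(state, xb, yb)
  dx <- xb - xa; dy <- yb - ya
  if (state$periodic) {
    dx <- ((dx %% state$width) + state$width) %% state$width
    if (dx == state$width - 1) dx <- -1
    dy <- ((dy %% state$height) + state$height) %% state$height
    if (dy == state$height - 1) dy <- -1
  }
  if (abs(dx) + abs(dy) != 1) stop("edge endpoints must be adjacent nodes")
  oa <- (if (axa == 1) state$vert_ori else state$horiz_ori)[xa, ya]
  ob <- (if (axb == 1) state$vert_ori else state$horiz_ori)[xb, yb]
  if (oa == 0 || ob == 0) stop("both edge endpoints must hold monomers")
  tibble::tibble(xa = as.integer(xa), ya = as.integer(ya), axa = axa - 1L,
                 xb = as.integer(xb), yb = as.integer(yb), axb = axb - 1L)
}

edge_occupied <- function(links, edge) {
  if (nrow(links) == 0) return(FALSE)
  same <- (links$xa == edge$xa & links$ya == edge$ya &
           links$xb == edge$xb & links$yb == edge$yb) |
          (links$xa == edge$xb & links$ya == edge$yb &
           links$xb == edge$xa & links$yb == edge$ya)
  any(same)
}

#' Serialize lattice snapshots as JSON lines
#'
#' Writes one JSON record per occupied slot, per link and per reservoir
#' entry, giving a bit-exact round-trip through [read_snapshots()].
#'
#' @param snapshots A list of [cortex_state()] objects (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path) {
  if (inherits(snapshots, "cortex_state")) snapshots <- list(snapshots)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (st in snapshots) {
    rec <- list(
      type = "snapshot",
      width = st$width, height = st$height, periodic = st$periodic,
      iteration = st$iteration,
      slots = slot_table(st),
      acs = as.data.frame(st$acs),
      myosins = as.data.frame(st$myosins),
      loads = as.data.frame(st$loads),
      reservoir = as.list(st$reservoir)
    )
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_snapshots
#' @return For `read_snapshots()`, a list of `cortex_state` objects.
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    p <- cortex_params(
      actin = species_params(0, rec$reservoir$actin),
      crosslinker = species_params(0, rec$reservoir$crosslinker),
      myosin = species_params(0, rec$reservoir$myosin),
      width = rec$width, height = rec$height, periodic = rec$periodic)
    st <- cortex_state(p)
    st$iteration <- rec$iteration
    sl <- rec$slots
    if (length(sl) > 0 && NROW(sl) > 0) {
      for (i in seq_len(nrow(sl))) {
        mats <- slot_mats(sl$axis[i])
        st[[mats["ori"]]][sl$x[i], sl$y[i]] <- sl$orientation[i]
        st[[mats["time"]]][sl$x[i], sl$y[i]] <- sl$t_insert[i]
        st[[mats["bond"]]][sl$x[i], sl$y[i]] <- sl$bonded[i]
      }
    }
    fix_int <- function(df, cols) { for (cc in cols) df[[cc]] <- as.integer(df[[cc]]); df }
    if (NROW(rec$acs) > 0) {
      st$acs <- fix_int(tibble::as_tibble(rec$acs),
                        c("xa", "ya", "axa", "xb", "yb", "axb"))
    }
    if (NROW(rec$myosins) > 0) {
      my <- fix_int(tibble::as_tibble(rec$myosins),
                    c("xa", "ya", "axa", "xb", "yb", "axb", "active"))
      my$attach_sec <- as.numeric(my$attach_sec)
      st$myosins <- my
    }
    if (NROW(rec$loads) > 0) {
      ld <- fix_int(tibble::as_tibble(rec$loads), c("ori", "px", "py"))
      ld$accrued <- as.numeric(ld$accrued)
      st$loads <- ld
    }
    # reservoir counts: monomers placed above were debited from the full
    # budget, so restore the recorded values
    st$reservoir <- stats::setNames(
      as.numeric(rec$reservoir[c("actin", "crosslinker", "myosin")]),
      c("actin", "crosslinker", "myosin"))
    st
  })
}

# one row per occupied slot
slot_table <- function(state) {
  out <- list()
  for (axis in 1:2) {
    mats <- slot_mats(axis)
    occ <- which(state[[mats["ori"]]] > 0, arr.ind = TRUE)
    if (nrow(occ) == 0) next
    out[[axis]] <- tibble::tibble(
      x = as.integer(occ[, 1]), y = as.integer(occ[, 2]),
      axis = axis,
      orientation = state[[mats["ori"]]][occ],
      t_insert = state[[mats["time"]]][occ],
      bonded = state[[mats["bond"]]][occ])
  }
  if (length(out) == 0) {
    return(tibble::tibble(x = integer(), y = integer(), axis = integer(),
                          orientation = integer(), t_insert = integer(),
                          bonded = integer()))
  }
  dplyr::bind_rows(out)
}
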