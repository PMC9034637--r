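#' Elementary Monte Carlo moves (reference R implementations)
#'
#' These functions evaluate a single insertion or removal exactly as the
#' simulation kernel does, drawing from the current RNG stream, and are
#' the granular module surface used by the tests; [simulate_cortex()]
#' runs the same rules in compiled code.
#'
#' `attempt_actin_insert()` draws an orientation uniformly among the
#' four configurations; if the corresponding axis slot is occupied the
#' move is `"blocked"`.  Otherwise the insertion is accepted with
#' Metropolis weight \eqn{P^+ = e^{\mu_1}}; on acceptance a membrane link
#' `E1` is established and, when the new monomer sits directly in front
#' of the barbed end of a same-orientation run, a polymer bond of energy
#' `E0` joins it to that chain.
#'
#' `attempt_actin_remove()` evaluates \eqn{P^- = e^{-E}} with `E` the
#' monomer's total link energy ([monomer_link_energy()]).  On acceptance
#' the monomer returns to the reservoir and every crosslinker or myosin
#' link it carried dissolves (those molecules return to their
#' reservoirs, a dissolving myosin first freezing its accumulated load
#' onto the partner filament).  Removal of a monomer strictly inside a
#' chain is forbidden when `params$forbid_interior_removal` is set.
#'
#' @param state A [cortex_state()].
#' @param x,y Node coordinates.
#' @param params A [cortex_params()].
#' @param orientation Optional forced orientation for the insertion
#'   draw (used by tests); by default drawn uniformly.
#' @return A list with `result` (`"accepted"`, `"rejected"` or
#'   `"blocked"`) and the possibly updated `state`.
#' @export
attempt_actin_insert <- function(state, x, y, params, orientation = NULL) {
  check_coords(state, x, y)
  code <- if (is.null(orientation)) {
    sample.int(4L, 1L)
  } else {
    ori_code(orientation)
  }
  mats <- slot_mats(ori_axis(code))
  if (state[[mats["ori"]]][x, y] != 0L) {
    return(list(result = "blocked", state = state))
  }
  if (state$reservoir["actin"] < 1) {
    return(list(result = "blocked", state = state))
  }
  n_grid <- sum(state$vert_ori > 0) + sum(state$horiz_ori > 0)
  mu <- chemical_potential(actin_species(params), n_grid, params$log_base)
  if (!metropolis_accept(insertion_probability(mu))) {
    return(list(result = "rejected", state = state))
  }
  state <- place_monomer(state, x, y, code, time = state$iteration)
  list(result = "accepted", state = state)
}

#' @rdname attempt_actin_insert
#' @param axis `"vertical"` or `"horizontal"`: which slot to evaluate.
#' @export
attempt_actin_remove <- function(state, x, y, axis, params) {
  axis <- axis_code(axis)
  mats <- slot_mats(axis)
  if (state[[mats["ori"]]][x, y] == 0L) stop("slot is empty")
  code <- state[[mats["ori"]]][x, y]
  cm <- chain_map(state)
  cid <- chain_id_at(cm, x, y, axis - 1L)
  ch <- cm$chains[cm$chains$id == cid, ]
  pointed <- ch$x_pointed == x && ch$y_pointed == y
  barbed <- ch$x_barbed == x && ch$y_barbed == y
  if (!pointed && !barbed && params$forbid_interior_removal) {
    return(list(result = "rejected", state = state))
  }
  E <- monomer_link_energy(state, x, y, axis, params)$total
  if (!metropolis_accept(removal_probability(E))) {
    return(list(result = "rejected", state = state))
  }
  t_sec <- iteration_seconds(state$iteration, params)
  state <- freeze_touching_myosins(state, cm, x, y, axis - 1L, params, t_sec)
  state <- drop_monomer(state, x, y, axis)
  state <- rekey_loads_after_removal(state, ch, code, pointed, barbed, x, y)
  list(result = "accepted", state = state)
}

actin_species <- function(params) {
  species_params(params$mu0[1], params$N0[1], params$gamma[1], params$E_link[1])
}

# bank the live contribution of every active myosin touching a slot onto
# both bridged chains (called just before the slot's links dissolve)
freeze_touching_myosins <- function(state, cm, x, y, axis0, params, t_sec) {
  my <- state$myosins
  if (nrow(my) == 0) return(state)
  touches <- (my$xa == x & my$ya == y & my$axa == axis0) |
             (my$xb == x & my$yb == y & my$axb == axis0)
  for (m in which(touches & my$active == 1L)) {
    contrib <- params$W3 * (t_sec - my$attach_sec[m])
    for (endp in list(c(my$xa[m], my$ya[m], my$axa[m]),
                      c(my$xb[m], my$yb[m], my$axb[m]))) {
      cid <- chain_id_at(cm, endp[1], endp[2], endp[3])
      row <- cm$chains[cm$chains$id == cid, ]
      if (nrow(row) == 1) state <- bank_load(state, row, contrib)
    }
  }
  state
}

# persisted loads are keyed by (orientation, pointed end); removal of the
# pointed terminal shifts the key one step forward, death of the chain
# discards it
rekey_loads_after_removal <- function(state, ch, code, pointed, barbed, x, y) {
  if (nrow(state$loads) == 0) return(state)
  hit <- state$loads$ori == code & state$loads$px == ch$x_pointed &
    state$loads$py == ch$y_pointed
  if (!any(hit)) return(state)
  if (ch$length == 1L) {
    state$loads <- state$loads[!hit, ]
  } else if (pointed) {
    nxt <- step_pos(state, x, y, code)
    state$loads$px[hit] <- nxt["x"]
    state$loads$py[hit] <- nxt["y"]
  } else if (!barbed) {
    # interior removal splits the chain; split the banked load in
    # proportion to the fragment lengths, front fragment re-keyed
    total <- sum(state$loads$accrued[hit])
    nxt <- step_pos(state, x, y, code)
    back_len <- run_distance(ch$x_pointed, ch$y_pointed, x, y, code, state)
    front_len <- ch$length - back_len - 1L
    state$loads$accrued[hit] <- total * back_len / (back_len + front_len)
    state <- bank_load_raw(state, code, nxt["x"], nxt["y"],
                           total * front_len / (back_len + front_len))
  }
  state
}

bank_load_raw <- function(state, code, px, py, amount) {
  if (amount == 0) return(state)
  state$loads <- dplyr::bind_rows(
    state$loads,
    tibble::tibble(ori = code, px = as.integer(px), py = as.integer(py),
                   accrued = amount))
  state
}

# monomer steps from the pointed end to (x, y) along orientation `code`
run_distance <- function(px, py, x, y, code, state) {
  d <- 0L; cx <- px; cy <- py
  while (!(cx == x && cy == y)) {
    nxt <- step_pos(state, cx, cy, code)
    cx <- nxt["x"]; cy <- nxt["y"]
    d <- d + 1L
    if (d > state$width * state$height) stop("run walk did not terminate")
  }
  d
}

#' Crosslinker insertion and removal moves
#'
#' `attempt_ac_insert()` is `"blocked"` when the edge is ineligible
#' ([ac_eligible()]) or already carries a crosslinker; otherwise the
#' insertion is accepted with weight \eqn{P^+ = e^{\mu_2}}, registering a
#' link of energy `E2` on each endpoint monomer.  When several endpoint
#' axis pairs qualify one is drawn uniformly.  `attempt_ac_remove()`
#' accepts with \eqn{P^- = e^{-2 E_2}} (both links must release).
#'
#' @inheritParams attempt_actin_insert
#' @param xa,ya,xb,yb The edge's two adjacent nodes.
#' @return A list with `result` and `state` as in
#'   [attempt_actin_insert()].
#' @export
attempt_ac_insert <- function(state, xa, ya, xb, yb, params) {
  if (edge_occupied_nodes(state$acs, state, xa, ya, xb, yb) ||
      state$reservoir["crosslinker"] < 1) {
    return(list(result = "blocked", state = state))
  }
  pairs <- eligible_axis_pairs(state, xa, ya, xb, yb, antiparallel = FALSE,
                               ac_any = params$ac_link_oligomers)
  if (length(pairs) == 0) return(list(result = "blocked", state = state))
  pick <- if (length(pairs) > 1) pairs[[sample.int(length(pairs), 1L)]] else pairs[[1]]
  mu <- chemical_potential(
    species_params(params$mu0[2], params$N0[2], params$gamma[2], params$E_link[2]),
    nrow(state$acs), params$log_base)
  if (!metropolis_accept(insertion_probability(mu))) {
    return(list(result = "rejected", state = state))
  }
  state$acs <- dplyr::bind_rows(
    state$acs,
    tibble::tibble(xa = as.integer(xa), ya = as.integer(ya),
                   axa = unname(pick["axa"]),
                   xb = as.integer(xb), yb = as.integer(yb),
                   axb = unname(pick["axb"])))
  state$reservoir["crosslinker"] <- state$reservoir["crosslinker"] - 1
  list(result = "accepted", state = state)
}

#' @rdname attempt_ac_insert
#' @export
attempt_ac_remove <- function(state, xa, ya, xb, yb, params) {
  hit <- which((state$acs$xa == xa & state$acs$ya == ya &
                state$acs$xb == xb & state$acs$yb == yb) |
               (state$acs$xa == xb & state$acs$ya == yb &
                state$acs$xb == xa & state$acs$yb == ya))
  if (length(hit) == 0) stop("edge does not carry a crosslinker")
  if (!metropolis_accept(removal_probability(2 * params$E_link[2]))) {
    return(list(result = "rejected", state = state))
  }
  state$acs <- state$acs[-hit, ]
  state$reservoir["crosslinker"] <- state$reservoir["crosslinker"] + 1
  list(result = "accepted", state = state)
}

#' Myosin insertion and removal moves
#'
#' Mirror the crosslinker mechanics with \eqn{(\mu_3, E_3)} and the
#' anti-parallel eligibility rule ([myosin_eligible()]).  An accepted
#' insertion starts the attachment timer.  Removal of an *active* myosin
#' is accepted with \eqn{P^- = e^{-2 E_3}} and freezes its accumulated
#' load `W3 * t` onto both bridged filaments; a myosin whose bridge has
#' broken (one filament gone) is returned to the reservoir
#' deterministically.
#'
#' @inheritParams attempt_ac_insert
#' @export
attempt_myosin_insert <- function(state, xa, ya, xb, yb, params) {
  if (edge_occupied_nodes(state$myosins, state, xa, ya, xb, yb) ||
      state$reservoir["myosin"] < 1) {
    return(list(result = "blocked", state = state))
  }
  pairs <- eligible_axis_pairs(state, xa, ya, xb, yb, antiparallel = TRUE,
                               ac_any = FALSE)
  if (length(pairs) == 0) return(list(result = "blocked", state = state))
  pick <- if (length(pairs) > 1) pairs[[sample.int(length(pairs), 1L)]] else pairs[[1]]
  mu <- chemical_potential(
    species_params(params$mu0[3], params$N0[3], params$gamma[3], params$E_link[3]),
    nrow(state$myosins), params$log_base)
  if (!metropolis_accept(insertion_probability(mu))) {
    return(list(result = "rejected", state = state))
  }
  state$myosins <- dplyr::bind_rows(
    state$myosins,
    tibble::tibble(xa = as.integer(xa), ya = as.integer(ya),
                   axa = unname(pick["axa"]),
                   xb = as.integer(xb), yb = as.integer(yb),
                   axb = unname(pick["axb"]),
                   attach_sec = iteration_seconds(state$iteration, params),
                   active = 1L))
  state$reservoir["myosin"] <- state$reservoir["myosin"] - 1
  list(result = "accepted", state = state)
}

#' @rdname attempt_myosin_insert
#' @export
attempt_myosin_remove <- function(state, xa, ya, xb, yb, params) {
  hit <- which((state$myosins$xa == xa & state$myosins$ya == ya &
                state$myosins$xb == xb & state$myosins$yb == yb) |
               (state$myosins$xa == xb & state$myosins$ya == yb &
                state$myosins$xb == xa & state$myosins$yb == ya))
  if (length(hit) == 0) stop("edge does not carry a myosin")
  active <- state$myosins$active[hit] == 1L
  if (active && !metropolis_accept(removal_probability(2 * params$E_link[3]))) {
    return(list(result = "rejected", state = state))
  }
  if (active) {
    cm <- chain_map(state)
    my <- state$myosins[hit, ]
    t_sec <- iteration_seconds(state$iteration, params)
    contrib <- params$W3 * (t_sec - my$attach_sec)
    for (endp in list(c(my$xa, my$ya, my$axa), c(my$xb, my$yb, my$axb))) {
      cid <- chain_id_at(cm, endp[1], endp[2], endp[3])
      row <- cm$chains[cm$chains$id == cid, ]
      if (nrow(row) == 1) state <- bank_load(state, row, contrib)
    }
  }
  state$myosins <- state$myosins[-hit, ]
  state$reservoir["myosin"] <- state$reservoir["myosin"] + 1
  list(result = "accepted", state = state)
}
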