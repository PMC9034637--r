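#' Chain and filament census of a lattice state
#'
#' A *chain* is a maximal run of identically oriented monomers connected
#' by polymer bonds (each monomer records whether it is bonded to the
#' neighbour behind it, towards the pointed end).  A chain of three or
#' more monomers is a *filament* (F-actin); shorter runs are oligomers.
#' The pointed end is the first chain member (its polymer bond is
#' destabilised), the barbed end the last; the filament grows in the
#' direction of its orientation vector.
#'
#' `find_chains()` reports every chain; `find_filaments()` only chains
#' with `length >= 3`, joined with their persisted (redistributed) load.
#'
#' @param state A [cortex_state()].
#' @return A tibble with one row per chain: `id`, `orientation`,
#'   `length`, `x_pointed`, `y_pointed`, `x_barbed`, `y_barbed`,
#'   `is_filament`, `e_load_accrued`.
#' @export
find_chains <- function(state) {
  cm <- chain_map(state)
  cm$chains
}

#' @rdname find_chains
#' @export
find_filaments <- function(state) {
  dplyr::filter(find_chains(state), .data$is_filament)
}

# derive all chains plus a per-slot chain-id map; the workhorse for the
# R-side (non-kernel) analysis route
chain_map <- function(state) {
  maps <- list(matrix(NA_integer_, state$width, state$height),
               matrix(NA_integer_, state$width, state$height))
  rows <- list()
  id <- 0L
  loads <- state$loads
  for (axis in 1:2) {
    omat <- if (axis == 1) state$vert_ori else state$horiz_ori
    bmat <- if (axis == 1) state$vert_bond else state$horiz_bond
    starts <- which(omat > 0 & bmat == 0, arr.ind = TRUE)
    if (nrow(starts) == 0) next
    for (k in seq_len(nrow(starts))) {
      x0 <- starts[k, 1]; y0 <- starts[k, 2]
      code <- omat[x0, y0]
      id <- id + 1L
      x <- x0; y <- y0; len <- 1L
      maps[[axis]][x, y] <- id
      repeat {
        nxt <- step_pos(state, x, y, code)
        if (is.null(nxt) || omat[nxt["x"], nxt["y"]] != code ||
            bmat[nxt["x"], nxt["y"]] != 1L) break
        x <- nxt["x"]; y <- nxt["y"]
        len <- len + 1L
        maps[[axis]][x, y] <- id
      }
      acc <- 0
      if (nrow(loads) > 0) {
        hit <- loads$ori == code & loads$px == x0 & loads$py == y0
        if (any(hit)) acc <- sum(loads$accrued[hit])
      }
      rows[[id]] <- tibble::tibble(
        id = id, orientation = ori_name(code), length = len,
        x_pointed = as.integer(x0), y_pointed = as.integer(y0),
        x_barbed = as.integer(x), y_barbed = as.integer(y),
        is_filament = len >= 3L, e_load_accrued = acc)
    }
  }
  chains <- if (length(rows) == 0) {
    tibble::tibble(id = integer(), orientation = character(),
                   length = integer(), x_pointed = integer(),
                   y_pointed = integer(), x_barbed = integer(),
                   y_barbed = integer(), is_filament = logical(),
                   e_load_accrued = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  list(chains = chains, vert = maps[[1]], horiz = maps[[2]])
}

chain_id_at <- function(cm, x, y, axis0) {
  # axis0 is the 0-based axis code used in the link tables
  if (axis0 == 0L) cm$vert[x, y] else cm$horiz[x, y]
}

#' Itemized link energy of a monomer
#'
#' Returns the energy of every link holding the monomer at the cortex:
#' the membrane anchor `E1`, the polymer bond (`E0`, absent for the
#' pointed-end terminal monomer of a chain and for isolated monomers),
#' `E2` per attached crosslinker and `E3` per attached myosin.  The
#' total sets the removal weight \eqn{P^- = e^{-E}}.
#'
#' @param state A [cortex_state()].
#' @param x,y Node coordinates.
#' @param axis `"vertical"` or `"horizontal"`.
#' @param params A [cortex_params()].
#' @return A list with components `E_membrane`, `E_bond`, `E_ac`,
#'   `E_myosin`, `total`.
#' @export
monomer_link_energy <- function(state, x, y, axis, params) {
  axis <- axis_code(axis)
  check_coords(state, x, y)
  mats <- slot_mats(axis)
  if (state[[mats["ori"]]][x, y] == 0L) {
    stop("slot (", x, ",", y, ") is empty")
  }
  bonded <- state[[mats["bond"]]][x, y] == 1L
  n_ac <- count_links(state$acs, x, y, axis - 1L)
  n_my <- count_links(state$myosins, x, y, axis - 1L)
  out <- list(E_membrane = params$E_link[1],
              E_bond = if (bonded) params$E0 else 0,
              E_ac = n_ac * params$E_link[2],
              E_myosin = n_my * params$E_link[3])
  out$total <- out$E_membrane + out$E_bond + out$E_ac + out$E_myosin
  out
}

count_links <- function(links, x, y, axis0) {
  if (nrow(links) == 0) return(0L)
  sum((links$xa == x & links$ya == y & links$axa == axis0) |
      (links$xb == x & links$yb == y & links$axb == axis0))
}

#' Membrane-anchoring capacity of a filament
#'
#' A filament of length `L` is held at the cortex by `L` membrane links
#' of energy `E1`; its total anchoring capacity is `E1 * L`, recomputed
#' from the current length.  A filament whose accumulated elastic load
#' exceeds this threshold detaches whole.
#'
#' @param L Filament length in monomers.
#' @param E1 Membrane link energy (RT).
#' @return The threshold energy in RT.
#' @export
filament_threshold <- function(L, E1) {
  stopifnot(L >= 0)
  E1 * L
}

#' Current elastic load of every filament
#'
#' The load of a filament is its persisted (frozen + redistributed)
#' component plus `W3 * (t - t_attach)` summed over the active myosins
#' currently bridging it; a myosin contributes to both filaments it
#' bridges.  Loads only accumulate: contributions of departed myosins
#' stay frozen on the filament.
#'
#' @param state A [cortex_state()].
#' @param params A [cortex_params()].
#' @param t_sec Evaluation time in calibrated seconds; defaults to the
#'   state's iteration mapped through the calibration in `params`.
#' @return The [find_filaments()] tibble with columns `threshold` and
#'   `e_load` added.
#' @export
filament_loads <- function(state, params, t_sec = NULL) {
  if (is.null(t_sec)) t_sec <- iteration_seconds(state$iteration, params)
  cm <- chain_map(state)
  fil <- dplyr::filter(cm$chains, .data$is_filament)
  fil$threshold <- filament_threshold(fil$length, params$E_link[1])
  live <- numeric(nrow(fil))
  my <- state$myosins
  if (nrow(my) > 0 && nrow(fil) > 0) {
    for (i in seq_len(nrow(my))) {
      if (my$active[i] != 1L) next
      for (endp in list(c(my$xa[i], my$ya[i], my$axa[i]),
                        c(my$xb[i], my$yb[i], my$axb[i]))) {
        cid <- chain_id_at(cm, endp[1], endp[2], endp[3])
        j <- match(cid, fil$id)
        if (!is.na(j)) live[j] <- live[j] + params$W3 * (t_sec - my$attach_sec[i])
      }
    }
  }
  fil$e_load <- fil$e_load_accrued + live
  fil
}

iteration_seconds <- function(iteration, params) {
  iteration / (2 * params$width * params$height) * params$kappa * 60
}

#' Total cortical tension
#'
#' The summed elastic load of every attached filament, in RT.
#'
#' @inheritParams filament_loads
#' @return A single number.
#' @export
total_tension <- function(state, params, t_sec = NULL) {
  sum(filament_loads(state, params, t_sec)$e_load)
}

#' Filament networks
#'
#' Builds the graph whose vertices are filaments (chains of three or more
#' monomers) and whose edges are crosslinker or active-myosin links, and
#' returns its connected components.  Following the convention used for
#' the "number of bundles" observable, a *network* is a component with at
#' least two filaments.
#'
#' @param state A [cortex_state()].
#' @param min_filaments Smallest component size (in filaments) to report.
#' @return A tibble with one row per network: `network_id`,
#'   `n_filaments`, `n_monomers`, and a list-column `filament_ids`.
#' @export
find_networks <- function(state, min_filaments = 2) {
  cm <- chain_map(state)
  fil <- dplyr::filter(cm$chains, .data$is_filament)
  if (nrow(fil) == 0) {
    return(tibble::tibble(network_id = integer(), n_filaments = integer(),
                          n_monomers = integer(), filament_ids = list()))
  }
  parent <- stats::setNames(fil$id, fil$id)
  find_root <- function(i) {
    key <- as.character(i)
    while (parent[[key]] != i) { i <- parent[[key]]; key <- as.character(i) }
    i
  }
  links <- dplyr::bind_rows(
    state$acs[, c("xa", "ya", "axa", "xb", "yb", "axb")],
    if (nrow(state$myosins) > 0)
      state$myosins[state$myosins$active == 1L,
                    c("xa", "ya", "axa", "xb", "yb", "axb")]
  )
  if (!is.null(links) && nrow(links) > 0) {
    for (i in seq_len(nrow(links))) {
      fa <- chain_id_at(cm, links$xa[i], links$ya[i], links$axa[i])
      fb <- chain_id_at(cm, links$xb[i], links$yb[i], links$axb[i])
      if (is.na(fa) || is.na(fb)) next
      if (!fa %in% fil$id || !fb %in% fil$id || fa == fb) next
      ra <- find_root(fa); rb <- find_root(fb)
      if (ra != rb) parent[[as.character(ra)]] <- rb
    }
  }
  fil$root <- vapply(fil$id, find_root, numeric(1))
  nets <- fil |>
    dplyr::group_by(.data$root) |>
    dplyr::summarise(n_filaments = dplyr::n(),
                     n_monomers = sum(.data$length),
                     filament_ids = list(.data$id), .groups = "drop") |>
    dplyr::filter(.data$n_filaments >= min_filaments) |>
    dplyr::arrange(dplyr::desc(.data$n_monomers))
  tibble::tibble(network_id = seq_len(nrow(nets)),
                 n_filaments = nets$n_filaments,
                 n_monomers = nets$n_monomers,
                 filament_ids = nets$filament_ids)
}

#' Threshold detachment and load redistribution
#'
#' Applies the tension rule to a state: every filament whose elastic
#' load exceeds its anchoring capacity `E1 * L` (strict inequality)
#' detaches whole -- its monomers and any attached crosslinkers and
#' myosins return to their reservoirs -- and its load is split equally
#' among the filaments remaining in the same network.  A detaching
#' filament with no surviving network partners discards its load.
#' Redistribution may push survivors over threshold, so passes cascade
#' until no filament exceeds its capacity.
#'
#' This is the reference R implementation used for validation; during
#' simulations the kernel applies the identical rule after every
#' iteration.
#'
#' @inheritParams filament_loads
#' @return A list with the updated `state` and an `events` tibble
#'   (one row per cascade pass: `n_detached`, `monomers_released`,
#'   `load_redistributed`, `load_discarded`).
#' @export
process_detachments <- function(state, params, t_sec = NULL) {
  if (is.null(t_sec)) t_sec <- iteration_seconds(state$iteration, params)
  events <- list()
  pass <- 0L
  repeat {
    fil <- filament_loads(state, params, t_sec)
    over <- fil[fil$e_load > fil$threshold, ]
    if (nrow(over) == 0) break
    pass <- pass + 1L
    comps <- find_networks(state, min_filaments = 1)
    redistributed <- 0; discarded <- 0
    gains <- stats::setNames(numeric(nrow(fil)), fil$id)
    for (i in seq_len(nrow(over))) {
      comp <- which(vapply(comps$filament_ids,
                           function(ids) over$id[i] %in% ids, logical(1)))
      members <- if (length(comp) > 0) comps$filament_ids[[comp]] else over$id[i]
      recip <- setdiff(members, over$id)
      if (length(recip) == 0) {
        discarded <- discarded + over$e_load[i]
      } else {
        gains[as.character(recip)] <- gains[as.character(recip)] +
          over$e_load[i] / length(recip)
        redistributed <- redistributed + over$e_load[i]
      }
    }
    # myosins bridging a detaching filament to a survivor dissolve with
    # it; their accumulated contribution to the survivor freezes first
    cm <- chain_map(state)
    my <- state$myosins
    if (nrow(my) > 0) {
      for (m in seq_len(nrow(my))) {
        if (my$active[m] != 1L) next
        fa <- chain_id_at(cm, my$xa[m], my$ya[m], my$axa[m])
        fb <- chain_id_at(cm, my$xb[m], my$yb[m], my$axb[m])
        pair <- c(fa, fb)
        if (any(pair %in% over$id) && !all(pair %in% over$id)) {
          surv <- setdiff(pair, over$id)
          j <- match(surv, fil$id)
          if (!is.na(j)) {
            state <- bank_load(state, fil[j, ],
                               params$W3 * (t_sec - my$attach_sec[m]))
          }
        }
      }
    }
    # teardown detaching filaments
    for (i in seq_len(nrow(over))) {
      state <- remove_whole_filament(state, over[i, ])
    }
    # survivors bank their share in the persisted loads
    for (key in names(gains)[gains > 0]) {
      row <- fil[fil$id == as.integer(key), ]
      state <- bank_load(state, row, gains[[key]])
    }
    events[[pass]] <- tibble::tibble(
      n_detached = nrow(over),
      monomers_released = sum(over$length),
      load_redistributed = redistributed,
      load_discarded = discarded)
  }
  list(state = state,
       events = if (length(events) > 0) dplyr::bind_rows(events)
                else tibble::tibble(n_detached = integer(),
                                    monomers_released = integer(),
                                    load_redistributed = numeric(),
                                    load_discarded = numeric()))
}

remove_whole_filament <- function(state, fil_row) {
  code <- ori_code(fil_row$orientation)
  axis <- ori_axis(code)
  x <- fil_row$x_pointed; y <- fil_row$y_pointed
  # freeze live myosin contributions onto partner chains first: handled
  # implicitly because partner loads were snapshot in the caller via
  # filament_loads; here links simply dissolve
  for (k in seq_len(fil_row$length)) {
    state <- drop_monomer(state, x, y, axis)
    if (k < fil_row$length) {
      nxt <- step_pos(state, x, y, code)
      x <- nxt["x"]; y <- nxt["y"]
    }
  }
  # drop its persisted load rows
  if (nrow(state$loads) > 0) {
    hit <- state$loads$ori == code & state$loads$px == fil_row$x_pointed &
      state$loads$py == fil_row$y_pointed
    state$loads <- state$loads[!hit, ]
  }
  state
}

bank_load <- function(state, fil_row, amount) {
  code <- ori_code(fil_row$orientation)
  hit <- state$loads$ori == code & state$loads$px == fil_row$x_pointed &
    state$loads$py == fil_row$y_pointed
  if (any(hit)) {
    state$loads$accrued[hit] <- state$loads$accrued[hit] + amount
  } else {
    state$loads <- dplyr::bind_rows(
      state$loads,
      tibble::tibble(ori = code, px = fil_row$x_pointed,
                     py = fil_row$y_pointed, accrued = amount))
  }
  state
}
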