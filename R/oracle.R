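#' Exact enumeration of miniature lattice systems
#'
#' For validation of the sampling kernel, tiny actin-only (optionally
#' actin + crosslinker) systems on closed lattices can be enumerated
#' exhaustively and their exact stationary distribution computed from
#' the one-step transition matrix implied by the Monte Carlo rules.
#' Myosin is excluded: its time-dependent load makes the chain
#' non-homogeneous.
#'
#' A state records each slot's orientation, each monomer's bonded-behind
#' flag, and each edge's crosslinker (with its endpoint axis pair);
#' insertion-time stamps are not part of the state because no transition
#' probability depends on them.
#'
#' @param params A [cortex_params()] with `N0[3] == 0` and a closed
#'   lattice of at most 12 slots.
#' @param max_states Safety cap on the enumeration.
#' @return For `enumerate_states()`, a list of state descriptors (lists
#'   with `vert`, `horiz`, `vbond`, `hbond`, `ac` integer vectors).
#' @examples
#' p <- cortex_params(actin = species_params(-1, 1, gamma = 0, E_link = 1),
#'                    width = 1, height = 1, periodic = FALSE)
#' length(enumerate_states(p)) # 5
#' @export
enumerate_states <- function(params, max_states = 2e5) {
  stopifnot(inherits(params, "cortex_params"))
  if (params$periodic) stop("the oracle uses closed lattices")
  if (params$N0[3] > 0) stop("myosin-bearing systems are not enumerable")
  W <- params$width; H <- params$height
  n <- W * H
  if (2 * n > 12) stop("lattice too large to enumerate (more than 12 slots)")
  N1 <- params$N0[1]; N2 <- params$N0[2]

  node_xy <- function(i) c(x = (i - 1) %% W + 1, y = (i - 1) %/% W + 1)
  idx <- function(x, y) (y - 1) * W + x

  # slot assignments under the conservation cap
  states <- list(list(vert = integer(n), horiz = integer(n),
                      vbond = integer(n), hbond = integer(n)))
  for (i in seq_len(n)) {
    for (field in c("vert", "horiz")) {
      vals <- if (field == "vert") c(0L, 1L, 2L) else c(0L, 3L, 4L)
      states <- unlist(lapply(states, function(s) {
        lapply(vals, function(v) { s[[field]][i] <- v; s })
      }), recursive = FALSE)
      states <- Filter(function(s) sum(s$vert > 0) + sum(s$horiz > 0) <= N1,
                       states)
      if (length(states) > max_states) stop("state space exceeds max_states")
    }
  }
  # bond flags: a monomer may be bonded only to a same-orientation
  # neighbour behind it
  behind_idx <- function(s, i, code) {
    xy <- node_xy(i)
    d <- ori_step(flip_ori(code))
    bx <- xy["x"] + d[, "dx"]; by <- xy["y"] + d[, "dy"]
    if (bx < 1 || bx > W || by < 1 || by > H) return(NA_integer_)
    idx(bx, by)
  }
  expand_bonds <- function(s, field, bfield) {
    out <- list(s)
    for (i in seq_len(n)) {
      code <- s[[field]][i]
      if (code == 0L) next
      b <- behind_idx(s, i, code)
      can_bond <- !is.na(b) && s[[field]][b] == code
      if (can_bond) {
        out <- unlist(lapply(out, function(ss) {
          lapply(c(0L, 1L), function(fl) { ss[[bfield]][i] <- fl; ss })
        }), recursive = FALSE)
      }
    }
    out
  }
  states <- unlist(lapply(states, expand_bonds, field = "vert",
                          bfield = "vbond"), recursive = FALSE)
  states <- unlist(lapply(states, expand_bonds, field = "horiz",
                          bfield = "hbond"), recursive = FALSE)

  # crosslinker occupancy per edge: 0 (empty) or 1..4 encoding the
  # endpoint axis pair (vv, vh, hv, hh)
  edges <- oracle_edges(W, H)
  if (N2 > 0 && nrow(edges) > 0) {
    states <- unlist(lapply(states, function(s) {
      s$ac <- integer(nrow(edges))
      opts_per_edge <- lapply(seq_len(nrow(edges)), function(e) {
        c(0L, oracle_ac_options(s, edges[e, ], params, W, H))
      })
      combos <- expand.grid(opts_per_edge, KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(combos)), function(r) {
        s$ac <- as.integer(unlist(combos[r, ]))
        if (sum(s$ac > 0) > N2) return(NULL)
        s
      })
    }), recursive = FALSE)
    states <- Filter(Negate(is.null), states)
  } else {
    states <- lapply(states, function(s) { s$ac <- integer(nrow(edges)); s })
  }
  if (length(states) > max_states) stop("state space exceeds max_states")
  states
}

oracle_edges <- function(W, H) {
  rows <- list()
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (x < W) rows[[length(rows) + 1]] <- c(x = x, y = y, dir = 0L)
    if (y < H) rows[[length(rows) + 1]] <- c(x = x, y = y, dir = 1L)
  }
  if (length(rows) == 0) {
    return(data.frame(x = integer(), y = integer(), dir = integer()))
  }
  as.data.frame(do.call(rbind, rows))
}

# eligible endpoint-axis pair codes at an edge of an oracle state, in
# the pinned order vv=1, vh=2, hv=3, hh=4
oracle_ac_options <- function(s, edge, params, W, H) {
  idx <- function(x, y) (y - 1) * W + x
  a <- idx(edge$x, edge$y)
  b <- if (edge$dir == 0) idx(edge$x + 1, edge$y) else idx(edge$x, edge$y + 1)
  cid <- oracle_chain_ids(s, W, H)
  lens <- table(c(cid$vert[cid$vert > 0], cid$horiz[cid$horiz > 0]))
  out <- integer(0)
  for (aa in 0:1) {
    oa <- if (aa == 0) s$vert[a] else s$horiz[a]
    if (oa == 0) next
    for (ab in 0:1) {
      ob <- if (ab == 0) s$vert[b] else s$horiz[b]
      if (ob == 0) next
      fa <- if (aa == 0) cid$vert[a] else cid$horiz[a]
      fb <- if (ab == 0) cid$vert[b] else cid$horiz[b]
      if (fa == fb) next
      if (!params$ac_link_oligomers &&
          (lens[[as.character(fa)]] < 3 || lens[[as.character(fb)]] < 3)) next
      out <- c(out, aa * 2L + ab + 1L)
    }
  }
  out
}

# chain ids per slot of an oracle state (0 = empty)
oracle_chain_ids <- function(s, W, H) {
  n <- W * H
  vert <- integer(n); horiz <- integer(n)
  id <- 0L
  node_xy <- function(i) c((i - 1) %% W + 1, (i - 1) %/% W + 1)
  idx <- function(x, y) (y - 1) * W + x
  for (field in c("vert", "horiz")) {
    bfield <- if (field == "vert") "vbond" else "hbond"
    tgt <- if (field == "vert") "vert" else "horiz"
    for (i in seq_len(n)) {
      code <- s[[field]][i]
      if (code == 0L || s[[bfield]][i] == 1L) next
      id <- id + 1L
      cur <- i
      repeat {
        if (field == "vert") vert[cur] <- id else horiz[cur] <- id
        xy <- node_xy(cur)
        d <- ori_step(code)
        nx <- xy[1] + d[, "dx"]; ny <- xy[2] + d[, "dy"]
        if (nx < 1 || nx > W || ny < 1 || ny > H) break
        nxt <- idx(nx, ny)
        if (s[[field]][nxt] != code || s[[bfield]][nxt] != 1L) break
        cur <- nxt
      }
    }
  }
  list(vert = vert, horiz = horiz)
}

#' @rdname enumerate_states
#' @param states The list returned by `enumerate_states()` (recomputed
#'   when omitted).
#' @return For `stationary_distribution()`, a list with `pi` (the
#'   stationary probability vector), `states`, `transition` (the dense
#'   transition matrix) and `expected_monomers`.
#' @export
stationary_distribution <- function(params, states = NULL) {
  if (is.null(states)) states <- enumerate_states(params)
  W <- params$width; H <- params$height
  n <- W * H
  edges <- oracle_edges(W, H)
  key <- function(s) paste(c(s$vert, s$horiz, s$vbond, s$hbond, s$ac),
                           collapse = ",")
  keys <- vapply(states, key, character(1))
  lookup <- stats::setNames(seq_along(states), keys)
  S <- length(states)
  Tm <- matrix(0, S, S)
  acc <- function(w) min(1, w)  # Metropolis acceptance of a weight
  ins_w <- function(sp_idx, count) {
    spp <- species_params(params$mu0[sp_idx], params$N0[sp_idx],
                          params$gamma[sp_idx], params$E_link[sp_idx])
    insertion_probability(chemical_potential(spp, count, params$log_base))
  }
  for (si in seq_len(S)) {
    s <- states[[si]]
    for (node in seq_len(n)) {
      # ---- actin sub-move: orientation draw 1/4 each ----
      inter <- list()  # list of (state, prob) after the actin part
      for (o in 1:4) {
        s2 <- s; p <- 0.25
        field <- if (o <= 2) "vert" else "horiz"
        bfield <- if (o <= 2) "vbond" else "hbond"
        occ <- s[[field]][node]
        n1 <- sum(s$vert > 0) + sum(s$horiz > 0)
        if (occ == 0L) {
          res1 <- params$N0[1] - n1
          if (res1 >= 1) {
            pa <- acc(ins_w(1, n1))
            if (pa > 0) {
              s3 <- s
              s3[[field]][node] <- o
              b <- oracle_behind(node, o, W, H)
              s3[[bfield]][node] <-
                if (!is.na(b) && s[[field]][b] == o) 1L else 0L
              inter[[length(inter) + 1]] <- list(s3, p * pa)
              p <- p * (1 - pa)
            }
          }
          if (p > 0) inter[[length(inter) + 1]] <- list(s, p)
        } else {
          rm_out <- oracle_remove(s, node, occ, field, bfield, params, W, H,
                                  edges)
          if (is.null(rm_out)) {
            inter[[length(inter) + 1]] <- list(s, p)
          } else {
            if (rm_out$prob > 0) {
              inter[[length(inter) + 1]] <- list(rm_out$state, p * rm_out$prob)
            }
            if (rm_out$prob < 1) {
              inter[[length(inter) + 1]] <- list(s, p * (1 - rm_out$prob))
            }
          }
        }
      }
      # ---- crosslinker sub-move on the two edges from this node ----
      for (it in inter) {
        s_mid <- it[[1]]; p_mid <- it[[2]]
        for (d in 0:1) {
          p_edge <- p_mid * 0.5
          xy <- c((node - 1) %% W + 1, (node - 1) %/% W + 1)
          valid <- if (d == 0) xy[1] < W else xy[2] < H
          if (!valid || params$N0[2] == 0) {
            ti <- lookup[[key(s_mid)]]
            Tm[si, ti] <- Tm[si, ti] + p_edge / n
            next
          }
          eidx <- which(edges$x == xy[1] & edges$y == xy[2] & edges$dir == d)
          if (s_mid$ac[eidx] > 0L) {
            pr <- acc(removal_probability(2 * params$E_link[2]))
            s_rm <- s_mid; s_rm$ac[eidx] <- 0L
            Tm[si, lookup[[key(s_rm)]]] <- Tm[si, lookup[[key(s_rm)]]] +
              p_edge * pr / n
            Tm[si, lookup[[key(s_mid)]]] <- Tm[si, lookup[[key(s_mid)]]] +
              p_edge * (1 - pr) / n
          } else {
            n2 <- sum(s_mid$ac > 0)
            opts <- if (params$N0[2] - n2 >= 1) {
              oracle_ac_options(s_mid, edges[eidx, ], params, W, H)
            } else integer(0)
            if (length(opts) == 0) {
              Tm[si, lookup[[key(s_mid)]]] <- Tm[si, lookup[[key(s_mid)]]] +
                p_edge / n
            } else {
              pa <- acc(ins_w(2, n2))
              for (op in opts) {
                s_in <- s_mid; s_in$ac[eidx] <- op
                Tm[si, lookup[[key(s_in)]]] <- Tm[si, lookup[[key(s_in)]]] +
                  p_edge * pa / (length(opts) * n)
              }
              Tm[si, lookup[[key(s_mid)]]] <- Tm[si, lookup[[key(s_mid)]]] +
                p_edge * (1 - pa) / n
            }
          }
        }
      }
    }
  }
  # stationary vector: solve pi' T = pi' with sum(pi) = 1
  A <- t(Tm) - diag(S)
  A[S, ] <- 1
  b <- c(rep(0, S - 1), 1)
  pi_vec <- solve(A, b)
  nm <- vapply(states, function(s) sum(s$vert > 0) + sum(s$horiz > 0),
               numeric(1))
  list(pi = pi_vec, states = states, transition = Tm,
       expected_monomers = sum(pi_vec * nm))
}

oracle_behind <- function(node, code, W, H) {
  x <- (node - 1) %% W + 1; y <- (node - 1) %/% W + 1
  d <- ori_step(flip_ori(code))
  bx <- x + d[, "dx"]; by <- y + d[, "dy"]
  if (bx < 1 || bx > W || by < 1 || by > H) return(NA_integer_)
  (by - 1) * W + bx
}

# removal outcome of the occupied slot (NULL when removal is forbidden)
oracle_remove <- function(s, node, code, field, bfield, params, W, H, edges) {
  bonded <- s[[bfield]][node] == 1L
  # front neighbour bonded to this monomer?
  x <- (node - 1) %% W + 1; y <- (node - 1) %/% W + 1
  d <- ori_step(code)
  fx <- x + d[, "dx"]; fy <- y + d[, "dy"]
  front <- if (fx < 1 || fx > W || fy < 1 || fy > H) NA_integer_
           else (fy - 1) * W + fx
  front_bonded <- !is.na(front) && s[[field]][front] == code &&
    s[[bfield]][front] == 1L
  if (bonded && front_bonded && params$forbid_interior_removal) return(NULL)
  axis0 <- if (field == "vert") 0L else 1L
  n_ac <- 0L
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      if (s$ac[e] == 0L) next
      pair <- s$ac[e] - 1L
      aa <- pair %/% 2L; ab <- pair %% 2L
      a <- (edges$y[e] - 1) * W + edges$x[e]
      b <- if (edges$dir[e] == 0) a + 1L else a + W
      if ((a == node && aa == axis0) || (b == node && ab == axis0)) {
        n_ac <- n_ac + 1L
      }
    }
  }
  E <- params$E_link[1] + (if (bonded) params$E0 else 0) +
    n_ac * params$E_link[2]
  pr <- min(1, removal_probability(E))
  s2 <- s
  s2[[field]][node] <- 0L
  s2[[bfield]][node] <- 0L
  if (front_bonded) s2[[bfield]][front] <- 0L
  # dissolve crosslinkers touching the slot
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      if (s2$ac[e] == 0L) next
      pair <- s2$ac[e] - 1L
      aa <- pair %/% 2L; ab <- pair %% 2L
      a <- (edges$y[e] - 1) * W + edges$x[e]
      b <- if (edges$dir[e] == 0) a + 1L else a + W
      if ((a == node && aa == axis0) || (b == node && ab == axis0)) {
        s2$ac[e] <- 0L
      }
    }
  }
  list(state = s2, prob = pr)
}
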