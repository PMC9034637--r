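# shared builders for hand-constructed lattice states

`%||%` <- function(a, b) if (is.null(a)) b else a

# miniature closed-lattice configurations for the exact-enumeration oracle
oracle_params <- function(mu, E1, N0, W = 1, H = 1, gamma = 0, E0 = 2,
                          N2 = 0, mu2 = -1, E2 = 2, ac_any = FALSE) {
  cortex_params(actin = species_params(mu, N0, gamma, E1),
                crosslinker = species_params(mu2, N2, 0, E2),
                E0 = E0, width = W, height = H, periodic = FALSE,
                ac_link_oligomers = ac_any)
}

actin_only <- function(mu0 = -5, N0 = 100, gamma = 0, E1 = 3, W = 8, H = 8,
                       ...) {
  cortex_params(actin = species_params(mu0, N0, gamma, E1),
                width = W, height = H, ...)
}

three_species <- function(W = 8, H = 8, N1 = 200, N2 = 50, N3 = 50,
                          E1 = 2, E2 = 3, E3 = 3, ...) {
  cortex_params(actin = species_params(-1, N1, 1, E1),
                crosslinker = species_params(-1, N2, 1, E2),
                myosin = species_params(-1, N3, 1, E3),
                width = W, height = H, ...)
}

# place a bonded run of `len` monomers with the given orientation,
# starting at the pointed end (x, y)
place_run <- function(state, x, y, orientation, len) {
  code <- cortexmc:::ori_code(orientation)
  for (k in seq_len(len)) {
    state <- place_monomer(state, x, y, orientation)
    if (k < len) {
      nxt <- cortexmc:::step_pos(state, x, y, code)
      x <- nxt["x"]; y <- nxt["y"]
    }
  }
  state
}

# brute-force connected components of filaments via pairwise link union
brute_networks <- function(state) {
  fil <- find_filaments(state)
  if (nrow(fil) == 0) return(integer(0))
  cm <- cortexmc:::chain_map(state)
  links <- rbind(as.data.frame(state$acs[, 1:6]),
                 if (nrow(state$myosins) > 0)
                   as.data.frame(state$myosins[state$myosins$active == 1L, 1:6]))
  memb <- as.list(fil$id)
  if (!is.null(links) && nrow(links) > 0) {
    repeat {
      merged <- FALSE
      for (i in seq_len(nrow(links))) {
        fa <- cortexmc:::chain_id_at(cm, links$xa[i], links$ya[i], links$axa[i])
        fb <- cortexmc:::chain_id_at(cm, links$xb[i], links$yb[i], links$axb[i])
        if (is.na(fa) || is.na(fb)) next
        if (!(fa %in% fil$id) || !(fb %in% fil$id) || fa == fb) next
        ia <- which(vapply(memb, function(m) fa %in% m, logical(1)))
        ib <- which(vapply(memb, function(m) fb %in% m, logical(1)))
        if (ia != ib) {
          memb[[ia]] <- union(memb[[ia]], memb[[ib]])
          memb[[ib]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  sizes <- vapply(memb, function(m) sum(fil$length[fil$id %in% m]), numeric(1))
  nfil <- vapply(memb, length, integer(1))
  sort(sizes[nfil >= 2], decreasing = TRUE)
}

# mean and batch-means standard error of a (possibly autocorrelated) series
batch_se <- function(x, nb = 40) {
  b <- tapply(x, rep(seq_len(nb), each = ceiling(length(x) / nb))[seq_along(x)],
              mean)
  stats::sd(b) / sqrt(length(b))
}
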