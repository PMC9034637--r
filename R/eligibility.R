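#' Crosslinker and myosin edge eligibility
#'
#' A crosslinker may occupy a lattice edge when the two endpoint nodes
#' hold monomers belonging to two *distinct* filaments, in any relative
#' orientation (parallel, anti-parallel or perpendicular), and the edge
#' does not already carry a crosslinker.  A myosin additionally requires
#' the two filaments to be anti-parallel (opposite orientations on the
#' same axis) and the edge's myosin slot to be free.
#'
#' When a node holds monomers on both axes, any occupied axis pair may
#' qualify; these functions return `TRUE` if at least one pair does.
#' With `params$ac_link_oligomers = TRUE` the crosslinker rule is relaxed
#' to any two monomers on distinct chains (no filament-length
#' requirement).
#'
#' @param state A [cortex_state()].
#' @param xa,ya Base node of the edge.
#' @param xb,yb Adjacent node of the edge.
#' @param params A [cortex_params()] (only the `ac_link_oligomers` flag
#'   is consulted for `ac_eligible()`).
#' @return `TRUE` or `FALSE`.
#' @export
ac_eligible <- function(state, xa, ya, xb, yb,
                        params = cortex_params()) {
  if (edge_occupied_nodes(state$acs, state, xa, ya, xb, yb)) return(FALSE)
  length(eligible_axis_pairs(state, xa, ya, xb, yb,
                             antiparallel = FALSE,
                             ac_any = params$ac_link_oligomers)) > 0
}

#' @rdname ac_eligible
#' @export
myosin_eligible <- function(state, xa, ya, xb, yb,
                            params = cortex_params()) {
  if (edge_occupied_nodes(state$myosins, state, xa, ya, xb, yb)) return(FALSE)
  length(eligible_axis_pairs(state, xa, ya, xb, yb,
                             antiparallel = TRUE, ac_any = FALSE)) > 0
}

edge_occupied_nodes <- function(links, state, xa, ya, xb, yb) {
  if (nrow(links) == 0) return(FALSE)
  any((links$xa == xa & links$ya == ya & links$xb == xb & links$yb == yb) |
      (links$xa == xb & links$ya == yb & links$xb == xa & links$yb == ya))
}

# candidate endpoint-axis pairs at an edge, in the pinned order
# (vert,vert), (vert,horiz), (horiz,vert), (horiz,horiz); axis codes are
# 0-based as in the link tables
eligible_axis_pairs <- function(state, xa, ya, xb, yb, antiparallel, ac_any) {
  check_coords(state, xa, ya); check_coords(state, xb, yb)
  dx <- xb - xa; dy <- yb - ya
  if (state$periodic) {
    dx <- ((dx %% state$width) + state$width) %% state$width
    if (dx == state$width - 1) dx <- -1
    dy <- ((dy %% state$height) + state$height) %% state$height
    if (dy == state$height - 1) dy <- -1
  }
  if (abs(dx) + abs(dy) != 1) stop("edge endpoints must be adjacent nodes")
  cm <- chain_map(state)
  lens <- stats::setNames(cm$chains$length, cm$chains$id)
  out <- list()
  for (aa in 0:1) {
    oa <- (if (aa == 0) state$vert_ori else state$horiz_ori)[xa, ya]
    if (oa == 0) next
    for (ab in 0:1) {
      ob <- (if (ab == 0) state$vert_ori else state$horiz_ori)[xb, yb]
      if (ob == 0) next
      fa <- chain_id_at(cm, xa, ya, aa)
      fb <- chain_id_at(cm, xb, yb, ab)
      if (fa == fb) next
      if (!ac_any || antiparallel) {
        if (lens[[as.character(fa)]] < 3 || lens[[as.character(fb)]] < 3) next
      }
      if (antiparallel && !is_antiparallel(oa, ob)) next
      out[[length(out) + 1]] <- c(axa = aa, axb = ab)
    }
  }
  out
}

is_antiparallel <- function(o1, o2) o2 == flip_ori(o1)
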