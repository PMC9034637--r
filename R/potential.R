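#' Semi-grand-canonical chemical potential
#'
#' Computes \eqn{\mu_i = \mu_{i,0} - \gamma_i \log(N_i / N_{i,0})} for a
#' species with `N_on_grid` molecules currently on the lattice.  At
#' `N_on_grid = 0` with `gamma > 0` the potential diverges; `+Inf` is
#' returned and acts as a certain-acceptance sentinel in the Metropolis
#' comparison.
#'
#' @param species A [species_params()] object.
#' @param N_on_grid Current number of molecules of the species on the
#'   lattice, `0 <= N_on_grid <= N0`.
#' @param log_base Base of the logarithm (natural by default).
#' @return The potential in RT units (possibly `Inf`).
#' @examples
#' chemical_potential(species_params(-5, 3000, gamma = 2), 3000) # -5
#' chemical_potential(species_params(-5, 3000, gamma = 2), 1)    # -5 + 2 log(3000)
#' @export
chemical_potential <- function(species, N_on_grid, log_base = exp(1)) {
  stopifnot(inherits(species, "species_params"))
  if (N_on_grid < 0 || N_on_grid > species$N0) {
    stop("N_on_grid must lie in [0, N0]; conservation is violated otherwise")
  }
  if (species$gamma == 0) return(species$mu0)
  if (N_on_grid == 0) return(Inf)
  species$mu0 - species$gamma * log(N_on_grid / species$N0, base = log_base)
}

#' Insertion and removal acceptance weights
#'
#' `insertion_probability()` returns the Metropolis weight
#' \eqn{P^+ = e^{\mu}} for moving a molecule from the reservoir onto the
#' lattice; values above 1 are legal and mean certain acceptance.
#' `removal_probability()` returns \eqn{P^- = e^{-E}} for the reverse
#' move, where `E_total` is the summed energy of every link holding the
#' molecule at the cortex.
#'
#' @param mu Chemical potential (RT).
#' @param E_total Total link energy (RT), non-negative.
#' @return A non-negative acceptance weight.
#' @examples
#' insertion_probability(0)            # 1
#' removal_probability(1)              # exp(-1): terminal pointed-end monomer at E1 = 1
#' removal_probability(12 + 1) / removal_probability(1) # exp(-12): interior suppression
#' @export
insertion_probability <- function(mu) exp(mu)

#' @rdname insertion_probability
#' @export
removal_probability <- function(E_total) {
  stopifnot(E_total >= 0)
  exp(-E_total)
}

#' Metropolis acceptance
#'
#' Draws one uniform variate `u` from the current RNG stream and accepts
#' when `u < P`.  `P >= 1` therefore always accepts and `P = 0` always
#' rejects.
#'
#' @param P Acceptance weight, `P >= 0`.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
metropolis_accept <- function(P) {
  stopifnot(P >= 0)
  stats::runif(1) < P
}
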