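---
title: "Methods: a semi-grand-canonical lattice model of the actomyosin cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-grand-canonical lattice model of the actomyosin cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cortexmc` simulates a coarse-grained actomyosin cortex: a two-dimensional
square lattice (the inner face of the plasma membrane) exchanging three
molecular species with a finite, perfectly mixed cytoplasmic reservoir --
G-actin monomers, actin crosslinkers (ACs, standing in for fascin,
α-actinin and similar bundlers), and bipolar myosin II minifilaments.
Each lattice node holds at most one vertically oriented monomer (north or
south) and one horizontally oriented monomer (east or west), so
perpendicular filaments may overlap; crosslinkers and myosin occupy the
edges between adjacent nodes (at most one of each per edge).  Molecules
never move or rotate on the lattice: all dynamics is insertion and
removal.

Because the reservoir is finite, the system is *semi-grand-canonical*:
the insertion weight of species $i$ is $P^+ = e^{\mu_i}$ with

$$\mu_i = \mu_{i,0} - \gamma_i \,\log\!\frac{N_i}{N_{i,0}},$$

where $N_i$ is the number of molecules of species $i$ currently on the
lattice, $N_{i,0}$ the fixed total, $\mu_{i,0}$ a reference potential and
$\gamma_i$ a form factor.  Removal of a molecule held by links of total
energy $E$ has weight $P^- = e^{-E}$.  All energies are in units of the
thermal energy RT (2.47 kJ/mol).  Both weights enter a Metropolis
comparison against one uniform variate; weights above one mean certain
acceptance.  An empty lattice with $\gamma_i > 0$ makes $\mu_i$ diverge;
the implementation treats this as the certain-acceptance sentinel rather
than a numerical fault.  The logarithm is natural by default, consistent
with the exponential acceptance weights, and is configurable
(`log_base`) for sensitivity checks.

## The move set

One *iteration* draws a single lattice position and evaluates the three
species in the fixed order actin → crosslinker → myosin (the order is
irrelevant at stationarity but pinned for reproducibility).  The RNG
draw order is documented and fixed: position x, position y, actin
orientation, [actin acceptance], edge direction, [AC pair tie-break],
[AC acceptance], [myosin pair tie-break], [myosin acceptance]; bracketed
draws are consumed only when the corresponding attempt is evaluated.
Identical seed and configuration therefore give bitwise-identical
trajectories.

**Actin.** An orientation is drawn uniformly among north, south, east,
west.  If the corresponding axis slot at the sampled node is empty, an
insertion is attempted with $P^+ = e^{\mu_1}$; if it is occupied, removal
of that monomer is attempted.  This single pinned rule reproduces both
conventions the sampling scheme needs: on a doubly occupied node the
removal axis is effectively drawn uniformly, and on an empty node every
orientation is equally likely.  A monomer inserted directly in front of
the barbed end of a run of identically oriented monomers forms a polymer
bond of energy $E_0$ and joins that chain; every monomer also receives a
membrane anchor of energy $E_1$.  A chain of three or more monomers is a
filament (the trimer is the polymerization nucleus).  The *pointed-end*
terminal monomer of every chain has its polymer bond destabilised: its
removal costs only $E_1$ (plus any linker energies), while interior and
barbed-side monomers carry the extra $E_0 \approx 12$ RT, making their
removal about five orders of magnitude less probable.  By default
interior removal is forbidden outright (`forbid_interior_removal`),
making the rule-level statement "filaments never break" exact; the
suppression can be made soft for sensitivity analysis.  Barbed-end
growth plus pointed-end decay yields treadmilling.

**Chain identity is bond-based.** A monomer landing *behind* a pointed
end, or between two collinear chains, does not fuse runs into one
filament: bonds form only at insertion in front of a barbed end.  This
keeps filament identity stable (needed for load bookkeeping) at the cost
of allowing a same-orientation "blocker" to stall a filament's growth
until the blocker happens to leave.  This choice caps filament length in
dense regimes, which is the main known divergence from behaviours that
presume long, freely grown filaments (see *Limitations*).

**Crosslinkers.** An edge is AC-eligible when its two endpoint nodes
hold monomers of two *distinct* filaments in any relative orientation
(parallel, anti-parallel, perpendicular).  Insertion uses
$P^+ = e^{\mu_2}$ and registers energy $E_2$ on both endpoint monomers;
removal must release both links at once, $P^- = e^{-2E_2}$.  When
several endpoint axis pairs qualify (nodes can hold two monomers), one
is drawn uniformly in a pinned order.  Linking to oligomers (chains
shorter than three) is disallowed by default and available as
`ac_link_oligomers`, which the exact-enumeration oracle uses.

**Myosin.** Identical mechanics with $(\mu_3, E_3)$, but eligibility
requires the two filaments to be *anti-parallel* (opposite orientations
on the same axis): between parallel filaments the motor would only
translocate, with no state change at this resolution.  Because
cortex-attached filaments cannot slide, an attached motor converts
attachment time into elastic load: a filament bridged by $n$ active
myosins carries

$$E_\mathrm{load} = \sum_{i=1}^{n} W_3\, t_i,$$

with $W_3$ the motor power (RT per calibrated second) and $t_i$ the time
since myosin $i$ attached; each myosin loads *both* filaments it
bridges.  Loads only accumulate: when a myosin detaches (or its bridge
breaks because a partner shrank below three monomers), its contribution
up to that moment is frozen onto the filaments rather than released.  A
bridge-broken myosin stops generating force, its timer freezes, and it
is returned to the reservoir deterministically at its next removal
evaluation -- a Metropolis draw there would leave a force-less molecule
with no defined link energy.

**Detachment and redistribution.** After every iteration, any filament
whose load strictly exceeds its membrane anchoring capacity
$E_\mathrm{threshold} = E_1 \times L$ (recomputed from the current
length $L$) detaches whole: its monomers, crosslinkers and myosins
return to their reservoirs, and its load is split equally among the
filaments remaining in its network (the connected component over
AC/active-myosin links at the moment of detachment).  A network-less
filament's load is discarded.  All over-threshold filaments in a pass
detach simultaneously, then loads redistribute, then the check repeats:
redistribution can push survivors over threshold, so collapses cascade.
This cooperative collapse, racing against cooperative AC-driven
assembly, is the oscillation mechanism.

## Time calibration

The simulation clock advances one *sweep-unit* per $2WH$ iterations (the
slot capacity of a $W \times H$ lattice), which makes runs on different
lattice sizes comparable.  Physical units come from an in-vivo
reference: cortical F-actin networks reach equilibrium in about 18
minutes.  `calibrate_kappa()` runs the actin-only reference condition
(`cortex_preset("fig1")`), detects the equilibration point of the
occupancy series -- first entry into a ±5% band around the long-run
plateau that is sustained for 20% of the run -- averages it over seeds,
and sets $\kappa$ (minutes per sweep-unit) so that this point maps to 18
min.  Both thresholds are exposed.  The filament-bound actin series was
considered as the detection observable but rejected: it coarsens
logarithmically without a stable plateau on practical run lengths,
making the detector seed-unstable, whereas occupancy settles cleanly.

## Default parameters and why

* **Lattice 25×25, periodic.**  The lattice must be small relative to
  the actin budget.  Filament elongation requires the insertion weight
  to beat pointed-end decay, $e^{\mu_1} > 2e^{-E_1}$ under this move
  set, while the free-monomer gas alone equilibrates at slot occupancy
  $f$ with $f/(1-f) = e^{\mu_1 + E_1}$; eliminating $\mu_1$ shows
  cooperative polymerization needs the gas to reach two thirds of the
  $2WH$ slot capacity.  With budgets $N_{1,0} = 2000\text{--}6000$ a
  lattice of capacity 1250 sits safely below them and exhibits the full
  phenomenology (polymerization transition, network takeover,
  whole-cortex oscillation); a lattice of capacity comparable to
  $N_{1,0}$ can never leave the dilute-gas regime.  Periodic boundaries
  avoid edge artifacts in treadmilling and network statistics; closed
  boundaries are available and are used by the enumeration oracle.
* **$E_0 = 12$ RT** from the 30 kJ/mol bond estimate at RT = 2.47
  kJ/mol (`actin_bond_energy()`).
* **$W_3 = 3\times10^{-4}$ RT/s.**  Not tabulated by any preset; chosen
  once as the smallest value on a half-decade grid that sustains
  whole-cortex oscillations at the `fig5bcd` preset on the calibrated
  axis -- operationally: at least ten complete cycles in a
  4000-sweep-unit window (matching the period-measurement protocol), a
  dominant Fourier peak at least 5× the median spectral power, and
  peak-to-trough amplitude of at least 25% of the mean cortical actin,
  on a majority of three seeds.  One half-decade lower fails the cycle
  count; higher values oscillate faster with smaller amplitude until
  the dynamics degrades into local, aperiodic pruning.
* **Presets** carry the tabulated parameter rows for the standard study
  conditions; cells that a condition sweeps hold a documented base
  value, and `sweep_cortex()` performs the sweeps.  The tabulated
  crosslinker count of the `fig5bcd` row is ambiguous; 3000 is adopted
  because every other column of that row uses $\gamma = 1$, $E = 3$ and
  the companion row confirms $E_1 = 1$ as the control.

## Validation strategy

Every formula-level operation exists twice: in the compiled kernel and
as plain R queries (`find_filaments()`, `monomer_link_energy()`,
`find_networks()`, `total_tension()`, the `attempt_*()` moves,
`process_detachments()`).  Tests cross-check the two routes on
identical states, and network detection additionally against a
brute-force pairwise-union oracle.  The sampling loop itself is
validated against `enumerate_states()` / `stationary_distribution()`:
exact stationary vectors of miniature closed-lattice systems (up to ~300
states, actin-only and actin+AC), built from the same
transition rules but solved by linear algebra, independent of the
kernel.  Long kernel runs match the exact expected occupancy within
three batch-means standard errors on every tested system, including
bonded chains and crosslinker coupling.  Myosin's time-dependent load
makes the chain non-homogeneous and is validated instead by
property tests: load arithmetic, strict-inequality thresholds,
redistribution bookkeeping (tension before a cascade equals tension
after plus the discarded amount), and cascade semantics.

The simulator **is** the data generator here -- there is no external
data.  What passing tests show is therefore internal: that the
implementation realises the stated transition rules exactly, and that
the emergent behaviours (three-phase polymerization, critical monomer
concentration, treadmilling orderings, network thresholds, anti-phase
tension oscillations) follow from those rules at the preset conditions.
They do not show that the coarse-grained rules are a quantitative model
of any particular cell cortex: lattice anisotropy (two directions only),
single-monomer-resolution filaments, instantaneous reservoir mixing and
the absence of severing/capping regulators are all idealisations.

## Numerical choices

* Uniform integer draws are taken as `floor(u * n)` clamped to `n - 1`;
  ties in the AC/myosin endpoint-pair choice are broken by one extra
  uniform draw over the pinned pair order (vv, vh, hv, hh).
* A blocked move (occupied slot on the drawn orientation, ineligible
  edge, exhausted reservoir, forbidden interior removal) consumes no
  acceptance draw.
* Detachment uses strict inequality ($E_\mathrm{load} > E_1 L$), so a
  load exactly at threshold never detaches.
* Zero-iteration runs return an empty trajectory and leave the state
  untouched; series shorter than 8 samples are rejected by the Fourier
  analysis; a constant series reports a peak ratio of 1 ("no
  oscillation").
* The spectral period estimator removes the mean, takes the strongest
  non-zero-frequency bin of the raw periodogram, and reports the
  peak-to-median power ratio as significance; it is exact to one
  frequency bin on sampled sinusoids.
* Filament tracking across snapshots matches same-orientation filaments
  by maximal overlap of occupied cells, ties broken by pointed-end
  proximity, with minimum-image displacement on periodic lattices.
* Interior removal (when enabled) splits a chain and divides any banked
  load between the fragments in proportion to their lengths.

## Problem sizes

The shipped tests run lattices between 1×1 (exact enumeration) and
25×25, with $10^4$ to $10^7$ iterations per run and three seeds for the
stochastic comparatives; the acceptance script calibrates over ten seeds
of 2.5 million iterations and measures the oscillation period on a
5-million-iteration three-species run (about twenty collapse cycles).
These sizes were chosen so the full suite completes in minutes on one
CPU while every comparative claim is resolved across seeds.

## Known limitations

* The bond-based no-fusion chain identity caps filament growth at
  same-orientation blockers in dense regimes; as a consequence the
  length distribution with crosslinkers is *broader* here, not narrower,
  and amplitude trends under stronger anchoring ($E_1$) or more myosin
  run opposite to expectations that presume long unconstrained filaments,
  even though the corresponding period trends reproduce.
* The absolute oscillation period at the default conditions is of order
  two hours on the calibrated axis, an order of magnitude above
  in-vivo periods reported for pulsatile cortices; with the motor power, lattice size and
  equilibration estimate all free, the absolute scale is only weakly
  constrained -- comparative statements (orderings across parameter
  changes) are the robust outputs.
* Oscillation statistics at high myosin counts carry $O(N_3)$ per-event
  bookkeeping; runs beyond $N_{3,0} \sim 10^4$ on large lattices are
  noticeably slower.
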