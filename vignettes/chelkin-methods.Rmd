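---
title: "From coordination states to association constants, rates and mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coordination states to association constants, rates and mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelkin)
```

# The problem

A divalent metal ion M in water exchanges its first-shell waters S for
amine donor groups of a ligand L, populating a ladder of ternary species
ML\_nS\_m.  Three questions about this ladder are of chemical interest:

1. **Thermodynamics** — how stable is each ML\_i relative to the free
   metal, and what stepwise association constants
   K\_i = \[ML\_i\]/(\[ML\_{i-1}\]\[L\]) follow?
2. **Kinetics** — how fast are the formation (k\_i, L mol^-1 s^-1) and
   dissociation (k\_-i, s^-1) steps, given that the interesting ones span
   many orders of magnitude?
3. **Mechanism** — when a donor group enters the first shell, does the
   leaving water depart before (dissociative) or after (associative) the
   nitrogen arrives?

Together these three views quantify the *chelate effect*: the extra
stability of complexes of multidentate ligands over the equivalent number
of monodentate donors at equal coordination number.

`chelkin` implements the analysis layer for these questions.  Its inputs
are coordination-state observables — 2D free-energy surfaces over the
(ligand, water) coordination numbers, coordination-number time series,
and metal–nitrogen/metal–oxygen distance trajectories — regardless of the
engine that produced them.  A first-class synthetic-data module generates
every input with known ground truth, so the entire pipeline is testable
end to end.

# Equilibrium stage

## From surfaces to species levels

A `FreeEnergySurface` is a rectangular grid of free energies (kJ/mol)
over the ligand and water coordination coordinates; unvisited cells carry
`Inf`.  `defaultBasins()` assigns every visited cell to the species whose
ligand coordination matches the cell's rounded ligand coordinate, and
`projectSurfaceToLevels()` aggregates each basin either as a Boltzmann
sum,

$$\Delta G_i = -k_B T \,\ln \sum_{\text{cells} \in i} e^{-F/k_BT},$$

(the default: the basin's integrated statistical weight) or as the basin
minimum.  Published "relative stability" diagrams do not always say which
convention they use, and for one ligand we found the two conventions
differ by the standard-state shift; both modes are therefore exposed and
none is asserted as canonical.  Levels are pinned so the free metal is 0;
every derived pK is invariant under a constant shift of the surface (a
tested invariant).

## Populations, constants and errors

`solveEquilibrium()` interprets the levels as *box-equilibrium* free
energies at the simulated composition: populations are Boltzmann factors
normalised to the total metal concentration, and the free-ligand
concentration comes from the ligand mass balance
$[L] = [L_0] - \sum_i s_i [\mathrm{ML}_i]$.  No self-consistent iteration
is performed — an enhanced-sampling surface already reflects the finite
ligand reservoir of the box it came from.  This is a deliberate
convention: converting to standard-state constants and iterating the
mass-action system is a *different* convention that would double-count
the depletion.  The tests nevertheless verify that the emitted K\_i and
concentrations satisfy the full mass-action system exactly, using an
independent `uniroot` root-finder as oracle.

`pkUncertaintyMC()` propagates the level uncertainties (typically
~2 kJ/mol for converged enhanced-sampling estimates) by redrawing each
level from a normal distribution and re-solving; draws that exhaust the
ligand balance are rejected and counted, and a rejection fraction above
50% aborts with an error rather than returning a silently biased spread.
All Monte Carlo is seed-deterministic.

## Thermodynamic bookkeeping

`thermoDecompose()` closes $\Delta G = \Delta H - T\Delta S$, normalises
by the number of bound donor groups, and `deltaDeltaS()` converts
entropy differences between ligand systems to J mol^-1 K^-1 — the
numbers behind statements like "the chelate gain of ethylenediamine over
two methylamines is ~20 J mol^-1 K^-1 of entropy".  The shipped
reference thermodynamic table is reproduced by the test suite at printed
precision, with two caveats the tests document explicitly: stacked
one-decimal rounding lets a printed triple close only to 0.15 kJ/mol,
and one row (dien\_1) carries a misprinted enthalpy that fails its own
identity by 1.0 kJ/mol.

## Minimum free-energy pathways

`minFreeEnergyPath()` returns the 4-connected grid path between two
coordination states that minimises the highest free energy en route (the
minimax path), located by bisection on the barrier level with flood-fill
connectivity, then traced by breadth-first search.  This is a compact,
exactly testable formulation of lowest-barrier pathway extraction: a
brute-force enumeration oracle over all simple paths verifies it on small
grids.

# Kinetic stage: Markov state models

## Discretisation

`assignMicrostates()` clusters the (ligand, water) coordination frames
with k-means++ seeding and Lloyd iterations (tolerance 1e-6, at most 500
iterations; an emptied cluster is re-seeded from the farthest point).
Centers are fitted on a subsample *balanced across occupied integer
coordination cells*: in a strongly binding system the free-metal state
may hold well under 1% of the frames, and a density-weighted subsample
would starve it of centers — the balanced subsample guarantees every
sampled species can attract one.  Assignment of all frames is a single
nearest-center pass.

## Estimation and validation

`estimateTransitionMatrix()` counts sliding-window transitions at the
chosen lag, restricts to the largest strongly connected component (via
igraph), and row-normalises; the default estimator enforces detailed
balance through the standard self-consistent reversible MLE iteration,
since coordination equilibria are physically reversible.
`impliedTimescales()` ($t_i = -\tau\,\Delta t/\ln\lambda_i$) flags the
smallest lag at which the slow spectrum is lag-independent within 10%,
and `chapmanKolmogorov()` compares the propagated model $T(\tau)^n$
against matrices re-estimated at $n\tau$ (threshold 0.1).  A hidden
two-timescale trap projected onto one observed state is the
non-Markovian counterexample in the tests.

## Coarse-graining

`pccaCoarseGrain()` implements PCCA+: memberships are an affine
transformation of the dominant eigenvector subspace, with the simplex
vertices found by the inner-simplex search (first vertex: row of largest
norm; each next vertex: row farthest from the affine span of those
already chosen), then clipped to the probability simplex and
row-normalised.  Macrostates are mapped to ML\_i species through the
membership-weighted ligand coordination of their member centers, which
on ladder fixtures yields a bijection between macrostates and
coordination numbers.  Ties in the crisp assignment break toward the
lower coordination state, deterministically.

## From first passage times to molar rates

For a box holding one metal, the inverse forward first passage time is a
pseudo-first-order rate $k_i[L]$; dividing by the equilibrium free-ligand
concentration ($[L] = n_\mathrm{lig}^\mathrm{eq}/\gamma$ with
$\gamma = N_{Av} V$ the count-per-molar factor) gives the second-order
molar constant, while the backward rate is first-order and needs no
conversion.  At ratio level this reproduces
$k_i/k_{-i} = K_i$ — the consistency condition that pins the convention,
and the one the package asserts on thermoconsistent fixtures.

Two implementation choices matter here:

* **Per-step rates are local.**  In a multi-step ladder the *global*
  MFPT from ML\_i to ML\_{i-1} includes long excursions through deeper
  coordination states and can overestimate the dissociation time by
  orders of magnitude.  `ratesFromMsm()` therefore uses the first
  passage time of the adjacent-pair restriction of the coarse chain
  ($\tau\,\Delta t/T_{ab}$, the geometric law), which coincides with the
  plain MFPT for a two-state system, recovers the ladder rates of the
  chemical master equation, and keeps $k_i/k_{-i} = K_i$ exact under a
  reversible estimate.  The exported `mfpt()` keeps the full
  linear-solve definition (and is verified against the
  fundamental-matrix oracle to 1e-10).
* **Unobserved steps are flagged, not extrapolated.**  A step whose
  transitions never occur in the data is reported with rate 0 and a
  no-events flag; elusive odd intermediates simply drop out of the
  macrostate set and the merged step is flagged.

`bayesianRateErrors()` samples transition matrices from the per-row
Dirichlet posterior of the counts, pushes every sample through the same
coarse-grained conversion, and reports central 95% intervals; interval
width contracts like the square root of the counts (tested), and the
true rate of simulated fixtures falls inside the interval at the nominal
frequency across repeated experiments.

# The chelate decomposition

Bidentate binding is a two-step reaction: open-ring formation
(one donor bound) followed by ring closure,

$$K^{or} = \frac{k_+^{or}}{k_-^{or}}, \quad
  K^{cr} = \frac{k_+^{cr}}{k_-^{cr}}, \quad
  k_f = \frac{k_+^{or} k_+^{cr}}{k_-^{or} + k_+^{cr}}, \quad
  k_d = \frac{k_-^{or} k_-^{cr}}{k_-^{or} + k_+^{cr}},$$

so that $K_1 = K^{or}K^{cr} = k_f/k_d$ identically
(`chelateDecompose()`; the identity is property-tested over ten orders
of magnitude of random rates).  `limitBehavior()` reports the classical
limits — $k_f \to k_+^{or}$ when ring closure outruns open-ring
dissociation, $k_d \to k_-^{cr}$ in the opposite regime — together with
their exact relative errors, and the qualitative "much greater than" of
the narrative is operationalised as a ratio above 10.
`extractBidentateRates()` bridges a three-macrostate model
(M, open ring, closed ring) to these inputs, converting the ring steps
to first-order intramolecular rates.

# Mechanism classification

`detectBindingEvents()` declares a nitrogen bound below 3.4 Å and
requires 20 ps of residence; shorter excursions in either direction are
treated as spurious re-crossings and smoothed away before events are
extracted.  `classifyMechanism()` compares the summed first-shell
coordination around the entry frame with its pre-event baseline (the
mode over the 20 ps pre-window): *dissociative* when the leaving water
(the first-shell water with the latest exit inside the window) is out
before the nitrogen enters and the total never exceeds the baseline;
*associative* when the water is still inside at entry and at least one
frame in between is overcoordinated; *ambiguous* otherwise — including
the single-frame simultaneous exchange, which is retained as its own
label rather than forced binary.  The baseline-as-mode and the
one-frame-overcoordination threshold are this package's
operationalisation of qualitative descriptions; both windows are
anchored at the entry frame.

`leavingWaterGeometry()` applies, per frame, the minimal rigid rotation
placing the metal at the origin and the entering nitrogen along +X (all
pairwise distances preserved to 1e-9 Å, tested), and records the
projected leaving-water position and the N–metal–O angle.  On generator
fixtures planting a 90° exit direction the recovered mean angle is
within 3°, mirroring the orthogonal water departure reported for
cadmium–amine complexes.

# The synthetic-data module

The generators are first-class, tested code — they define the study
conditions under which every stochastic claim in the package is checked.

* `simulateCTMC()` runs an exact Gillespie simulation of the binding
  ladder with per-box propensities $a_{+i} = k_i n_{ML_{i-1}} n_L/\gamma$
  and $a_{-i} = k_{-i} n_{ML_i}$, one metal per box (matching one-ion
  simulation cells), explicit tracking of the unbound ligand count, and
  discretisation to frames.  Holding times pass Kolmogorov–Smirnov tests
  against the specified exponentials; occupancies match the chain's
  stationary law within counting error; realisations are bit-reproducible
  under a fixed seed.  The replica protocol mirrors a typical unbiased-MD
  ensemble — starting states cycle over a coverage grid of the species,
  with a fixed replica count and frame budget (200 replicas of 20000
  frames in the validation suites).  The time base of a fixture is chosen
  so that its *slowest* process yields at least on the order of a hundred
  transitions within that budget; published solution-scale rates such as
  a dissociation at 0.26 s^-1 produce no events on any tractable horizon,
  so fixtures state their rates in molar units and scale the horizon
  accordingly.  This is a sampling-design choice, stated here once.
* `synthFes()` builds congruent paraboloid basins at integer coordination
  pairs with depths from the requested levels plus optional Gaussian
  noise; because the stencils are congruent, the Boltzmann projection
  returns the exact input levels at zero noise, and within
  $\sigma\sqrt{2}$ per level difference with noise.  Overlapping basins
  are rejected.
* `synthBindingTrajectory()` plants labelled binding events with the
  distance signatures described above, sub-residence dips as negatives,
  and (in Cartesian mode) a configurable leaving-water exit angle with
  10° jitter.

What the generators deliberately do **not** emulate: force-field physics,
metadynamics bias dynamics, correlated multi-ligand motion, anisotropic
shell geometry, or non-exponential waiting times.  A pass on these
fixtures therefore certifies the *estimators* — discretisation,
estimation, coarse-graining, conversion, classification — not the
upstream sampling engine.

# Numerical choices and degenerate inputs

* $k_B = 0.0083145$ kJ mol^-1 K^-1, default $T = 300$ K,
  pK = log10 K; concentrations in mol/L, energies kJ/mol, times ps at
  the trajectory interface and seconds in rate constants.
* Log-sum-exp is used for basin aggregation (stable for deep basins);
  the reversible MLE iterates to 1e-12; PCCA+ refuses degenerate
  simplices with an actionable error.
* Report tables round as the field prints them: one decimal for kJ/mol
  and for pK.
* Degenerate inputs have defined behaviour rather than NA contagion:
  all-unvisited basins, exhausted ligand balances, absorbing states,
  unreachable targets, truncated classification windows and zero-event
  steps each raise a specific error, warning or flag (all tested).

# Validation problem sizes

The default validation suites use problem sizes a laptop handles in
minutes: 200-replica ensembles of 20000–40000 frames for rate recovery
(two one-step fixtures whose rates span from 10 s^-1 to 1e9
L mol^-1 s^-1, plus a two-step ladder for thermodynamic–kinetic
consistency), 100-system sweeps for the mass-action oracle, 200 random
chains for the first-passage oracle, and 30–60 planted events for the
mechanism suites.  These sizes were chosen so that statistical error
sits comfortably inside the tolerances being asserted (25% on recovered
rates, 0.3 log units on pK consistency, 3° on exit angles).

# Known limitations

* The rate conversion assumes a single metal per box and a well-mixed
  reservoir; multi-metal boxes are not modelled.
* Local per-step rates are the ladder rates of the master equation; if
  one instead wants the observable relaxation of an ensemble (excursions
  included), use `mfpt()` directly.
* The mechanism classifier sees sharp cutoffs; smoothed coordination
  functions would shift event times by up to the switching width.
* Interchange mechanisms (I\_a/I\_d) are outside the binary
  classification; the ambiguous label is where such events land.
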