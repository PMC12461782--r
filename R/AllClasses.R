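## Central S4 containers.  Validity methods enforce the structural invariants
## that downstream numerics rely on (finite-or-Inf grids, stochastic rows,
## conservation-compatible compositions).

#' FreeEnergySurface: gridded free energy over coordination numbers
#'
#' A rectangular grid of free energies (kJ/mol) over the two collective
#' coordinates used to describe a metal complex in water: the ligand (amino)
#' coordination number and the water coordination number.  Cells never visited
#' by the sampling carry `Inf`.
#'
#' @slot values numeric matrix, `length(axisLig)` rows x `length(axisWat)`
#'   columns, free energy in kJ/mol; `Inf` marks unvisited cells.
#' @slot axisLig numeric, ligand coordination-number coordinate of each row.
#' @slot axisWat numeric, water coordination-number coordinate of each column.
#' @slot temperature numeric, K.
#' @export
setClass("FreeEnergySurface",
  representation(
    values = "matrix",
    axisLig = "numeric",
    axisWat = "numeric",
    temperature = "numeric"
  ),
  prototype(temperature = 300)
)

setValidity("FreeEnergySurface", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@axisLig))
    msg <- c(msg, "nrow(values) must equal length(axisLig)")
  if (ncol(object@values) != length(object@axisWat))
    msg <- c(msg, "ncol(values) must equal length(axisWat)")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number")
  v <- object@values
  if (any(is.na(v)) || any(v == -Inf))
    msg <- c(msg, "grid values must be finite or +Inf (unvisited)")
  if (!any(is.finite(v)))
    msg <- c(msg, "no visited cells")
  if (length(msg)) msg else TRUE
})

#' SpeciesLevels: per-species relative free energies
#'
#' Free energies of the ML_i species relative to the free metal (species 0),
#' with their standard deviations, as extracted from a
#' [FreeEnergySurface-class] or supplied directly.
#'
#' @slot species character labels, first is the free metal.
#' @slot nLig integer, bound ligand donor sites per species.
#' @slot deltaG numeric, kJ/mol relative to species 0 (so `deltaG[1] == 0`).
#' @slot sigma numeric, standard deviation of each level, kJ/mol.
#' @export
setClass("SpeciesLevels",
  representation(
    species = "character",
    nLig = "integer",
    deltaG = "numeric",
    sigma = "numeric"
  )
)

setValidity("SpeciesLevels", function(object) {
  n <- length(object@species)
  msg <- character()
  if (length(object@nLig) != n || length(object@deltaG) != n ||
      length(object@sigma) != n)
    msg <- c(msg, "species, nLig, deltaG and sigma must have equal length")
  if (n > 0 && abs(object@deltaG[1]) > 1e-9)
    msg <- c(msg, "deltaG of the reference (free metal) species must be 0")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
  if (any(object@nLig < 0)) msg <- c(msg, "nLig must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SolutionComposition: total concentrations and stoichiometry
#'
#' The solution conditions under which populations are interpreted: total
#' metal and ligand concentrations, ligands bound per complex species
#' (the stoichiometric coefficients of the ligand mass balance), ligand
#' denticity, temperature, and optionally the simulation box volume needed
#' for count/concentration conversion in the kinetic stage.
#'
#' @slot M0 numeric, total metal concentration, mol/L.
#' @slot L0 numeric, total ligand concentration, mol/L.
#' @slot s integer, whole ligands bound per species (s[1] = 0 for free metal).
#' @slot denticity integer, donor groups per ligand.
#' @slot temperature numeric, K.
#' @slot boxVolume numeric, L; `NA_real_` when not needed.
#' @export
setClass("SolutionComposition",
  representation(
    M0 = "numeric",
    L0 = "numeric",
    s = "integer",
    denticity = "integer",
    temperature = "numeric",
    boxVolume = "numeric"
  ),
  prototype(denticity = 1L, temperature = 300, boxVolume = NA_real_)
)

setValidity("SolutionComposition", function(object) {
  msg <- character()
  if (object@M0 <= 0) msg <- c(msg, "M0 must be > 0")
  if (object@L0 < 0) msg <- c(msg, "L0 must be >= 0")
  if (length(object@s) && object@s[1] != 0L)
    msg <- c(msg, "s[1] (free metal) must be 0")
  if (any(object@s < 0)) msg <- c(msg, "s must be non-negative integers")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (!is.na(object@boxVolume) && object@boxVolume <= 0)
    msg <- c(msg, "boxVolume must be > 0 when given")
  if (length(msg)) msg else TRUE
})

#' EquilibriumResult: species concentrations and association constants
#'
#' Output of [solveEquilibrium()]: equilibrium concentrations of every ML_i
#' species, the free ligand concentration from the ligand mass balance, and
#' the stepwise constants K_i = \[ML_i\]/(\[ML_(i-1)\]\[L\]) together with their
#' cumulative products beta_i and log10 forms.
#'
#' @slot species character labels.
#' @slot concentrations numeric, mol/L per species (species 1 = free metal).
#' @slot freeLigand numeric, mol/L.
#' @slot K numeric, stepwise constants, L/mol (length: n species - 1).
#' @slot beta numeric, cumulative constants.
#' @slot pK numeric, log10 K.
#' @slot pKErr numeric, Monte Carlo standard deviations of pK (NA before
#'   [pkUncertaintyMC()] is run).
#' @slot composition the [SolutionComposition-class] used.
#' @export
setClass("EquilibriumResult",
  representation(
    species = "character",
    concentrations = "numeric",
    freeLigand = "numeric",
    K = "numeric",
    beta = "numeric",
    pK = "numeric",
    pKErr = "numeric",
    composition = "SolutionComposition"
  )
)

setValidity("EquilibriumResult", function(object) {
  msg <- character()
  n <- length(object@species)
  if (length(object@concentrations) != n)
    msg <- c(msg, "one concentration per species required")
  if (n > 1 && length(object@K) != n - 1)
    msg <- c(msg, "one stepwise K per binding step required")
  if (object@freeLigand < 0) msg <- c(msg, "free ligand must be >= 0")
  if (any(object@concentrations < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MicrostateModel: discretised trajectory and its transition matrix
#'
#' The fine-grained Markov state model: cluster centers in the
#' (ligand, water) coordination plane, per-frame assignments for each
#' replica, and (after [estimateTransitionMatrix()]) the transition count
#' and probability matrices at a given lag, restricted to the largest
#' strongly connected set of states.
#'
#' @slot centers numeric matrix, one row per microstate, columns (lig, wat).
#' @slot assignments list of integer vectors, one per replica, microstate
#'   index per frame.
#' @slot dt numeric, saving interval of the frames, ps.
#' @slot lag integer, lag time in frames (0 before estimation).
#' @slot countMatrix numeric matrix of transition counts at `lag`.
#' @slot transitionMatrix row-stochastic numeric matrix.
#' @slot active integer, indices (into rows of `centers`) of the connected
#'   state set the matrices refer to.
#' @slot reversible logical, whether the stored estimate is
#'   detailed-balance constrained.
#' @export
setClass("MicrostateModel",
  representation(
    centers = "matrix",
    assignments = "list",
    dt = "numeric",
    lag = "integer",
    countMatrix = "matrix",
    transitionMatrix = "matrix",
    active = "integer",
    reversible = "logical"
  ),
  prototype(lag = 0L, reversible = TRUE)
)

setValidity("MicrostateModel", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  k <- nrow(object@centers)
  bad <- vapply(object@assignments, function(a)
    any(a < 1L | a > k), logical(1))
  if (any(bad)) msg <- c(msg, "assignments outside 1..nrow(centers)")
  if (length(object@transitionMatrix)) {
    rs <- rowSums(object@transitionMatrix)
    if (any(abs(rs - 1) > 1e-10))
      msg <- c(msg, "transition matrix rows must sum to 1")
    if (any(object@countMatrix < 0))
      msg <- c(msg, "count matrix must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' MacrostateModel: PCCA+ coarse-grained Markov model
#'
#' Result of [pccaCoarseGrain()]: fuzzy memberships of every active
#' microstate in each metastable macrostate, the crisp assignment, the
#' macrostate labels mapped onto ML_i species via the ligand coordination
#' of their member centers, and the coarse transition matrix.
#'
#' @slot membership numeric matrix, microstates x macrostates, rows sum to 1.
#' @slot crisp integer, macrostate index per active microstate.
#' @slot macroNLig integer, ligand coordination label (ML_i) per macrostate.
#' @slot transitionMatrix coarse row-stochastic matrix.
#' @slot pi numeric, coarse stationary distribution.
#' @slot lag integer, frames.
#' @slot dt numeric, ps.
#' @export
setClass("MacrostateModel",
  representation(
    membership = "matrix",
    crisp = "integer",
    macroNLig = "integer",
    transitionMatrix = "matrix",
    pi = "numeric",
    lag = "integer",
    dt = "numeric"
  )
)

setValidity("MacrostateModel", function(object) {
  msg <- character()
  if (length(object@membership)) {
    if (any(object@membership < -1e-8 | object@membership > 1 + 1e-8))
      msg <- c(msg, "memberships must lie in [0, 1]")
    if (any(abs(rowSums(object@membership) - 1) > 1e-8))
      msg <- c(msg, "membership rows must sum to 1")
    if (length(unique(object@crisp)) < ncol(object@membership))
      msg <- c(msg, "every macrostate must own at least one microstate")
  }
  rs <- rowSums(object@transitionMatrix)
  if (any(abs(rs - 1) > 1e-8))
    msg <- c(msg, "coarse transition matrix rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' RateEstimate: molar formation/dissociation rate constants
#'
#' Per binding step i: the forward (formation) rate constant k_i in
#' L mol^-1 s^-1 and the backward (dissociation) rate constant k_-i in s^-1,
#' obtained from inverse mean first passage times of a
#' [MacrostateModel-class] after count/concentration conversion, with
#' optional Bayesian credible intervals.
#'
#' @slot step integer, binding step index i (ML_(i-1) -> ML_i).
#' @slot kForward numeric, L mol^-1 s^-1; 0 with `noEvents` flag when no
#'   transition was observed.
#' @slot kBackward numeric, s^-1.
#' @slot kForwardCI numeric matrix, 2 columns (lower, upper), NA when not
#'   computed.
#' @slot kBackwardCI numeric matrix, as above.
#' @slot gamma numeric, Avogadro number x box volume, L/mol.
#' @slot nLigEq numeric, unbound ligand count at equilibrium.
#' @slot noEvents logical, per step: TRUE when either direction was
#'   unobserved.
#' @export
setClass("RateEstimate",
  representation(
    step = "integer",
    kForward = "numeric",
    kBackward = "numeric",
    kForwardCI = "matrix",
    kBackwardCI = "matrix",
    gamma = "numeric",
    nLigEq = "numeric",
    noEvents = "logical"
  )
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (any(object@kForward < 0) || any(object@kBackward < 0))
    msg <- c(msg, "rates must be non-negative")
  ok <- function(ci) !length(ci) || all(is.na(ci)) ||
    all(ci[, 1] <= ci[, 2], na.rm = TRUE)
  if (!ok(object@kForwardCI) || !ok(object@kBackwardCI))
    msg <- c(msg, "credible interval bounds must be ordered")
  if (length(msg)) msg else TRUE
})

#' DistanceTrajectory: metal-ligand and metal-water distance time series
#'
#' Per-frame distances from the metal to every ligand nitrogen and every
#' water oxygen, optionally with Cartesian coordinates for exit-geometry
#' analysis.
#'
#' @slot dt numeric, ps between frames.
#' @slot dN numeric matrix, frames x nitrogens, Angstrom.
#' @slot dO numeric matrix, frames x water oxygens, Angstrom.
#' @slot xyzMetal numeric matrix, frames x 3, or 0-row when absent.
#' @slot xyzN list of frames x 3 matrices, one per nitrogen (may be empty).
#' @slot xyzO list of frames x 3 matrices, one per water (may be empty).
#' @slot ligandOfN integer, which ligand molecule each nitrogen belongs to.
#' @export
setClass("DistanceTrajectory",
  representation(
    dt = "numeric",
    dN = "matrix",
    dO = "matrix",
    xyzMetal = "matrix",
    xyzN = "list",
    xyzO = "list",
    ligandOfN = "integer"
  ),
  prototype(xyzMetal = matrix(numeric(), 0, 3), xyzN = list(), xyzO = list())
)

setValidity("DistanceTrajectory", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (any(object@dN < 0) || any(object@dO < 0))
    msg <- c(msg, "distances must be >= 0")
  if (nrow(object@dN) != nrow(object@dO))
    msg <- c(msg, "dN and dO must cover the same frames")
  if (length(object@ligandOfN) &&
      length(object@ligandOfN) != ncol(object@dN))
    msg <- c(msg, "ligandOfN must label every nitrogen column")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "FreeEnergySurface", function(object) {
  v <- object@values
  cat("FreeEnergySurface:", nrow(v), "x", ncol(v), "grid,",
      sum(is.finite(v)), "visited cells\n")
  cat("  lig axis:", format(range(object@axisLig)), " wat axis:",
      format(range(object@axisWat)), "\n")
  cat("  T =", object@temperature, "K; min F =",
      format(min(v[is.finite(v)]), digits = 4), "kJ/mol\n")
})

setMethod("show", "SpeciesLevels", function(object) {
  cat("SpeciesLevels with", length(object@species), "species\n")
  print(data.frame(species = object@species, n_lig = object@nLig,
                   delta_g_kj_mol = object@deltaG,
                   sigma_kj_mol = object@sigma))
})

setMethod("show", "SolutionComposition", function(object) {
  cat("SolutionComposition: M0 =", object@M0, "M, L0 =", object@L0,
      "M, denticity", object@denticity, ", T =", object@temperature, "K\n")
  if (!is.na(object@boxVolume))
    cat("  box volume", format(object@boxVolume, digits = 4), "L (gamma =",
        format(object@boxVolume * avogadroNumber, digits = 4), "/M)\n")
})

setMethod("show", "EquilibriumResult", function(object) {
  cat("EquilibriumResult\n")
  print(data.frame(species = object@species,
                   conc_mol_l = signif(object@concentrations, 6)))
  cat("  [L] =", format(object@freeLigand, digits = 6), "M\n")
  if (length(object@pK)) {
    err <- if (all(is.na(object@pKErr))) "" else
      paste0(" +/- ", signif(object@pKErr, 2))
    cat("  pK:", paste0(signif(object@pK, 4), err, collapse = ", "), "\n")
  }
})

setMethod("show", "MicrostateModel", function(object) {
  cat("MicrostateModel:", nrow(object@centers), "centers,",
      length(object@assignments), "replica(s), dt =", object@dt, "ps")
  if (object@lag > 0)
    cat(", lag =", object@lag, "frames,", length(object@active),
        "connected states")
  cat("\n")
})

setMethod("show", "MacrostateModel", function(object) {
  cat("MacrostateModel:", ncol(object@membership), "macrostates (ML_",
      paste(object@macroNLig, collapse = ", ML_"), "), lag =",
      object@lag, "frames\n", sep = "")
})

setMethod("show", "RateEstimate", function(object) {
  cat("RateEstimate (gamma =", format(object@gamma, digits = 4),
      "L/mol, n_lig_eq =", format(object@nLigEq, digits = 4), ")\n")
  print(data.frame(step = object@step,
                   k_forward_M_s = signif(object@kForward, 3),
                   k_backward_s = signif(object@kBackward, 3),
                   no_events = object@noEvents))
})

setMethod("show", "DistanceTrajectory", function(object) {
  cat("DistanceTrajectory:", nrow(object@dN), "frames, dt =", object@dt,
      "ps,", ncol(object@dN), "nitrogens,", ncol(object@dO), "waters",
      if (nrow(object@xyzMetal)) "(with coordinates)" else "", "\n")
})
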