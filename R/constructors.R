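#' Construct a FreeEnergySurface
#'
#' @param values numeric matrix of free energies (kJ/mol), rows indexed by
#'   `axisLig`, columns by `axisWat`; use `Inf` for unvisited cells.
#' @param axisLig,axisWat numeric axis coordinates (coordination numbers).
#' @param temperature temperature in K.
#' @return A [FreeEnergySurface-class] object.
#' @examples
#' fes <- FreeEnergySurface(matrix(c(0, -17.2), 2, 1),
#'                          axisLig = c(0, 2), axisWat = 6)
#' @export
FreeEnergySurface <- function(values, axisLig, axisWat, temperature = 300) {
  new("FreeEnergySurface", values = as.matrix(values),
      axisLig = as.numeric(axisLig), axisWat = as.numeric(axisWat),
      temperature = temperature)
}

#' Construct SpeciesLevels
#'
#' @param deltaG free energies relative to the first (free metal) species,
#'   kJ/mol.  The first entry must be 0.
#' @param nLig bound ligand donor sites per species; defaults to
#'   `0, 1, ..., n-1` times one.
#' @param sigma standard deviations (kJ/mol), default 0.
#' @param species labels, default `"ML0" ...`.
#' @return A [SpeciesLevels-class] object.
#' @export
SpeciesLevels <- function(deltaG, nLig = seq_along(deltaG) - 1L,
                          sigma = rep(0, length(deltaG)),
                          species = paste0("ML", seq_along(deltaG) - 1L)) {
  new("SpeciesLevels", species = as.character(species),
      nLig = as.integer(nLig), deltaG = as.numeric(deltaG),
      sigma = as.numeric(sigma))
}

#' Construct a SolutionComposition
#'
#' @param M0 total metal concentration, mol/L.
#' @param L0 total ligand concentration, mol/L.
#' @param s integer vector: whole ligands bound in each species, starting at
#'   0 for the free metal.
#' @param denticity donor groups per ligand.
#' @param temperature K.
#' @param boxVolume simulation box volume in litres (only needed for the
#'   kinetic count/concentration conversion).
#' @return A [SolutionComposition-class] object.
#' @export
SolutionComposition <- function(M0, L0, s, denticity = 1L,
                                temperature = 300, boxVolume = NA_real_) {
  new("SolutionComposition", M0 = M0, L0 = L0, s = as.integer(s),
      denticity = as.integer(denticity), temperature = temperature,
      boxVolume = boxVolume)
}

#' Construct a DistanceTrajectory
#'
#' @param dt frame spacing, ps.
#' @param dN frames x nitrogens distance matrix, Angstrom.
#' @param dO frames x waters distance matrix, Angstrom.
#' @param xyzMetal,xyzN,xyzO optional Cartesian coordinates (frames x 3
#'   matrix for the metal, lists of such matrices for nitrogens/waters).
#' @param ligandOfN integer ligand id per nitrogen column; defaults to one
#'   ligand per nitrogen (monodentate).
#' @return A [DistanceTrajectory-class] object.
#' @export
DistanceTrajectory <- function(dt, dN, dO,
                               xyzMetal = matrix(numeric(), 0, 3),
                               xyzN = list(), xyzO = list(),
                               ligandOfN = seq_len(ncol(dN))) {
  new("DistanceTrajectory", dt = dt, dN = as.matrix(dN), dO = as.matrix(dO),
      xyzMetal = xyzMetal, xyzN = xyzN, xyzO = xyzO,
      ligandOfN = as.integer(ligandOfN))
}

## ---- accessors ----------------------------------------------------------

#' Accessors for chelkin containers
#'
#' Small read-only accessors: `deltaG()` returns the per-species free-energy
#' levels, `concentrations()` the equilibrium species concentrations,
#' `freeLigand()` the free-ligand concentration, `stepwiseK()` the stepwise
#' association constants, `cumulativeBetaOf()` the cumulative constants,
#' `pKvalues()` log10 K, `transitionMatrixOf()` the (micro or macro)
#' transition matrix and `membershipOf()` the PCCA+ memberships.
#'
#' @param object a chelkin S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))
#' @rdname accessors
#' @export
setMethod("deltaG", "SpeciesLevels", function(object) {
  setNames(object@deltaG, object@species)
})

#' @rdname accessors
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname accessors
#' @export
setMethod("concentrations", "EquilibriumResult", function(object) {
  setNames(object@concentrations, object@species)
})

#' @rdname accessors
#' @export
setGeneric("freeLigand", function(object) standardGeneric("freeLigand"))
#' @rdname accessors
#' @export
setMethod("freeLigand", "EquilibriumResult", function(object) object@freeLigand)

#' @rdname accessors
#' @export
setGeneric("stepwiseK", function(object) standardGeneric("stepwiseK"))
#' @rdname accessors
#' @export
setMethod("stepwiseK", "EquilibriumResult", function(object) object@K)

#' @rdname accessors
#' @export
setGeneric("pKvalues", function(object) standardGeneric("pKvalues"))
#' @rdname accessors
#' @export
setMethod("pKvalues", "EquilibriumResult", function(object) object@pK)

#' @rdname accessors
#' @export
setGeneric("transitionMatrixOf",
           function(object) standardGeneric("transitionMatrixOf"))
#' @rdname accessors
#' @export
setMethod("transitionMatrixOf", "MicrostateModel",
          function(object) object@transitionMatrix)
#' @rdname accessors
#' @export
setMethod("transitionMatrixOf", "MacrostateModel",
          function(object) object@transitionMatrix)

#' @rdname accessors
#' @export
setGeneric("membershipOf", function(object) standardGeneric("membershipOf"))
#' @rdname accessors
#' @export
setMethod("membershipOf", "MacrostateModel", function(object) object@membership)
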