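## Equilibrium thermodynamics: free-energy surfaces -> species levels ->
## populations, stepwise association constants and their Monte Carlo errors.
##
## Populations follow the Boltzmann relation n_i/n_j = exp(-dG_ij / kB T);
## stepwise constants K_i = [ML_i] / ([ML_(i-1)] [L]) with the free ligand
## concentration recovered from the mass balance
## [L] = [L0] - sum_i s_i [ML_i].

#' Default basin assignment for a free-energy surface
#'
#' Assigns every visited grid cell to the ML_i species whose ligand
#' coordination number matches the cell's rounded ligand-axis coordinate.
#' Species are returned in increasing ligand coordination.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param nLig which ligand coordination numbers define species; default all
#'   values present on the (rounded) ligand axis with at least one visited
#'   cell.
#' @return Named list of integer matrices, each two columns (row, col) of
#'   grid cells belonging to one species.
#' @export
defaultBasins <- function(fes, nLig = NULL) {
  roundedLig <- round(fes@axisLig)
  visited <- is.finite(fes@values)
  if (is.null(nLig)) {
    nLig <- sort(unique(roundedLig[rowSums(visited) > 0]))
  }
  basins <- lapply(nLig, function(n) {
    rows <- which(roundedLig == n)
    cells <- which(visited[rows, , drop = FALSE], arr.ind = TRUE)
    cells[, 1] <- rows[cells[, 1]]
    colnames(cells) <- c("row", "col")
    cells
  })
  names(basins) <- paste0("ML", nLig)
  basins
}

#' Project a free-energy surface onto per-species levels
#'
#' Aggregates the free energy of each species' basin either as a Boltzmann
#' sum, dG_i = -kB T log sum_cells exp(-F/kB T) (mode `"boltzmann"`, the
#' default, i.e. the basin's integrated weight), or as the basin minimum
#' (mode `"minimum"`).  Levels are shifted so the first species is 0.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param basins named list of cell index matrices as from [defaultBasins()].
#' @param mode `"boltzmann"` or `"minimum"`.
#' @param nLig ligand coordination number per basin; parsed from basin names
#'   of the form `"ML<i>"` by default.
#' @param sigma per-species level error, kJ/mol (recycled); default 0.
#' @return A [SpeciesLevels-class].
#' @export
projectSurfaceToLevels <- function(fes, basins = defaultBasins(fes),
                                   mode = c("boltzmann", "minimum"),
                                   nLig = NULL, sigma = 0) {
  mode <- match.arg(mode)
  kT <- kBoltzmann * fes@temperature
  raw <- vapply(names(basins), function(sp) {
    cells <- basins[[sp]]
    if (!nrow(cells)) stop("basin for species '", sp, "' is empty")
    f <- fes@values[cells]
    f <- f[is.finite(f)]
    if (!length(f))
      stop("basin for species '", sp, "' contains only unvisited cells")
    if (mode == "minimum") min(f)
    else {
      fmin <- min(f)  # log-sum-exp, stable for deep basins
      fmin - kT * log(sum(exp(-(f - fmin) / kT)))
    }
  }, numeric(1))
  if (is.null(nLig)) {
    nLig <- suppressWarnings(as.integer(sub("^ML", "", names(basins))))
    if (any(is.na(nLig))) nLig <- seq_along(basins) - 1L
  }
  ord <- order(nLig)
  SpeciesLevels(deltaG = raw[ord] - raw[ord][1], nLig = nLig[ord],
                sigma = rep_len(sigma, length(raw)),
                species = names(basins)[ord])
}

#' Solve the coordination equilibrium from species levels
#'
#' Populations are proportional to Boltzmann factors exp(-dG_i / kB T) and
#' are normalised so the species concentrations sum to the total metal
#' concentration `M0` (the levels are interpreted as box-equilibrium free
#' energies at the simulated composition, so no further self-consistent
#' iteration is performed).  The free ligand concentration follows from the
#' ligand mass balance, and the stepwise constants from
#' K_i = \[ML_i\]/(\[ML_(i-1)\]\[L\]).
#'
#' @param levels a [SpeciesLevels-class], species ordered by binding step.
#' @param comp a [SolutionComposition-class]; `comp@s` must align with the
#'   species in `levels`.
#' @return An [EquilibriumResult-class].
#' @export
solveEquilibrium <- function(levels, comp) {
  n <- length(levels@deltaG)
  if (length(comp@s) != n)
    stop("composition stoichiometry length (", length(comp@s),
         ") does not match number of species (", n, ")")
  kT <- kBoltzmann * comp@temperature
  w <- exp(-(levels@deltaG - min(levels@deltaG)) / kT)
  conc <- comp@M0 * w / sum(w)
  L <- comp@L0 - sum(comp@s * conc)
  if (L <= 0)
    stop(sprintf(
      "free ligand concentration is non-positive (deficit %.4g mol/L): levels inconsistent with composition",
      -L))
  K <- conc[-1] / (conc[-n] * L)
  beta <- cumprod(K)
  new("EquilibriumResult", species = levels@species,
      concentrations = conc, freeLigand = L, K = K, beta = beta,
      pK = log10(K), pKErr = rep(NA_real_, n - 1L), composition = comp)
}

#' Monte Carlo uncertainty of the association constants
#'
#' Repeatedly redraws each species level from Normal(dG_i, sigma_i),
#' re-solves the equilibrium, and summarises the resulting pK_i spread.
#' Draws for which the ligand balance gives \[L\] <= 0 are rejected and
#' counted; the run aborts when more than half the draws are rejected.
#'
#' @param levels a [SpeciesLevels-class] with `sigma` set.
#' @param comp a [SolutionComposition-class].
#' @param nSamples number of Monte Carlo draws (>= 2).
#' @param seed integer seed; identical seeds give identical results.
#' @return List with `mean`, `sd` (per pK_i), `rejected` (fraction), and
#'   `nSamples`.
#' @export
pkUncertaintyMC <- function(levels, comp, nSamples = 1000L, seed = 1L) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  nSp <- length(levels@deltaG)
  rng <- newRNG(seed)
  draws <- matrix(NA_real_, nSamples, nSp - 1L)
  rejected <- 0L
  for (b in seq_len(nSamples)) {
    dg <- levels@deltaG + withRNG(rng, rnorm(nSp, 0, levels@sigma))
    dg <- dg - dg[1]
    lv <- SpeciesLevels(dg, nLig = levels@nLig, species = levels@species)
    res <- tryCatch(solveEquilibrium(lv, comp), error = function(e) NULL)
    if (is.null(res)) rejected <- rejected + 1L
    else draws[b, ] <- res@pK
  }
  frac <- rejected / nSamples
  if (frac > 0.5)
    stop(sprintf("%.0f%% of Monte Carlo draws rejected ([L] <= 0): composition incompatible with sampled levels",
                 100 * frac))
  ok <- stats::complete.cases(draws)
  list(mean = colMeans(draws[ok, , drop = FALSE]),
       sd = apply(draws[ok, , drop = FALSE], 2, sd),
       rejected = frac, nSamples = nSamples)
}

#' Cumulative association constants
#'
#' beta_i = K_1 K_2 ... K_i, and additively on the log scale,
#' p(beta_i) = sum_j<=i pK_j.
#'
#' @param K positive stepwise association constants.
#' @return List with `beta` and `pBeta`.
#' @export
cumulativeBeta <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("all stepwise constants must be finite and positive")
  list(beta = cumprod(K), pBeta = cumsum(log10(K)))
}

#' Chelate-effect metric on the log-constant scale
#'
#' The classical comparison of a multidentate ligand's stepwise constant
#' with the cumulative constant of the equivalent number of monodentate
#' ligands: `pKMulti - pBetaMono`.  When `pBetaMonoLower` is given the
#' generalized second-step form `pK2(bi) - pBeta4(mono) + pBeta2(mono)`
#' is returned.
#'
#' @param pKMulti stepwise log-constant of the multidentate ligand.
#' @param pBetaMono cumulative log-constant of the monodentate reference at
#'   matched donor-group count.
#' @param pBetaMonoLower optional lower-coordination cumulative
#'   log-constant added back for second-step comparisons.
#' @return The chelate-effect difference (log10 units).
#' @export
chelateMetric <- function(pKMulti, pBetaMono, pBetaMonoLower = NULL) {
  vals <- c(pKMulti, pBetaMono, pBetaMonoLower)
  if (any(!is.finite(vals))) stop("inputs must be finite")
  out <- pKMulti - pBetaMono
  if (!is.null(pBetaMonoLower)) out <- out + pBetaMonoLower
  out
}

#' Enthalpy of binding from bound/unbound ensemble averages
#'
#' dH_bind = H_bound - H_unbound; standard errors, when given, propagate in
#' quadrature.
#'
#' @param hBound,hUnbound mean ensemble energies, kJ/mol.
#' @param seBound,seUnbound optional standard errors.
#' @return List with `deltaH` and `se` (NA when no errors supplied).
#' @export
enthalpyFromEnsembles <- function(hBound, hUnbound,
                                  seBound = NA_real_, seUnbound = NA_real_) {
  if (!is.finite(hBound) || !is.finite(hUnbound))
    stop("ensemble means must be finite")
  list(deltaH = hBound - hUnbound,
       se = sqrt(seBound^2 + seUnbound^2))
}
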