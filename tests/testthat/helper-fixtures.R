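# Shared fixtures and independent oracles.

# published thermodynamic bookkeeping table (shipped as plain text)
cdThermoTable <- function() {
  read.table(system.file("extdata", "cd_thermo_table.tsv",
                         package = "chelkin"), header = TRUE)
}

bidentateTable <- function() {
  read.table(system.file("extdata", "bidentate_constants.tsv",
                         package = "chelkin"), header = TRUE)
}

# independent mass-action oracle: given stepwise constants K and the
# composition, root-find the free-ligand balance with uniroot and rebuild
# all concentrations from the law of mass action
massActionOracle <- function(K, comp) {
  beta <- c(1, cumprod(K))               # beta_0 = 1 for the free metal
  s <- comp@s
  g <- function(L) {
    w <- beta * L^(seq_along(beta) - 1L)
    L + comp@M0 * sum(s * w) / sum(w) - comp@L0
  }
  L <- uniroot(g, c(1e-300, comp@L0), tol = 1e-14)$root
  w <- beta * L^(seq_along(beta) - 1L)
  conc <- comp@M0 * w / sum(w)
  list(L = L, conc = conc)
}

# fundamental-matrix first-passage oracle
mfptOracle <- function(T, source, target, tauDt) {
  keep <- setdiff(seq_len(nrow(T)), target)
  N <- solve(diag(length(keep)) - T[keep, keep, drop = FALSE])
  sum(N[match(source, keep), ]) * tauDt
}

# random reversible row-stochastic matrix
randomReversibleT <- function(n) {
  S <- matrix(runif(n * n, 0.05, 1), n, n)
  S <- S + t(S)
  S / rowSums(S)
}

# wrap a bare transition matrix as a coarse model for mfpt()
asMacroModel <- function(T, dt = 1, lag = 1L) {
  n <- nrow(T)
  new("MacrostateModel", membership = diag(n), crisp = seq_len(n),
      macroNLig = seq_len(n) - 1L, transitionMatrix = T,
      pi = rep(1 / n, n), lag = lag, dt = dt)
}

# sample a discrete-time trajectory from a transition matrix
sampleChain <- function(T, n, start = 1L) {
  out <- integer(n)
  out[1] <- start
  for (i in 2:n)
    out[i] <- sample.int(nrow(T), 1L, prob = T[out[i - 1], ])
  out
}

# a 4-state binding ladder with moderate well depths: every species keeps
# a workable equilibrium population, so short trajectories sample all
# transitions in both directions
gentleLadderScenario <- function(kMinus = rep(1e4, 3)) {
  comp <- SolutionComposition(0.05, 0.15, 0:3, 2L,
                              boxVolume = 1 / (0.05 * 6.02214076e23))
  scenarioSpec(SpeciesLevels(c(0, -4, -7, -9)), comp, kMinus = kMinus)
}

# a well-conditioned two-species recovery scenario: ligand in excess so the
# per-state unbound count stays close to the equilibrium free-ligand value;
# the box holds one metal (gamma = 1/M0) and LConc/M0 ligands
oneStepScenario <- function(kPlus, kMinus, M0 = 2e-3, LConc = 0.04) {
  comp <- SolutionComposition(M0, LConc, 0:1, 1L,
                              boxVolume = 1 / (M0 * 6.02214076e23))
  K <- kPlus / kMinus
  # dG consistent with K at the (self-consistent) free-ligand concentration
  dG <- -10
  for (i in 1:60) {
    eq <- solveEquilibrium(SpeciesLevels(c(0, dG)), comp)
    dG <- dG - 0.0083145 * 300 * (log(K) - log(eq@K[1]))
  }
  scenarioSpec(SpeciesLevels(c(0, dG)), comp, kMinus = kMinus, kPlus = kPlus)
}
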