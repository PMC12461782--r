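## Mean first passage times and their conversion into molar formation and
## dissociation rate constants.
##
## MFPTs solve the standard linear system m_i = lag dt + sum_j T_ij m_j
## (m = 0 on the target set).  The inverse forward MFPT of a single-metal
## box is the pseudo-first-order formation rate k_i [L]; dividing by the
## equilibrium free-ligand concentration [L] = n_lig_eq / gamma (with
## gamma = N_Av V the count-per-molar factor) yields the molar
## second-order constant.  The inverse backward MFPT is first order and
## needs no conversion.  At ratio level k_i / k_-i equals the stepwise
## equilibrium constant K_i, the consistency condition that fixes this
## convention.

#' Mean first passage time between two macrostates
#'
#' @param model a [MacrostateModel-class] (or any object with a
#'   row-stochastic `transitionMatrix`, `lag` and `dt`).
#' @param source,target macrostate indices.
#' @return MFPT in ps.
#' @export
mfpt <- function(model, source, target) {
  T <- model@transitionMatrix
  n <- nrow(T)
  source <- as.integer(source); target <- as.integer(target)
  if (source == target) return(0)
  keep <- setdiff(seq_len(n), target)
  Tsub <- T[keep, keep, drop = FALSE]
  # reachability of the target from the source
  reach <- (matrixPower((T > 0) * 1, n) [source, target]) > 0
  if (!reach) stop("target macrostate unreachable from source")
  m <- solve(diag(length(keep)) - Tsub, rep(model@lag * model@dt, length(keep)))
  m[match(source, keep)]
}

#' Convert macrostate MFPTs into molar rate constants
#'
#' For each binding step i (macrostate ML_(i-1) -> ML_i along the ligand
#' coordination ladder), the forward molar rate constant is
#' k_i = (gamma / n_lig_eq) / MFPT(i-1 -> i) = 1 / ([L] MFPT), in
#' L mol^-1 s^-1, and the backward constant k_-i = 1 / MFPT(i -> i-1) in
#' s^-1.  The per-step MFPTs are first passage times of the adjacent-pair
#' restriction of the coarse chain (geometric: lag dt / T_ab), i.e. the
#' *local* step rates of the kinetic ladder: unlike global MFPTs they are
#' not inflated by excursions through deeper coordination states, they
#' reduce to the plain MFPT for a two-state model, and under a reversible
#' estimate the ratio k_i/k_-i reproduces the stepwise equilibrium
#' constant K_i exactly.  Steps whose macrostates are missing from the
#' model (elusive intermediates) are skipped and flagged as merged.
#'
#' @param model a [MacrostateModel-class].
#' @param comp a [SolutionComposition-class] with `boxVolume` set.
#' @param equilibrium an [EquilibriumResult-class] providing the free
#'   ligand concentration.
#' @param mfptUnit seconds per ps of MFPT time; default `1e-12` (MFPTs are
#'   in ps).
#' @return A [RateEstimate-class].  `step` holds the ligand coordination of
#'   the formed macrostate; a gap in `step` marks a merged step.
#' @export
ratesFromMsm <- function(model, comp, equilibrium, mfptUnit = 1e-12) {
  if (is.na(comp@boxVolume)) stop("composition has no boxVolume")
  gamma <- avogadroNumber * comp@boxVolume
  L <- equilibrium@freeLigand
  nLigEq <- L * gamma
  if (nLigEq <= 0) stop("equilibrium unbound ligand count is <= 0")
  lig <- model@macroNLig
  if (length(unique(lig)) < length(lig) || length(lig) < 2L)
    stop("macrostates do not resolve distinct ML_i coordination species ",
         "(ligand labels: ", paste(lig, collapse = ", "), "); the sampled ",
         "trajectories may cover only one species in both directions - ",
         "use a longer horizon or different clustering")
  ord <- order(lig)
  steps <- integer(0); kf <- numeric(0); kb <- numeric(0); noEv <- logical(0)
  Tc <- model@transitionMatrix
  tau <- model@lag * model@dt
  for (j in seq_len(length(ord) - 1L)) {
    a <- ord[j]; b <- ord[j + 1L]
    tf <- if (Tc[a, b] > 0) tau / Tc[a, b] else Inf
    tb <- if (Tc[b, a] > 0) tau / Tc[b, a] else Inf
    steps <- c(steps, lig[b])
    kf <- c(kf, if (is.finite(tf) && tf > 0) (gamma / nLigEq) / (tf * mfptUnit) else 0)
    kb <- c(kb, if (is.finite(tb) && tb > 0) 1 / (tb * mfptUnit) else 0)
    noEv <- c(noEv, !is.finite(tf) || !is.finite(tb))
  }
  if (any(diff(sort(lig)) > 1))
    message("rate chain skips unresolved intermediate state(s); steps ",
            paste(steps, collapse = ", "), " are merged transitions")
  nBind <- length(steps)
  na2 <- matrix(NA_real_, nBind, 2)
  new("RateEstimate", step = steps, kForward = kf, kBackward = kb,
      kForwardCI = na2, kBackwardCI = na2,
      gamma = gamma, nLigEq = nLigEq, noEvents = noEv)
}

#' Bayesian credible intervals for the MSM rates
#'
#' Samples transition matrices row-wise from the Dirichlet posterior of
#' the transition counts (uniform prior), re-runs the PCCA+ coarse-graining
#' pipeline's rate conversion on each sample, and reports the central 95%
#' interval of every forward/backward rate.
#'
#' @param model estimated [MicrostateModel-class] (counts present).
#' @param macro the [MacrostateModel-class] whose membership is reused for
#'   every sample (the macrostate definition is held fixed).
#' @param comp,equilibrium as in [ratesFromMsm()].
#' @param nSamples posterior draws (>= 2).
#' @param seed integer seed.
#' @param level credible level, default 0.95.
#' @return A [RateEstimate-class] with the point estimate from the original
#'   model and filled credible intervals.
#' @export
bayesianRateErrors <- function(model, macro, comp, equilibrium,
                               nSamples = 100L, seed = 1L, level = 0.95) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  if (!length(model@countMatrix)) stop("model carries no counts")
  point <- ratesFromMsm(macro, comp, equilibrium)
  rng <- newRNG(seed)
  C <- model@countMatrix
  if (any(rowSums(C) < 1)) stop("every state needs at least one observed transition")
  chi <- macro@membership
  pi0 <- stationaryDistribution(model@transitionMatrix)
  nBind <- length(point@step)
  kfS <- matrix(NA_real_, nSamples, nBind)
  kbS <- matrix(NA_real_, nSamples, nBind)
  for (s in seq_len(nSamples)) {
    T <- withRNG(rng, dirichletRows(C + 1e-8))
    piMicro <- stationaryDistribution(T)
    piMacro <- as.vector(t(chi) %*% piMicro)
    Tc <- t(chi * piMicro) %*% T %*% chi / piMacro
    Tc <- Tc / rowSums(Tc)
    mm <- macro
    mm@transitionMatrix <- Tc
    mm@pi <- piMacro
    r <- tryCatch(suppressMessages(ratesFromMsm(mm, comp, equilibrium)),
                  error = function(e) NULL)
    if (!is.null(r) && length(r@kForward) == nBind) {
      kfS[s, ] <- r@kForward
      kbS[s, ] <- r@kBackward
    }
  }
  a <- (1 - level) / 2
  qr2 <- function(m) t(apply(m, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  point@kForwardCI <- qr2(kfS)
  point@kBackwardCI <- qr2(kbS)
  validObject(point)
  point
}

dirichletRows <- function(C) {
  G <- matrix(rgamma(length(C), shape = as.vector(C)), nrow(C), ncol(C))
  G / rowSums(G)
}

#' Stability constants from paired rate constants
#'
#' pK_i = log10(k_i / k_-i), the kinetic route to the stepwise association
#' constants.
#'
#' @param rates a [RateEstimate-class].
#' @return Named numeric vector of pK_i per step; steps with missing
#'   events are NA.
#' @export
pkFromRates <- function(rates) {
  if (length(rates@kForward) != length(rates@kBackward))
    stop("forward and backward rates must be paired")
  pk <- ifelse(rates@noEvents | rates@kForward <= 0 | rates@kBackward <= 0,
               NA_real_, log10(rates@kForward / rates@kBackward))
  setNames(pk, paste0("pK", rates@step))
}
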