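# Mean first passage times, rate conversion and Bayesian uncertainties.

test_that("mfpt equals the fundamental-matrix solve on random chains", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    T <- randomReversibleT(n)
    mm <- asMacroModel(T, dt = runif(1, 0.5, 2))
    ij <- sample(n, 2)
    expect_equal(mfpt(mm, ij[1], ij[2]),
                 mfptOracle(T, ij[1], ij[2], mm@lag * mm@dt),
                 tolerance = 1e-10)
  }
})

test_that("mfpt matches closed forms for simple chains", {
  # 2-state geometric: p12 = 0.5, lag dt = 1 ps -> 2 ps
  T2 <- matrix(c(0.5, 0.5, 0.7, 0.3), 2, 2, byrow = TRUE)
  expect_equal(mfpt(asMacroModel(T2), 1, 2), 2)
  expect_equal(mfpt(asMacroModel(T2), 1, 1), 0)

  # birth-death chain: standard summation formula
  # m(i -> i+1) = sum over paths: for state 1 of 0<->1<->2 ladder
  p <- c(0.3, 0.2); q <- c(0.1, 0.25)  # up from 1,2; down from 2,3
  T <- matrix(0, 3, 3)
  T[1, 2] <- p[1]; T[2, 3] <- p[2]; T[2, 1] <- q[1]; T[3, 2] <- q[2]
  diag(T) <- 1 - rowSums(T)
  # closed form for birth-death MFPT(1 -> 3):
  # m = sum_{k=1..2} sum_{j<=k} (1/p_k) prod_{i=j..k-1} (q_i/p_i)
  m13 <- (1 / p[1]) + (1 / p[2]) * (1 + q[1] / p[1])
  expect_equal(mfpt(asMacroModel(T), 1, 3), m13, tolerance = 1e-10)
})

test_that("unreachable targets raise an error", {
  T <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(mfpt(asMacroModel(T), 1, 2), "unreachable")
})

test_that("molar rates are recovered from a one-step CTMC within 25%", {
  sc <- oneStepScenario(kPlus = 1e6, kMinus = 10)
  # horizon long enough to see dissociation (mean bound time 0.1 s)
  trajs <- simulateCTMC(sc, nReplicas = 10, tMax = 1.0, dt = 5e-6, seed = 31)
  micro <- estimateTransitionMatrix(
    assignMicrostates(trajs, k = 4, seed = 32), lag = 1)
  macro <- pccaCoarseGrain(micro, 2)
  est <- ratesFromMsm(macro, sc$comp, sc$equilibrium)
  expect_lt(abs(est@kForward - 1e6) / 1e6, 0.25)
  expect_lt(abs(est@kBackward - 10) / 10, 0.25)
  # kinetic pK agrees with the thermodynamic one
  expect_lt(abs(pkFromRates(est) - pKvalues(sc$equilibrium)), 0.3)
})

test_that("doubling the box volume at fixed concentrations leaves molar rates unchanged", {
  est <- lapply(c(2e-3, 1e-3), function(M0) {
    # same concentrations, twice the volume (gamma doubles, 2x ligands)
    sc <- oneStepScenario(kPlus = 1e7, kMinus = 1e3, M0 = M0)
    trajs <- simulateCTMC(sc, nReplicas = 20, tMax = 2e-2, dt = 5e-7,
                          seed = 33)
    micro <- estimateTransitionMatrix(
      assignMicrostates(trajs, k = 4, seed = 34), lag = 1)
    ratesFromMsm(pccaCoarseGrain(micro, 2), sc$comp, sc$equilibrium)
  })
  expect_equal(est[[2]]@gamma, 2 * est[[1]]@gamma)
  expect_lt(abs(est[[1]]@kForward - est[[2]]@kForward) / est[[1]]@kForward,
            0.25)
  expect_lt(abs(est[[1]]@kBackward - est[[2]]@kBackward) / est[[1]]@kBackward,
            0.25)
})

test_that("steps without observed events are flagged with zero rate", {
  # absorbing bound state: no dissociation ever observed
  T <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  mm <- asMacroModel(T)
  comp <- SolutionComposition(0.05, 1, 0:1, 1L,
                              boxVolume = 1 / (0.05 * 6.02214076e23))
  eq <- solveEquilibrium(SpeciesLevels(c(0, -10)), comp)
  est <- ratesFromMsm(mm, comp, eq)
  expect_equal(est@kBackward, 0)
  expect_true(est@noEvents)
  expect_true(is.na(pkFromRates(est)))
})

test_that("kinetic stability constants follow log10 of the rate ratio", {
  mk <- function(kf, kb) new("RateEstimate", step = 1L, kForward = kf,
                             kBackward = kb,
                             kForwardCI = matrix(NA_real_, 1, 2),
                             kBackwardCI = matrix(NA_real_, 1, 2),
                             gamma = 20, nLigEq = 3, noEvents = FALSE)
  expect_equal(unname(pkFromRates(mk(1e5, 1))), 5)
  expect_equal(unname(pkFromRates(mk(42, 42))), 0)
})

test_that("Bayesian intervals concentrate with counts and bracket the truth", {
  comp <- SolutionComposition(0.05, 1, 0:1, 1L,
                              boxVolume = 1 / (0.05 * 6.02214076e23))
  eq <- solveEquilibrium(SpeciesLevels(c(0, -8)), comp)
  mkModel <- function(C) {
    T <- C / rowSums(C)
    micro <- new("MicrostateModel", centers = cbind(0:1, 8:7),
                 assignments = list(1:2), dt = 1, lag = 1L,
                 countMatrix = C, transitionMatrix = T, active = 1:2,
                 reversible = FALSE)
    list(micro = micro, macro = asMacroModel(T))
  }
  C <- matrix(c(90, 10, 5, 95), 2, 2, byrow = TRUE)
  m1 <- mkModel(C); m2 <- mkModel(C * 100)
  b1 <- bayesianRateErrors(m1$micro, m1$macro, comp, eq, nSamples = 400,
                           seed = 41)
  b2 <- bayesianRateErrors(m2$micro, m2$macro, comp, eq, nSamples = 400,
                           seed = 41)
  w1 <- diff(b1@kBackwardCI[1, ]); w2 <- diff(b2@kBackwardCI[1, ])
  # posterior width shrinks like 1/sqrt(counts): x100 counts ~ x10 narrower
  expect_gt(w1 / w2, 6)
  expect_lt(w1 / w2, 16)
  # point estimate sits inside its own credible interval
  expect_gt(b1@kBackward, b1@kBackwardCI[1, 1])
  expect_lt(b1@kBackward, b1@kBackwardCI[1, 2])
  # seed determinism
  b1b <- bayesianRateErrors(m1$micro, m1$macro, comp, eq, nSamples = 400,
                            seed = 41)
  expect_identical(b1@kForwardCI, b1b@kForwardCI)
  expect_error(bayesianRateErrors(m1$micro, m1$macro, comp, eq,
                                  nSamples = 1, seed = 1), ">= 2")
})

test_that("symmetric two-state counts give symmetric rate intervals", {
  comp <- SolutionComposition(0.05, 1, 0:1, 1L,
                              boxVolume = 1 / (0.05 * 6.02214076e23))
  eq <- solveEquilibrium(SpeciesLevels(c(0, 1e-9)), comp)
  C <- matrix(c(80, 20, 20, 80), 2, 2, byrow = TRUE)
  T <- C / rowSums(C)
  micro <- new("MicrostateModel", centers = cbind(0:1, 8:7),
               assignments = list(1:2), dt = 1, lag = 1L,
               countMatrix = C, transitionMatrix = T, active = 1:2,
               reversible = FALSE)
  b <- bayesianRateErrors(micro, asMacroModel(T), comp, eq, nSamples = 2000,
                          seed = 5)
  # the per-second backward rate and the forward rate times [L] are
  # exchangeable here, so their intervals coincide up to Monte Carlo error
  fwdPerBox <- b@kForwardCI * eq@freeLigand
  expect_equal(unname(fwdPerBox[1, ]), unname(b@kBackwardCI[1, ]),
               tolerance = 0.05)
})

test_that("true rates fall inside the 95% interval in most repeated experiments", {
  sc <- oneStepScenario(kPlus = 1e6, kMinus = 1e3)
  hits <- 0L
  nRep <- 12L
  for (r in seq_len(nRep)) {
    trajs <- simulateCTMC(sc, nReplicas = 6, tMax = 6e-3, dt = 1e-6,
                          seed = 100 + r)
    micro <- estimateTransitionMatrix(
      assignMicrostates(trajs, k = 4, seed = 1), lag = 1)
    macro <- pccaCoarseGrain(micro, 2)
    b <- bayesianRateErrors(micro, macro, sc$comp, sc$equilibrium,
                            nSamples = 200, seed = r)
    if (b@kBackwardCI[1, 1] <= 1e3 && 1e3 <= b@kBackwardCI[1, 2])
      hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.75 * nRep))
})
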