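## Two-step decomposition of bidentate ligand binding:
##   M + L-L  <=>  M(L-L)_open   (open ring: one donor bound)
##   M(L-L)_open  <=>  M(L-L)    (closed ring: chelate formed)
## with K_or = k+or/k-or, K_cr = k+cr/k-cr, and overall
##   k_f = k+or k+cr / (k-or + k+cr),   k_d = k-or k-cr / (k-or + k+cr),
## so that K_1 = K_or K_cr = k_f / k_d identically.

#' Construct a bidentate rate set
#'
#' @param kPlusOr forward open-ring (first donor binding) rate constant
#'   (L mol^-1 s^-1 in the molar convention, or s^-1 per box).
#' @param kMinusOr open-ring dissociation rate, s^-1.
#' @param kPlusCr ring-closure rate, s^-1.
#' @param kMinusCr ring-opening rate, s^-1.
#' @return A named list of class `"BidentateRateSet"`.
#' @export
bidentateRates <- function(kPlusOr, kMinusOr, kPlusCr, kMinusCr) {
  r <- c(kPlusOr = kPlusOr, kMinusOr = kMinusOr,
         kPlusCr = kPlusCr, kMinusCr = kMinusCr)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("all four rate constants must be finite and positive")
  structure(as.list(r), class = "BidentateRateSet")
}

#' Decompose bidentate binding into open-ring and closed-ring steps
#'
#' Computes the intermediate stability constants K_or and K_cr, the overall
#' formation and dissociation rate constants k_f and k_d, the overall
#' stability constant K_1 = K_or K_cr (= k_f/k_d by microscopic
#' reversibility), and labels the rate-determining step of each direction:
#' formation is "first-binding-limited" when ring closure outruns open-ring
#' dissociation (k+cr/k-or > 10, so k_f ~ k+or), and dissociation is
#' "ring-opening-limited" when k_d is within 10% of k-cr.
#'
#' @param rates a `BidentateRateSet` from [bidentateRates()].
#' @return A list of class `"ChelateDecomposition"` with elements `KOr`,
#'   `KCr`, `K1`, `kF`, `kD`, `logKOr`, `logKCr`, `logK1`,
#'   `formationLimitedBy`, `dissociationLimitedBy`.
#' @examples
#' # ring closure at 7.2e9 1/s against ring opening at 2.9e3 1/s: log K_cr = 6.4
#' r <- bidentateRates(1e9, 1e9, 7.2e9, 2.9e3)
#' chelateDecompose(r)$logKCr
#' @export
chelateDecompose <- function(rates) {
  stopifnot(inherits(rates, "BidentateRateSet"))
  KOr <- rates$kPlusOr / rates$kMinusOr
  KCr <- rates$kPlusCr / rates$kMinusCr
  kF <- rates$kPlusOr * rates$kPlusCr / (rates$kMinusOr + rates$kPlusCr)
  kD <- rates$kMinusOr * rates$kMinusCr / (rates$kMinusOr + rates$kPlusCr)
  K1 <- KOr * KCr
  formation <- if (rates$kPlusCr / rates$kMinusOr > 10)
    "first-binding-limited" else "mixed"
  dissociation <- if (abs(kD - rates$kMinusCr) / rates$kMinusCr <= 0.1)
    "ring-opening-limited" else "mixed"
  structure(list(KOr = KOr, KCr = KCr, K1 = K1, kF = kF, kD = kD,
                 logKOr = log10(KOr), logKCr = log10(KCr),
                 logK1 = log10(K1),
                 formationLimitedBy = formation,
                 dissociationLimitedBy = dissociation),
            class = "ChelateDecomposition")
}

#' @export
print.ChelateDecomposition <- function(x, ...) {
  cat("Chelate decomposition (open ring / closed ring)\n")
  cat(sprintf("  log K_or = %.2f, log K_cr = %.2f, pK_1 = %.2f\n",
              x$logKOr, x$logKCr, x$logK1))
  cat(sprintf("  k_f = %.3g, k_d = %.3g (K_1 = k_f/k_d = %.3g)\n",
              x$kF, x$kD, x$K1))
  cat("  formation:", x$formationLimitedBy,
      "| dissociation:", x$dissociationLimitedBy, "\n")
  invisible(x)
}

#' Asymptotic limits of the two-step rate expressions
#'
#' Reports the limiting approximations k_f ~ k+or (fast ring closure) and
#' k_d ~ k-cr (ring-opening-limited dissociation) together with their
#' relative errors against the exact two-step expressions.
#'
#' @param rates a `BidentateRateSet`.
#' @return A data.frame with one row per approximation: `quantity`,
#'   `exact`, `approx`, `relError`.
#' @export
limitBehavior <- function(rates) {
  d <- chelateDecompose(rates)
  data.frame(
    quantity = c("kF", "kD"),
    exact = c(d$kF, d$kD),
    approx = c(rates$kPlusOr, rates$kMinusCr),
    relError = c(abs(d$kF - rates$kPlusOr) / rates$kPlusOr,
                 abs(d$kD - rates$kMinusCr) / rates$kMinusCr))
}

#' Extract bidentate two-step rates from a three-state macrostate model
#'
#' Maps a macrostate chain M <-> open-ring <-> closed-ring (ligand
#' coordination 0, 1, 2) onto the two-step rate set: k+or from the molar
#' forward rate of the first step, k-or, k+cr and k-cr from the first-order
#' inverse MFPTs of the remaining transitions.
#'
#' @param model a [MacrostateModel-class] with exactly three macrostates at
#'   ligand coordination 0, 1 and 2.
#' @param comp,equilibrium as in [ratesFromMsm()].
#' @return A `BidentateRateSet` (molar k+or); an error when the open-ring
#'   intermediate is missing, or a flag when the closed-ring state was
#'   never seen to open.
#' @export
extractBidentateRates <- function(model, comp, equilibrium) {
  lig <- sort(model@macroNLig)
  if (!identical(lig, 0:2))
    stop("open-ring intermediate macrostate missing: need states at ligand ",
         "coordination 0, 1, 2 (try finer clustering; the singly bound ",
         "configurations are elusive)")
  est <- ratesFromMsm(model, comp, equilibrium)
  est <- list(kPlusOr = est@kForward[1], kMinusOr = est@kBackward[1],
              # ring closure/opening are intramolecular: first order both ways
              kPlusCr = est@kForward[2] * equilibrium@freeLigand,
              kMinusCr = est@kBackward[2])
  if (est$kMinusCr <= 0)
    warning("closed-ring state never observed to open (k-cr unobserved)")
  if (est$kMinusCr <= 0) est$kMinusCr <- NA_real_
  structure(est, class = "BidentateRateSet")
}
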