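## PCCA+ coarse-graining: fuzzy memberships of microstates in metastable
## macrostates from the dominant eigenvector subspace of the (reversible)
## transition matrix, via the inner-simplex vertex search followed by the
## feasibility transform (memberships clipped to the probability simplex
## and row-normalised).

pccaMemberships <- function(T, nMacro) {
  e <- eigen(T)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values[ord])[seq_len(nMacro)]
  if (any(abs(Im(e$values[ord][seq_len(nMacro)])) > 1e-8))
    stop("dominant eigenvalues are complex; use a reversible estimate or a different nMacro")
  X <- Re(e$vectors[, ord[seq_len(nMacro)], drop = FALSE])
  X[, 1] <- 1                                  # stationary eigenvector
  # inner-simplex vertex search: the nMacro rows of X that span the most
  # spread-out simplex become the macrostate prototypes
  verts <- integer(nMacro)
  d <- rowSums(X^2)
  verts[1] <- which.max(d)
  # translate so the first vertex is the origin; each further vertex is the
  # row farthest from the span of the directions already chosen (the first
  # vertex's own translated row is zero and spans nothing)
  Y <- sweep(X, 2, X[verts[1], ])
  for (j in seq_len(nMacro - 1L) + 1L) {
    proj <- if (j == 2L) Y else {
      q <- qr(t(Y[verts[2:(j - 1L)], , drop = FALSE]))
      Y - t(qr.fitted(q, t(Y)))
    }
    verts[j] <- which.max(rowSums(proj^2))
  }
  A <- tryCatch(solve(X[verts, , drop = FALSE]),
                error = function(e)
                  stop("membership optimization failed (degenerate simplex); try a different nMacro"))
  chi <- X %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  if (any(rs <= 0))
    stop("membership optimization failed (empty row); try a different nMacro")
  chi / rs
}

#' Coarse-grain a microstate model with PCCA+
#'
#' Computes fuzzy macrostate memberships from the `nMacro` dominant
#' eigenvectors, assigns each microstate crisply to its largest membership
#' (ties broken toward the macrostate of lower ligand coordination), maps
#' each macrostate to an ML_i species by the membership-weighted ligand
#' coordination of its member centers, and builds the coarse transition
#' matrix by stationary-weighted membership projection.
#'
#' @param model an estimated [MicrostateModel-class].
#' @param nMacro number of macrostates (<= number of real dominant
#'   eigenvalues).
#' @return A [MacrostateModel-class]; macrostates are ordered by increasing
#'   ligand coordination.
#' @export
pccaCoarseGrain <- function(model, nMacro) {
  if (model@lag < 1L) stop("estimate the transition matrix first")
  T <- model@transitionMatrix
  if (nMacro > nrow(T))
    stop("nMacro exceeds the number of connected microstates")
  if (nMacro == nrow(T)) {
    chi <- diag(nrow(T))
  } else {
    chi <- pccaMemberships(T, nMacro)
  }
  ligCoord <- model@centers[model@active, 1]
  macroLig <- as.vector(t(chi) %*% ligCoord / colSums(chi))
  ord <- order(macroLig)
  chi <- chi[, ord, drop = FALSE]
  macroLig <- macroLig[ord]
  # crisp assignment; ties toward lower ligand coordination (first column
  # after ordering)
  crisp <- apply(chi, 1, function(r) which(r >= max(r) - 1e-12)[1])
  if (length(unique(crisp)) < nMacro)
    stop("a macrostate has no crisply assigned microstate; try a different nMacro")
  pi <- stationaryDistribution(T)
  piMacro <- as.vector(t(chi) %*% pi)
  # coarse transition matrix: T_AB = sum_ij pi_i chi_iA T_ij chi_jB / pi_A
  Tc <- t(chi * pi) %*% T %*% chi / piMacro
  Tc <- Tc / rowSums(Tc)
  new("MacrostateModel", membership = chi, crisp = as.integer(crisp),
      macroNLig = as.integer(round(macroLig)),
      transitionMatrix = Tc, pi = piMacro,
      lag = model@lag, dt = model@dt)
}
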