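## Transition-matrix estimation and Markovianity validation.
##
## Counts use a sliding window at the requested lag within each replica.
## The maximum-likelihood estimator is row normalisation of the counts; the
## reversible estimator is the standard detailed-balance-constrained
## self-consistent iteration.  Both are restricted to the largest strongly
## connected component of the count graph.

countTransitions <- function(assignments, lag, k) {
  C <- matrix(0, k, k)
  for (a in assignments) {
    n <- length(a)
    if (n <= lag) next
    from <- a[seq_len(n - lag)]
    to <- a[seq_len(n - lag) + lag]
    tab <- table(factor(from, levels = seq_len(k)),
                 factor(to, levels = seq_len(k)))
    C <- C + array(tab, dim = c(k, k))
  }
  C
}

largestSCC <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  members <- which(comp$membership == which.max(comp$csize))
  sort(members)
}

reversibleMLE <- function(C, tol = 1e-12, maxIter = 10000L) {
  # self-consistent iteration for the detailed-balance-constrained MLE
  Cs <- C + t(C)
  ci <- rowSums(C)
  X <- Cs / sum(C)          # initial symmetric guess
  for (it in seq_len(maxIter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    Xnew <- Cs / denom
    Xnew[Cs == 0] <- 0
    delta <- max(abs(Xnew - X))
    X <- Xnew
    if (delta < tol) break
  }
  X / rowSums(X)
}

#' Estimate the microstate transition matrix
#'
#' @param model a [MicrostateModel-class] from [assignMicrostates()].
#' @param lag lag time in frames (>= 1).
#' @param reversible constrain the estimate to detailed balance (default
#'   TRUE).
#' @param states optionally require these microstates to be in the
#'   connected set; an error lists any that are not.
#' @return The model with `countMatrix`, `transitionMatrix`, `lag` and
#'   `active` (indices into the original centers) filled in.
#' @export
estimateTransitionMatrix <- function(model, lag, reversible = TRUE,
                                     states = NULL) {
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1 frame")
  k <- nrow(model@centers)
  C <- countTransitions(model@assignments, lag, k)
  active <- largestSCC(C)
  if (!is.null(states)) {
    missing <- setdiff(as.integer(states), active)
    if (length(missing))
      stop("requested states not in the connected set: ",
           paste(missing, collapse = ", "))
  }
  Ca <- C[active, active, drop = FALSE]
  T <- if (reversible) reversibleMLE(Ca) else Ca / rowSums(Ca)
  rownames(T) <- colnames(T) <- active
  model@countMatrix <- Ca
  model@transitionMatrix <- T
  model@lag <- lag
  model@active <- active
  model@reversible <- reversible
  validObject(model)
  model
}

stationaryDistribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Implied relaxation timescales over a set of lag times
#'
#' t_i(tau) = -tau dt / log lambda_i(tau) for the eigenvalues below 1 of
#' the transition matrix re-estimated at each lag.  The smallest lag at
#' which every reported timescale has plateaued (relative change upon
#' doubling the lag below `tol`) is flagged.
#'
#' @param model a [MicrostateModel-class] with assignments.
#' @param lags increasing integer lags (frames).
#' @param nIts how many timescales to report.
#' @param reversible estimator flag, as in [estimateTransitionMatrix()].
#' @param tol relative plateau tolerance (default 0.1).
#' @return List with `lags`, `timescales` (length(lags) x nIts, ps; `Inf`
#'   for eigenvalues at 1), and `converged` (first plateaued lag or NA).
#' @export
impliedTimescales <- function(model, lags, nIts = 2L, reversible = TRUE,
                              tol = 0.1) {
  lags <- as.integer(lags)
  if (is.unsorted(lags, strictly = TRUE)) stop("lags must be increasing")
  ts <- matrix(NA_real_, length(lags), nIts)
  for (i in seq_along(lags)) {
    m <- estimateTransitionMatrix(model, lags[i], reversible = reversible)
    ev <- eigen(m@transitionMatrix)$values
    if (reversible && any(abs(Im(ev)) > 1e-8))
      stop("complex eigenvalues in reversible mode (|Im| > 1e-8)")
    ev <- sort(Re(ev), decreasing = TRUE)
    ev <- ev[-1]                       # drop the stationary eigenvalue
    ev <- ev[seq_len(min(nIts, length(ev)))]
    t_i <- ifelse(ev >= 1 - 1e-12, Inf,
                  ifelse(ev <= 0, NA_real_,
                         -lags[i] * model@dt / log(ev)))
    ts[i, seq_along(t_i)] <- t_i
  }
  converged <- NA_integer_
  for (i in seq_along(lags)) {
    j <- which(lags >= 2L * lags[i])[1]
    if (is.na(j)) break
    a <- ts[i, ]; b <- ts[j, ]
    ok <- is.finite(a) & is.finite(b)
    if (any(ok) && all(abs(b[ok] - a[ok]) / pmax(a[ok], 1e-12) < tol)) {
      converged <- lags[i]
      break
    }
  }
  list(lags = lags, timescales = ts, converged = converged)
}

#' Chapman-Kolmogorov self-consistency test
#'
#' Compares the model propagated n steps, T(tau)^n, against a matrix
#' re-estimated from the data at lag n tau, through the occupation
#' probabilities of each macrostate (or microstate when no coarse model is
#' given).
#'
#' @param model an estimated [MicrostateModel-class].
#' @param nSteps vector of step multiples to test.
#' @param macro optional [MacrostateModel-class]; divergence is then
#'   measured on macrostate occupation probabilities.
#' @param threshold pass/fail bound on the maximum divergence (default 0.1).
#' @return List with `nSteps`, `divergence` (max absolute difference per
#'   multiple), `maxDivergence`, and `pass`.
#' @export
chapmanKolmogorov <- function(model, nSteps = 2:5, macro = NULL,
                              threshold = 0.1) {
  if (model@lag < 1L) stop("estimate the transition matrix first")
  T1 <- model@transitionMatrix
  maxLen <- max(vapply(model@assignments, length, integer(1)))
  div <- vapply(as.integer(nSteps), function(n) {
    if (n * model@lag >= maxLen)
      stop("insufficient data at lag ", n * model@lag, " frames")
    Tn <- matrixPower(T1, n)
    mn <- estimateTransitionMatrix(model, n * model@lag,
                                   reversible = model@reversible)
    common <- intersect(model@active, mn@active)
    i1 <- match(common, model@active)
    i2 <- match(common, mn@active)
    A <- Tn[i1, i1, drop = FALSE]
    B <- mn@transitionMatrix[i2, i2, drop = FALSE]
    if (!is.null(macro)) {
      M <- macro@membership[i1, , drop = FALSE]
      A <- A %*% M
      B <- B %*% M
    }
    max(abs(A - B))
  }, numeric(1))
  list(nSteps = as.integer(nSteps), divergence = div,
       maxDivergence = max(div), pass = max(div) <= threshold)
}

matrixPower <- function(T, n) {
  out <- diag(nrow(T))
  P <- T
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  out
}
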