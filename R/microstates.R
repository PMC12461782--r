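## Trajectory discretisation: k-means++ seeding followed by Lloyd
## iterations.  The loop is written out (rather than delegated) because the
## estimator contract fixes the empty-cluster policy: a cluster emptied
## during iteration is re-seeded from the point farthest from its center,
## with a message.

#' Discretise coordination trajectories into microstates
#'
#' Pools the frames of all replicas, runs k-means++ initialisation and
#' Lloyd iterations (tolerance 1e-6 on center movement, at most 500
#' iterations) in the (ligand, water) coordination plane, and stores the
#' per-replica assignment sequences.
#'
#' @param trajs a single trajectory or list of trajectories; each is a list
#'   with `dt` (ps) and `frames` (n x 2 matrix of (lig, wat) coordination),
#'   as produced by [simulateCTMC()] or [readColvar()].
#' @param k number of cluster centers (>= intended number of macrostates).
#' @param seed integer seed (k-means++ is stochastic).
#' @param maxFit centers are fitted on a subsample of at most this many
#'   frames (default 5e4) and all frames then assigned in one pass.  The
#'   subsample is balanced across occupied integer coordination cells so
#'   that rarely populated species (e.g. the free metal in a strongly
#'   binding system) still attract centers.
#' @return A [MicrostateModel-class] (no transition matrix yet).
#' @export
assignMicrostates <- function(trajs, k, seed = 1L, maxFit = 5e4) {
  if (!is.null(trajs$frames)) trajs <- list(trajs)
  frames <- lapply(trajs, function(tr) {
    f <- as.matrix(tr$frames)
    if (nrow(f) < 2) stop("each trajectory needs at least 2 frames")
    if (any(f < 0)) stop("coordination numbers must be non-negative")
    f
  })
  dts <- vapply(trajs, function(tr) tr$dt, numeric(1))
  if (any(dts <= 0)) stop("dt must be positive")
  if (length(unique(dts)) > 1) stop("replicas must share the same dt")
  x <- do.call(rbind, frames)
  if (k > nrow(unique(x)))
    stop("k exceeds the number of distinct frames")
  rng <- newRNG(seed)
  xFit <- if (nrow(x) > maxFit) {
    cell <- paste(round(x[, 1]), round(x[, 2]))
    perCell <- max(50L, as.integer(ceiling(maxFit / length(unique(cell)))))
    keep <- unlist(lapply(split(seq_len(nrow(x)), cell), function(ix) {
      if (length(ix) <= perCell) ix
      else withRNG(rng, sample(ix, perCell))
    }), use.names = FALSE)
    x[keep, , drop = FALSE]
  } else x
  centers <- withRNG(rng, kmeansPlusPlusInit(xFit, k))
  fit <- lloyd(xFit, centers, tol = 1e-6, maxIter = 500L)
  cluster <- nearestCenter(x, fit$centers)
  lens <- vapply(frames, nrow, integer(1))
  splits <- rep(seq_along(frames), lens)
  new("MicrostateModel", centers = fit$centers,
      assignments = split(cluster, splits),
      dt = dts[1], lag = 0L,
      countMatrix = matrix(numeric(), 0, 0),
      transitionMatrix = matrix(numeric(), 0, 0),
      active = integer())
}

## D^2-weighted seeding
kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0)
      centers[j, ] <- x[sample.int(n, 1L), ]
    else
      centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

nearestCenter <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  max.col(-d, ties.method = "first")
}

lloyd <- function(x, centers, tol = 1e-6, maxIter = 500L) {
  k <- nrow(centers)
  for (it in seq_len(maxIter)) {
    cl <- nearestCenter(x, centers)
    newCenters <- centers
    for (j in seq_len(k)) {
      pts <- x[cl == j, , drop = FALSE]
      if (nrow(pts) == 0L) {
        # re-seed an empty cluster from the point farthest from its center
        far <- which.max(rowSums((x - centers[cl, , drop = FALSE])^2))
        message("k-means: re-seeding empty cluster ", j,
                " from farthest point")
        newCenters[j, ] <- x[far, ]
      } else {
        newCenters[j, ] <- colMeans(pts)
      }
    }
    shift <- max(rowSums((newCenters - centers)^2))
    centers <- newCenters
    if (shift < tol^2) break
  }
  list(centers = centers, cluster = nearestCenter(x, centers))
}
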