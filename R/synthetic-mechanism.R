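## Synthetic binding-event distance traces with known mechanism labels.
##
## Geometry of a planted event (entry frame t0):
##   - the event nitrogen ramps from bulk (6 A) through the 3.4 A cutoff
##     at t0 down to a bound distance (2.3 A) and stays bound;
##   - the leaving water ramps from its shell distance (2.3 A) through the
##     3.2 A cutoff outward to bulk, crossing before t0 (dissociative) or
##     after t0 (associative, so the shell is transiently overcoordinated);
##   - spurious negatives are nitrogen dips below the cutoff shorter than
##     the residence time.

rampTrace <- function(nFrames, dt, tCross, from, to, cutoff, rampPs = 2) {
  # distance crosses `cutoff` exactly at tCross, moving from `from` to `to`
  tt <- (seq_len(nFrames) - 1L) * dt
  slope <- (to - from) / rampPs
  tStart <- tCross - (cutoff - from) / slope
  d <- from + slope * (tt - tStart)
  d[tt < tStart] <- from
  d[d > max(from, to)] <- max(from, to)
  d[d < min(from, to)] <- min(from, to)
  d
}

#' Generate a labelled binding-event trajectory
#'
#' Plants `nEvents` genuine binding events of the requested mechanism
#' (recycled if a vector) separated by `spacing` ps, plus `nSpurious`
#' sub-residence nitrogen dips that a correct detector must ignore.  In
#' Cartesian mode the leaving water departs at `exitAngle` degrees (with
#' jitter `exitAngleSd`) from the entering nitrogen direction in the XY
#' plane.
#'
#' @param mechanism `"dissociative"`, `"associative"`, or a vector of
#'   labels, one per event (recycled).
#' @param nEvents number of genuine events (>= 1).
#' @param noiseSigma Gaussian distance noise sd, Angstrom (default 0).
#' @param seed integer seed.
#' @param nSpurious number of planted sub-residence dips (default 0).
#' @param dt frame interval, ps (default 0.1).
#' @param nWaters first-shell waters at the start (default 8, grown to
#'   `nEvents + 4` when more events are requested: each event consumes one
#'   leaving water).
#' @param spacing ps between events (default 60).
#' @param coordinates also emit Cartesian coordinates (default FALSE).
#' @param exitAngle mean exit angle of the leaving water, degrees
#'   (default 90).
#' @param exitAngleSd angular jitter sd, degrees (default 10).
#' @param leadTime ps of water exit before nitrogen entry (dissociative)
#'   or after it (associative); default 3 and 4 ps respectively.
#' @return A [DistanceTrajectory-class] with attribute `"groundTruth"`, a
#'   data.frame of the planted events (`time`, `nitrogen`, `mechanism`,
#'   `spurious`).
#' @export
synthBindingTrajectory <- function(mechanism = "dissociative", nEvents = 1L,
                                   noiseSigma = 0, seed = 1L, nSpurious = 0L,
                                   dt = 0.1, nWaters = max(8L, nEvents + 4L),
                                   spacing = 60,
                                   coordinates = FALSE, exitAngle = 90,
                                   exitAngleSd = 10, leadTime = NULL) {
  if (nEvents < 1) stop("nEvents must be >= 1")
  labels <- rep_len(mechanism, nEvents)
  stopifnot(all(labels %in% c("dissociative", "associative")))
  rng <- newRNG(seed)
  nReal <- nEvents; nDip <- as.integer(nSpurious)
  total <- nReal + nDip
  tEnd <- 40 + spacing * total
  nFrames <- as.integer(round(tEnd / dt)) + 1L
  tt <- (seq_len(nFrames) - 1L) * dt
  slots <- 40 + spacing * (seq_len(total) - 1L)
  # interleave genuine events and spurious dips deterministically
  kind <- rep("real", total)
  if (nDip > 0) kind[seq(2, by = 2, length.out = min(nDip, total %/% 2))] <- "dip"
  nLeft <- sum(kind == "dip")
  if (nLeft < nDip) kind[which(kind == "real")[seq_len(nDip - nLeft)] ] <- "dip"
  kind <- kind[order(slots)]
  realSlots <- slots[kind == "real"][seq_len(nReal)]
  dipSlots <- slots[kind == "dip"]

  nN <- total
  dN <- matrix(6, nFrames, nN)
  dO <- matrix(2.3, nFrames, nWaters)
  truth <- list()
  wNext <- 1L
  jN <- 0L
  for (e in seq_len(nReal)) {
    jN <- jN + 1L
    t0 <- realSlots[e]
    lab <- labels[e]
    lead <- if (is.null(leadTime)) if (lab == "dissociative") 3 else 4 else leadTime
    tExit <- if (lab == "dissociative") t0 - lead else t0 + lead
    dN[, jN] <- pmin(dN[, jN], rampTrace(nFrames, dt, t0, 6, 2.3, 3.4))
    dO[, wNext] <- rampTrace(nFrames, dt, tExit, 2.3, 6, 3.2)
    truth[[length(truth) + 1L]] <- data.frame(
      time = t0, nitrogen = jN, water = wNext,
      mechanism = lab, spurious = FALSE)
    wNext <- wNext + 1L
    if (wNext > nWaters) stop("not enough waters for the requested events")
  }
  for (s in seq_along(dipSlots)) {
    j <- nReal + s
    t0 <- dipSlots[s]
    # 5 ps excursion below the cutoff, then back out
    dip <- 6 - 3.2 * exp(-((tt - t0) / 2.5)^2)
    dN[, j] <- pmin(dN[, j], dip)
    truth[[length(truth) + 1L]] <- data.frame(
      time = t0, nitrogen = j, water = NA_integer_,
      mechanism = NA_character_, spurious = TRUE)
  }
  if (noiseSigma > 0) {
    dN <- pmax(dN + withRNG(rng, matrix(rnorm(length(dN), 0, noiseSigma),
                                        nFrames, nN)), 0)
    dO <- pmax(dO + withRNG(rng, matrix(rnorm(length(dO), 0, noiseSigma),
                                        nFrames, nWaters)), 0)
  }
  xyzMetal <- matrix(numeric(), 0, 3); xyzN <- list(); xyzO <- list()
  if (coordinates) {
    xyzMetal <- matrix(0, nFrames, 3)
    xyzN <- lapply(seq_len(nN), function(j) cbind(dN[, j], 0, 0))
    # waters spread over directions away from +X; the leaving waters sit at
    # the exit angle (jittered per event) in the XY plane
    baseAngle <- seq(30, 330, length.out = nWaters) * pi / 180
    angles <- baseAngle
    for (tr in truth) {
      if (!isTRUE(tr$spurious) && !is.na(tr$water))
        angles[tr$water] <- (exitAngle +
          withRNG(rng, rnorm(1, 0, exitAngleSd))) * pi / 180
    }
    xyzO <- lapply(seq_len(nWaters), function(j)
      cbind(dO[, j] * cos(angles[j]), dO[, j] * sin(angles[j]), 0))
  }
  traj <- DistanceTrajectory(dt, dN, dO, xyzMetal = xyzMetal,
                             xyzN = xyzN, xyzO = xyzO)
  attr(traj, "groundTruth") <- do.call(rbind, truth)
  traj
}
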