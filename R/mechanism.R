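## Water-ligand exchange mechanism analysis.
##
## A ligand nitrogen counts as bound while its distance to the metal is
## below the ligand cutoff (3.4 A); a water while below the water cutoff
## (3.2 A for Cd, 2.9 A for Ni).  Binding events are entries that persist
## for at least the residence time (20 ps); shorter excursions in either
## direction are treated as spurious re-crossings and smoothed away.  The
## mechanism label comes from the ordering of water departure and nitrogen
## entry and from transient overcoordination of the first shell.

#' Sharp coordination-number time series
#'
#' Counts, per frame, the ligand nitrogens within `cutoffLig` and the water
#' oxygens within `cutoffWat` of the metal.
#'
#' @param traj a [DistanceTrajectory-class].
#' @param cutoffLig metal-nitrogen cutoff, Angstrom (default 3.4).
#' @param cutoffWat metal-oxygen cutoff, Angstrom (default 3.2).
#' @return Data.frame with columns `time` (ps), `lig`, `wat`, `total`.
#' @export
coordinationSeries <- function(traj, cutoffLig = 3.4, cutoffWat = 3.2) {
  if (cutoffLig <= 0 || cutoffWat <= 0) stop("cutoffs must be positive")
  lig <- rowSums(traj@dN < cutoffLig)
  wat <- rowSums(traj@dO < cutoffWat)
  data.frame(time = (seq_len(nrow(traj@dN)) - 1L) * traj@dt,
             lig = lig, wat = wat, total = lig + wat)
}

## smooth a logical bound-indicator: drop runs (bound first, then unbound)
## shorter than minFrames
smoothRuns <- function(bound, minFrames) {
  for (state in c(TRUE, FALSE)) {
    r <- rle(bound)
    # interior short runs of `state` are spurious re-crossings
    short <- r$values == state & r$lengths < minFrames
    # never flip the leading/trailing run: truncation, not a re-crossing
    short[c(1, length(short))] <- FALSE
    r$values[short] <- !state
    bound <- inverse.rle(r)
  }
  bound
}

#' Detect ligand binding events
#'
#' An event is a frame at which a nitrogen enters the first coordination
#' shell (distance drops below `cutoff`) and remains inside for at least
#' `minResidence` ps.  Sub-residence excursions below or above the cutoff
#' are ignored as spurious binding/unbinding.  Each event is annotated
#' with its coordination-transition class (0-1, 1-2, ... bound nitrogens).
#'
#' @param traj a [DistanceTrajectory-class] spanning at least
#'   `2 * minResidence` ps.
#' @param cutoff metal-nitrogen cutoff, Angstrom (default 3.4).
#' @param minResidence minimum residence time, ps (default 20).
#' @param cutoffWat water cutoff used only for the annotation columns.
#' @return Data.frame with one row per event: `time` (ps of the entry
#'   frame), `frame`, `nitrogen`, `ligand`, `classFrom`, `classTo`.
#'   Zero rows when nothing is detected.
#' @export
detectBindingEvents <- function(traj, cutoff = 3.4, minResidence = 20,
                                cutoffWat = 3.2) {
  nFrames <- nrow(traj@dN)
  if (nFrames * traj@dt < 2 * minResidence)
    stop("trajectory shorter than twice the residence time")
  minFrames <- max(1L, as.integer(round(minResidence / traj@dt)))
  boundMat <- traj@dN < cutoff
  for (j in seq_len(ncol(boundMat)))
    boundMat[, j] <- smoothRuns(boundMat[, j], minFrames)
  nBound <- rowSums(boundMat)
  events <- list()
  for (j in seq_len(ncol(boundMat))) {
    b <- boundMat[, j]
    entries <- which(diff(c(FALSE, b)) == 1L)
    for (f in entries) {
      # residence requirement on the smoothed indicator
      runEnd <- f
      while (runEnd < nFrames && b[runEnd + 1L]) runEnd <- runEnd + 1L
      if ((runEnd - f + 1L) < minFrames) next
      pre <- if (f > 1L) nBound[f - 1L] else 0L
      events[[length(events) + 1L]] <- data.frame(
        time = (f - 1L) * traj@dt, frame = f, nitrogen = j,
        ligand = traj@ligandOfN[j],
        classFrom = pre, classTo = pre + 1L)
    }
  }
  if (!length(events))
    return(data.frame(time = numeric(), frame = integer(),
                      nitrogen = integer(), ligand = integer(),
                      classFrom = integer(), classTo = integer()))
  out <- do.call(rbind, events)
  out[order(out$time), , drop = FALSE]
}

## most frequent value
statMode <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

#' Classify the exchange mechanism of binding events
#'
#' For each event, the summed first-shell coordination (water + ligand) in
#' a window of `window` ps around the entry frame is compared with its
#' pre-event baseline (the mode over the pre-window): *dissociative* when
#' the leaving water exits before the nitrogen enters and the total
#' coordination never exceeds the baseline; *associative* when the water
#' is still inside at the entry frame and leaves afterwards, with at least
#' one over-coordinated frame in between; *ambiguous* otherwise
#' (e.g. exchange within a single frame).  The leaving water is the
#' first-shell water with the latest exit time inside the window.  Events
#' whose window is truncated by the trajectory edge are skipped with a
#' warning.
#'
#' @param traj a [DistanceTrajectory-class].
#' @param events data.frame from [detectBindingEvents()].
#' @param window half-window, ps (default 20).
#' @param cutoffLig,cutoffWat shell cutoffs, Angstrom.
#' @return `events` with added columns `mechanism` (factor: dissociative /
#'   associative / ambiguous), `leavingWater` (column index into the water
#'   distances, NA when none left), and `waterExitTime` (ps, relative to
#'   the entry frame).
#' @export
classifyMechanism <- function(traj, events, window = 20,
                              cutoffLig = 3.4, cutoffWat = 3.2) {
  nFrames <- nrow(traj@dN)
  w <- as.integer(round(window / traj@dt))
  cs <- coordinationSeries(traj, cutoffLig, cutoffWat)
  mech <- character(nrow(events))
  leaving <- integer(nrow(events)); exitT <- numeric(nrow(events))
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    f <- events$frame[i]
    if (f - w < 1L || f + w > nFrames) {
      warning("event at ", events$time[i],
              " ps skipped: window truncated by trajectory edge")
      next
    }
    keep[i] <- TRUE
    pre <- (f - w):(f - 1L)
    win <- (f - w):(f + w)
    baseline <- statMode(cs$total[pre])
    over <- cs$total[win] > baseline
    # exits of first-shell waters inside the window
    exits <- rep(NA_integer_, ncol(traj@dO))
    for (jw in seq_len(ncol(traj@dO))) {
      inside <- traj@dO[win, jw] < cutoffWat
      if (!any(inside)) next
      trans <- which(diff(inside) == -1L)
      # only waters that actually leave and stay out to the window end
      lastOut <- if (length(trans)) trans[length(trans)] else NA_integer_
      if (!is.na(lastOut) && !any(inside[(lastOut + 1L):length(inside)]))
        exits[jw] <- lastOut
    }
    if (all(is.na(exits))) {
      mech[i] <- "ambiguous"; leaving[i] <- NA_integer_; exitT[i] <- NA_real_
      next
    }
    leaving[i] <- which.max(exits)
    exitFrame <- win[exits[leaving[i]]]      # last frame still inside
    exitT[i] <- (exitFrame - f) * traj@dt
    bracket <- if (exitFrame >= f) seq.int(f, exitFrame) else integer(0)
    if (exitFrame < f - 1L && !any(over)) {
      mech[i] <- "dissociative"
    } else if (exitFrame >= f && length(bracket) &&
               any(cs$total[bracket] > baseline)) {
      mech[i] <- "associative"
    } else {
      mech[i] <- "ambiguous"
    }
  }
  out <- events[keep, , drop = FALSE]
  out$mechanism <- factor(mech[keep],
                          levels = c("dissociative", "associative", "ambiguous"))
  out$leavingWater <- leaving[keep]
  out$waterExitTime <- exitT[keep]
  out
}

#' Summarise mechanisms per coordination-transition class
#'
#' Contingency of transition class (0-1, 1-2, ...) against mechanism label
#' with exact binomial 95% confidence intervals on the dissociative
#' fraction.
#'
#' @param events classified events from [classifyMechanism()].
#' @return Data.frame with one row per transition class: counts per label,
#'   `fracDissociative`, `ciLow`, `ciHigh`; classes without events are
#'   reported with `n = 0` and NA fractions.
#' @export
mechanismSummary <- function(events) {
  if (!nrow(events)) stop("no events to summarise")
  classes <- sort(unique(events$classTo))
  rows <- lapply(classes, function(cl) {
    e <- events[events$classTo == cl, ]
    n <- nrow(e)
    nd <- sum(e$mechanism == "dissociative")
    na <- sum(e$mechanism == "associative")
    if (n == 0)
      return(data.frame(class = paste0(cl - 1, "-", cl), n = 0L,
                        dissociative = 0L, associative = 0L, ambiguous = 0L,
                        fracDissociative = NA_real_,
                        ciLow = NA_real_, ciHigh = NA_real_))
    ci <- stats::binom.test(nd, n)$conf.int
    data.frame(class = paste0(cl - 1, "-", cl), n = n,
               dissociative = nd, associative = na,
               ambiguous = n - nd - na,
               fracDissociative = nd / n, ciLow = ci[1], ciHigh = ci[2])
  })
  do.call(rbind, rows)
}
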