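## Exit geometry of the leaving water: per-frame rigid transform placing
## the metal at the origin and the entering nitrogen along +X (minimal
## rotation bringing the metal->N direction onto the x axis), then the
## in-plane (x, y) projection of the leaving water and the N-metal-O angle.

## Rodrigues rotation taking unit vector a onto unit vector b
rotationOnto <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {           # antiparallel: rotate pi about any normal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  V <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + V + V %*% V / (1 + c_)
}

#' Exit geometry of the leaving water around a binding event
#'
#' For every frame in a +/- `window` ps interval around the event's entry
#' frame, translates the metal to the origin, rotates the entering
#' nitrogen onto the +X axis (minimal rotation, so all pairwise distances
#' are preserved), and records the (x, y) projection of the leaving water
#' together with the N-metal-O angle.
#'
#' @param traj a [DistanceTrajectory-class] with Cartesian coordinates.
#' @param event one row of the classified event table (needs `frame`,
#'   `nitrogen`, `leavingWater`).
#' @param window half-window in ps (default 5).
#' @param shellRadius first-shell radius marker, Angstrom (default 3.2).
#' @return List of class `"ExitGeometry"`: `time` (ps relative to entry),
#'   `xy` (n x 2 projected positions), `angle` (degrees, in \[0, 180\]),
#'   `distance` (metal-O, Angstrom), `shellRadius`.
#' @export
leavingWaterGeometry <- function(traj, event, window = 5,
                                 shellRadius = 3.2) {
  if (!nrow(traj@xyzMetal)) stop("trajectory carries no coordinates")
  jN <- event$nitrogen[1]; jW <- event$leavingWater[1]
  if (is.na(jW)) stop("event has no identified leaving water")
  f <- event$frame[1]
  w <- as.integer(round(window / traj@dt))
  frames <- max(1L, f - w):min(nrow(traj@xyzMetal), f + w)
  xy <- matrix(NA_real_, length(frames), 2)
  ang <- numeric(length(frames)); dist <- numeric(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[i]
    m <- traj@xyzMetal[fr, ]
    nvec <- traj@xyzN[[jN]][fr, ] - m
    if (sqrt(sum(nvec^2)) < 1e-9)
      stop("degenerate geometry: entering nitrogen coincides with the metal")
    ovec <- traj@xyzO[[jW]][fr, ] - m
    R <- rotationOnto(nvec, c(1, 0, 0))
    o2 <- as.vector(R %*% ovec)
    xy[i, ] <- o2[1:2]
    dist[i] <- sqrt(sum(ovec^2))
    ang[i] <- acos(pmin(1, pmax(-1,
      sum(nvec * ovec) / (sqrt(sum(nvec^2)) * sqrt(sum(ovec^2)))))) * 180 / pi
  }
  structure(list(time = (frames - f) * traj@dt, xy = xy, angle = ang,
                 distance = dist, shellRadius = shellRadius),
            class = "ExitGeometry")
}
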