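## Minimum free-energy pathway extraction: the path between two grid cells
## minimising the maximum free energy encountered (minimax path), found by
## binary search over the candidate barrier level plus 4-connected
## flood-fill connectivity, then traced by breadth-first search restricted
## to cells at or below the barrier.

#' Minimum free-energy path between two grid cells
#'
#' Returns the 4-connected path from `start` to `end` through visited cells
#' that minimises the highest free energy along the way, together with that
#' barrier value.  The barrier level is located by bisection on the sorted
#' unique grid values (connectivity is monotone in the threshold); the path
#' itself is the shortest one through the admissible cells.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param start,end length-2 integer vectors `(row, col)` into the grid;
#'   both must be visited cells.
#' @return List with `path` (n x 2 integer matrix of cells), `barrier`
#'   (kJ/mol) and `barrierCell` (the arg max along the path).
#' @export
minFreeEnergyPath <- function(fes, start, end) {
  v <- fes@values
  nr <- nrow(v); nc <- ncol(v)
  start <- as.integer(start); end <- as.integer(end)
  idx <- function(cell) (cell[2] - 1L) * nr + cell[1]
  if (!is.finite(v[idx(start)])) stop("start cell is unvisited")
  if (!is.finite(v[idx(end)])) stop("end cell is unvisited")

  connectedAt <- function(thr) {
    ok <- is.finite(v) & v <= thr
    if (!ok[idx(start)] || !ok[idx(end)]) return(FALSE)
    !is.null(bfsPath(ok, start, end, nr, nc))
  }
  lev <- sort(unique(v[is.finite(v)]))
  lev <- lev[lev >= max(v[idx(start)], v[idx(end)])]
  lo <- 1L; hi <- length(lev)
  if (!connectedAt(lev[hi]))
    stop("no connected path through visited cells between start and end")
  while (lo < hi) {  # smallest level at which start/end join
    mid <- (lo + hi) %/% 2L
    if (connectedAt(lev[mid])) hi <- mid else lo <- mid + 1L
  }
  barrier <- lev[hi]
  path <- bfsPath(is.finite(v) & v <= barrier, start, end, nr, nc)
  pf <- v[path]
  list(path = path, barrier = barrier,
       barrierCell = path[which.max(pf), ])
}

## shortest path by BFS over admissible cells; returns n x 2 matrix or NULL
bfsPath <- function(ok, start, end, nr, nc) {
  idx <- function(cell) (cell[2] - 1L) * nr + cell[1]
  startI <- idx(start); endI <- idx(end)
  prev <- integer(nr * nc)
  queue <- integer(nr * nc); qh <- 1L; qt <- 1L
  queue[qt] <- startI; qt <- qt + 1L
  prev[startI] <- -1L
  while (qh < qt) {
    cur <- queue[qh]; qh <- qh + 1L
    if (cur == endI) break
    r <- ((cur - 1L) %% nr) + 1L
    cc <- ((cur - 1L) %/% nr) + 1L
    for (d in 1:4) {
      r2 <- r + c(-1L, 1L, 0L, 0L)[d]
      c2 <- cc + c(0L, 0L, -1L, 1L)[d]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      i2 <- (c2 - 1L) * nr + r2
      if (!ok[i2] || prev[i2] != 0L) next
      prev[i2] <- cur
      queue[qt] <- i2; qt <- qt + 1L
    }
  }
  if (prev[endI] == 0L && endI != startI) return(NULL)
  cells <- integer(0)
  cur <- endI
  while (cur != -1L) {
    cells <- c(cur, cells)
    cur <- prev[cur]
  }
  cbind(row = ((cells - 1L) %% nr) + 1L,
        col = ((cells - 1L) %/% nr) + 1L)
}
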