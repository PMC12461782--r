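## Synthetic free-energy surfaces: congruent paraboloid basins centered at
## integer (lig, wat) coordination pairs with depths given by the species
## levels, optional Gaussian noise, and Inf outside the basins.  Because
## the basin stencils are congruent, the Boltzmann-sum projection recovers
## the input levels exactly at zero noise.

#' Generate a basin-structured free-energy surface
#'
#' One paraboloid basin per species, centered at (nLig_i, watMax - nLig_i),
#' with F = dG_i + curvature * r^2 inside radius `basinWidth` and Inf
#' outside; independent Gaussian noise of sd `noiseSigma` is added to every
#' visited cell.
#'
#' @param levels a [SpeciesLevels-class].
#' @param basinWidth basin radius in coordination units (default 0.45);
#'   basins of neighbouring species must not overlap.
#' @param noiseSigma Gaussian noise sd, kJ/mol (default 0).
#' @param seed integer seed.
#' @param watMax water coordination of the bare metal (default 8).
#' @param spacing grid spacing (default 0.1).
#' @param curvature basin stiffness, kJ/mol per squared coordination unit
#'   (default 30).
#' @param temperature K.
#' @return A [FreeEnergySurface-class].
#' @export
synthFes <- function(levels, basinWidth = 0.45, noiseSigma = 0, seed = 1L,
                     watMax = 8, spacing = 0.1, curvature = 30,
                     temperature = 300) {
  if (basinWidth <= 0) stop("basinWidth must be positive")
  centers <- cbind(lig = levels@nLig, wat = watMax - levels@nLig)
  if (nrow(centers) > 1) {
    dmin <- min(dist(centers))
    if (2 * basinWidth > dmin)
      stop("basins overlap: 2 * basinWidth (", 2 * basinWidth,
           ") exceeds the smallest center distance (", format(dmin), ")")
  }
  axisLig <- seq(min(centers[, 1]) - 0.5, max(centers[, 1]) + 0.5, by = spacing)
  axisWat <- seq(min(centers[, 2]) - 0.5, max(centers[, 2]) + 0.5, by = spacing)
  v <- matrix(Inf, length(axisLig), length(axisWat))
  for (i in seq_len(nrow(centers))) {
    r2 <- outer((axisLig - centers[i, 1])^2, (axisWat - centers[i, 2])^2, "+")
    inside <- r2 <= basinWidth^2
    v[inside] <- levels@deltaG[i] + curvature * r2[inside]
  }
  if (noiseSigma > 0) {
    rng <- newRNG(seed)
    vis <- is.finite(v)
    v[vis] <- v[vis] + withRNG(rng, rnorm(sum(vis), 0, noiseSigma))
  }
  FreeEnergySurface(v, axisLig, axisWat, temperature)
}
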