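## Thermodynamic bookkeeping of complex formation: dG = dH + (-T dS),
## per-denticity normalisation, and entropy differences between ligand
## series members in J mol^-1 K^-1.

#' Decompose a binding free energy into enthalpy and entropy terms
#'
#' Given dG and dH of formation of a complex whose ligands contribute `n`
#' donor groups in total, computes -T dS = dG - dH and the per-donor-group
#' normalised columns dH/n and -T dS/n used to compare ligands of different
#' denticity.
#'
#' @param deltaG,deltaH kJ/mol (vectorised over rows).
#' @param n total donor groups bound in the complex (>= 1).
#' @param temperature K.
#' @param species optional label(s).
#' @return A one-row data.frame with columns `species`, `n`, `delta_g`,
#'   `delta_h`, `minus_t_delta_s`, `delta_h_per_n`, `minus_t_delta_s_per_n`
#'   (all kJ/mol) and `delta_s_j_mol_k` (J mol^-1 K^-1).
#' @examples
#' thermoDecompose(-51.9, -87.0, n = 4)  # -T dS = 35.1, dH/n = -21.75
#' @export
thermoDecompose <- function(deltaG, deltaH, n, temperature = 300,
                            species = NA_character_) {
  if (any(n < 1)) stop("n (denticity of the complex) must be >= 1")
  mtds <- deltaG - deltaH
  data.frame(species = species, n = n,
             delta_g = deltaG, delta_h = deltaH,
             minus_t_delta_s = mtds,
             delta_h_per_n = deltaH / n,
             minus_t_delta_s_per_n = mtds / n,
             delta_s_j_mol_k = -mtds / temperature * 1000)
}

#' Entropy difference between two thermodynamic records
#'
#' ddS = ((-T dS)_B - (-T dS)_A) / T x 1000, in J mol^-1 K^-1: the entropic
#' gain of record A relative to record B (positive when A is entropically
#' favoured, the sign convention used when comparing a chelate with the
#' equivalent monodentate complex).
#'
#' @param recordA,recordB one-row data.frames from [thermoDecompose()], or
#'   bare -T dS values in kJ/mol.
#' @param temperature K.
#' @return ddS in J mol^-1 K^-1.
#' @examples
#' deltaDeltaS(20.1, 14.2)  # nme_2 vs en_1: ~20 J/mol/K
#' @export
deltaDeltaS <- function(recordA, recordB, temperature = 300) {
  g <- function(r) if (is.data.frame(r)) r$minus_t_delta_s else r
  (g(recordA) - g(recordB)) / temperature * 1000
}
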