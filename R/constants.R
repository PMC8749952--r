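# Physicochemical reference tables used across the package.

#: Monoisotopic residue masses (Da) for the 20 canonical amino acids.
#: Residue mass = peptide-bond residue, i.e. free amino acid minus water.
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#: Mass of water added once per peptide (N-terminal H + C-terminal OH).
MASS_WATER <- 18.010565

#: Kyte-Doolittle hydropathy index per residue.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#: Avogadro constant (2019 SI exact value), copies per mole.
AVOGADRO <- 6.02214076e23

CANONICAL_RESIDUES <- names(MONO_RESIDUE_MASS)

# Conservative substitutions permitted when scrambling a standard peptide.
# Polar pairs exchange side chains of near-identical character (S/T, D/E,
# N/Q, F/Y); aliphatic residues may only move to a neighbour of similar
# hydropathy along G < A < V < L < I (V<->I is included: their
# Kyte-Doolittle indices differ by just 0.3).
ALLOWED_SUBSTITUTIONS <- list(
  c("S", "T"), c("D", "E"), c("N", "Q"), c("F", "Y"),
  c("G", "A"), c("A", "V"), c("V", "L"), c("L", "I"), c("V", "I")
)

#' Residues a given residue may be substituted with under the scrambling rules
#' @param residue single canonical residue
#' @return character vector of allowed replacement residues (possibly empty)
#' @keywords internal
allowed_substitutes <- function(residue) {
  out <- character(0)
  for (pair in ALLOWED_SUBSTITUTIONS) {
    if (pair[1] == residue) out <- c(out, pair[2])
    if (pair[2] == residue) out <- c(out, pair[1])
  }
  unique(out)
}
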