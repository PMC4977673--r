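## Physical constants and residue tables used throughout the package.
## All masses are monoisotopic (Da); precursor-level bookkeeping at 10 ppm
## tolerance implies monoisotopic, not average, masses.

# Atomic monoisotopic masses (CODATA/IUPAC); electron subtracted for cations.
.ATOM <- c(
  C = 12.0,
  H = 1.00782503207,
  O = 15.9949146196,
  N = 14.0030740048,
  Na = 22.9897692809
)
.ELECTRON <- 0.00054857991

.MASS_WATER <- 2 * .ATOM[["H"]] + .ATOM[["O"]]
.MASS_CH2 <- .ATOM[["C"]] + 2 * .ATOM[["H"]]

# Monoisotopic residue masses for the 20 standard amino acids.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AMINO_ACIDS <- names(.RESIDUE_MASS)

# Monosaccharide residue masses (loss of water already accounted for).
# Hex = C6H10O5, HexNAc = C8H13NO5.
.MASS_HEX <- 6 * .ATOM[["C"]] + 10 * .ATOM[["H"]] + 5 * .ATOM[["O"]]
.MASS_HEXNAC <- 8 * .ATOM[["C"]] + 13 * .ATOM[["H"]] + .ATOM[["N"]] +
  5 * .ATOM[["O"]]

# Supported peptide modifications. GlcNAc_remnant is the single GlcNAc that
# Endo H leaves attached to the sequon Asn (+203 Da); carbamidomethyl is the
# fixed Cys alkylation; oxidation is variable Met oxidation.
.MODIFICATIONS <- data.frame(
  name = c("GlcNAc_remnant", "carbamidomethyl", "oxidation"),
  target = c("N", "C", "M"),
  delta = c(203.07937, 57.02146, 15.99491),
  stringsAsFactors = FALSE
)

# Side-chain chemical classes used for flanking-residue profiles.
.CHEMICAL_CLASSES <- list(
  Hydrophobic = c("A", "V", "L", "I", "M"),
  Aromatic = c("F", "Y", "W"),
  Polar_uncharged = c("S", "T", "N", "C", "Q"),
  Acidic = c("D", "E"),
  Basic = c("K", "R", "H"),
  Unique = c("G", "P")
)

.SITE_STATUSES <- c("validated", "non_validated", "non_covered", "unset")

#' Modification mass table
#'
#' Monoisotopic mass deltas for the peptide modifications the pipeline
#' understands: the +203.0794 Da GlcNAc remnant on Asn (the single
#' N-acetylglucosamine Endo H leaves on a formerly glycosylated sequon),
#' fixed carbamidomethylation of Cys (+57.0215) and variable oxidation of
#' Met (+15.9949).
#'
#' @return A data.frame with columns \code{name}, \code{target} (residue
#'   letter) and \code{delta} (Da).
#' @examples
#' modificationMasses()
#' @export
modificationMasses <- function() .MODIFICATIONS

#' Chemical classes of amino-acid side chains
#'
#' The six-class grouping used for flanking-residue profiles: Hydrophobic
#' (A, V, L, I, M), Aromatic (F, Y, W), Polar uncharged (S, T, N, C, Q),
#' Acidic (D, E), Basic (K, R, H) and Unique (G, P).
#'
#' @return Named list of character vectors partitioning the 20 standard
#'   residues.
#' @export
chemicalClasses <- function() .CHEMICAL_CLASSES
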