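#' Amino-acid constants and per-residue lookup tables
#'
#' Fixed 20-amino-acid ordering and the per-residue physicochemical scales
#' used to build point-cloud features. The ordering is the PSI-BLAST column
#' order (A R N D C Q E G H I L K M F P S T W Y V); one-hot and PSSM columns
#' both follow it, so the two 20-column blocks are directly comparable.
#'
#' Scales (raw values, normalised once at table-construction time):
#' \itemize{
#'   \item charge: isoelectric point of the free amino acid, rescaled to
#'     \eqn{[-1, 1]} by min-max over the 20 residues;
#'   \item polarity: Grantham polarity, min-max to \eqn{[0, 1]};
#'   \item polarizability: Charton-Charton polarizability, min-max to
#'     \eqn{[0, 1]};
#'   \item hydrophobicity: Kyte-Doolittle hydropathy, min-max to \eqn{[0, 1]}.
#' }
#' Maximum accessible surface areas (Angstrom^2) are the theoretical
#' Gly-X-Gly values of Tien et al. (2013), used to express per-residue
#' accessibility as a fraction of the fully exposed residue.
#'
#' @format \code{aa_order} is a character vector of the 20 one-letter codes.
#' @name aa_tables
#' @keywords internal
NULL

# PSI-BLAST column ordering; shared by the one-hot block and the PSSM block.
aa_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

aa_one_to_three <- structure(names(aa_three_to_one), names = aa_three_to_one)

.minmax01 <- function(x) (x - min(x)) / (max(x) - min(x))

# Isoelectric points of the free amino acids.
.aa_pi_raw <- c(
  A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07, Q = 5.65, E = 3.22,
  G = 5.97, H = 7.59, I = 6.02, L = 5.98, K = 9.74, M = 5.74, F = 5.48,
  P = 6.30, S = 5.68, T = 5.60, W = 5.89, Y = 5.66, V = 5.96
)[aa_order]

# Grantham (1974) polarity.
.aa_polarity_raw <- c(
  A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
  G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
  P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9
)[aa_order]

# Charton & Charton (1982) polarizability.
.aa_polarizability_raw <- c(
  A = 0.046, R = 0.291, N = 0.134, D = 0.105, C = 0.128, Q = 0.180,
  E = 0.151, G = 0.000, H = 0.230, I = 0.186, L = 0.186, K = 0.219,
  M = 0.221, F = 0.290, P = 0.131, S = 0.062, T = 0.108, W = 0.409,
  Y = 0.298, V = 0.140
)[aa_order]

# Kyte & Doolittle (1982) hydropathy.
.aa_hydropathy_raw <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)[aa_order]

# Normalised once; charge to [-1, 1], the rest to [0, 1].
aa_charge         <- 2 * .minmax01(.aa_pi_raw) - 1
aa_polarity       <- .minmax01(.aa_polarity_raw)
aa_polarizability <- .minmax01(.aa_polarizability_raw)
aa_hydrophobicity <- .minmax01(.aa_hydropathy_raw)

# Theoretical maximum ASA (Gly-X-Gly), Tien et al. 2013, Angstrom^2.
aa_max_asa <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)[aa_order]

# Van der Waals radii (Angstrom) of the heavy elements retained in clouds.
element_vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

heavy_elements <- names(element_vdw_radius)

#' Column names of the 53-feature point cloud, in canonical order
#'
#' Coordinates (x, y, z), B factor, occupancy, N-terminus distance, the two
#' secondary-structure indicators, accessible area, the 20-column amino-acid
#' one-hot block, four physicochemical scales and the 20-column PSSM block.
#'
#' @return Character vector of length 53.
#' @export
#' @examples
#' point_cloud_columns()[1:6]
point_cloud_columns <- function() {
  c("x", "y", "z", "b_factor", "occupancy", "nterm_distance",
    "is_helix", "is_sheet", "accessible_area",
    paste0("aa_", aa_order),
    "charge", "polarity", "polarizability", "hydrophobicity",
    paste0("pssm_", aa_order))
}
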