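#' @import methods
#' @importFrom stats median sd rnorm rlogis runif cor setNames
#' @importFrom utils read.delim write.table
NULL

## The 20 standard amino acids, one-letter, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

#' Amino-acid chemical classes
#'
#' The five-way partition of the 20 standard amino acids used by the per-CDR
#' contact-count features: charged (R, H, K, D, E), aromatic (F, Y, W), polar
#' (S, T, N, Q), hydrophobic (A, V, I, L, M) and special (C, G, P). Histidine
#' is charged only, never aromatic.
#'
#' @return Named character vector mapping one-letter amino-acid codes to
#'   class labels.
#' @examples
#' chemClass()[["H"]]
#' @export
chemClass <- function() {
  cls <- c(
    R = "charged", H = "charged", K = "charged", D = "charged", E = "charged",
    F = "aromatic", Y = "aromatic", W = "aromatic",
    S = "polar", T = "polar", N = "polar", Q = "polar",
    A = "hydrophobic", V = "hydrophobic", I = "hydrophobic",
    L = "hydrophobic", M = "hydrophobic",
    C = "special", G = "special", P = "special")
  cls[AA20]
}

CHEM_CLASSES <- c("charged", "aromatic", "polar", "hydrophobic", "special")

CDR_IDS <- c("H1", "H2", "H3", "L1", "L2", "L3")

#' Default CDR boundaries (North definition, Chothia numbering)
#'
#' Inclusive start/end Chothia positions for the six CDR loops. These
#' boundaries are a package constant and can be overridden per complex by
#' passing an explicit annotation table to \code{\link{parseComplex}} or
#' \code{\link{assignCdrs}}.
#'
#' @return data.frame with columns \code{cdr_id}, \code{chain_role}
#'   (\code{"heavy"} or \code{"light"}), \code{start}, \code{end}.
#' @examples
#' cdrBoundaries()
#' @export
cdrBoundaries <- function() {
  data.frame(
    cdr_id = CDR_IDS,
    chain_role = c("heavy", "heavy", "heavy", "light", "light", "light"),
    start = c(23L, 50L, 93L, 24L, 49L, 89L),
    end   = c(35L, 58L, 102L, 34L, 56L, 97L),
    stringsAsFactors = FALSE)
}

## Residue chemistry used by the interaction-network edge detectors.
HBOND_CAPABLE <- c("S", "T", "N", "Q", "Y", "H", "K", "R", "D", "E", "W")
POSITIVE_AA <- c("R", "K", "H")
NEGATIVE_AA <- c("D", "E")
AROMATIC_AA <- c("F", "Y", "W")
HYDROPHOBIC_AA <- c("A", "V", "I", "L", "M")

FEATURE_SET_NAMES <- c("aa_counts", "aa_counts_CDR", "num_multivalent",
                       "Ab_info", "SIN", "AIF", "dMaSIF", "Energetics")

## Fixed per-set widths (Ab_info is data-driven, hence absent).
FEATURE_SET_WIDTHS <- c(aa_counts = 400L, aa_counts_CDR = 150L,
                        num_multivalent = 7L, SIN = 26L, AIF = 26L,
                        dMaSIF = 26L, Energetics = 18L)

ENERGETICS_FIELDS <- c(
  "n_epitope_residues", "epitope_SASA", "epitope_total_energy",
  "interaction_total_energy", "crossterm_interface_energy", "interface_dG",
  "separated_interface_energy_ratio", "total_complex_energy",
  "antibody_normalized_score", "antigen_normalized_score",
  "sc_total", "dSASA",
  "H1_interaction_energy", "H2_interaction_energy", "H3_interaction_energy",
  "L1_interaction_energy", "L2_interaction_energy", "L3_interaction_energy")
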