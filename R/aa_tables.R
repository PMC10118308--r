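# Element- and residue-level lookup tables shared across the package.

#' Van der Waals radii by element
#'
#' Fixed element-keyed radius table used for contact detection and
#' solvent-accessible surface area. Elements absent from the table fall back
#' to the generic heavy-atom radius of 1.8 Angstrom.
#'
#' @format Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20
)

.vdw_default <- 1.8

#' Look up van der Waals radii for a vector of element symbols
#'
#' @param element character vector of element symbols (e.g. "C", "ZN").
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  if (any(is.na(el) | el == "" | !grepl("^[A-Z]{1,2}$", el))) {
    bad <- which(is.na(el) | el == "" | !grepl("^[A-Z]{1,2}$", el))
    stop("unresolvable element symbol for atom index ", bad[1L])
  }
  r <- unname(vdw_radii[el])
  r[is.na(r)] <- .vdw_default
  r
}

# Elements treated as metals; ligands made up exclusively of these never
# enter scoring.
.metal_elements <- c(
  "LI", "NA", "K", "RB", "CS", "BE", "MG", "CA", "SR", "BA",
  "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL", "GA",
  "MO", "W", "V", "CR", "PT", "AU", "AG", "PB", "SN"
)

# Modified residues kept as part of the protein chain when numbered in-chain.
.modified_residues <- c("MSE", "SEC", "PYL", "SEP", "TPO", "PTR")

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Three-to-one amino-acid code map
#' @keywords internal
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T", PTR = "Y"
)

.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa1to3 <- stats::setNames(names(.aa3to1)[1:20], .aa3to1[1:20])

#' Hydrophobic amino acids
#'
#' The seven-residue hydrophobic set (Cys, Phe, Ile, Leu, Met, Val, Tyr)
#' used for interface hydrophobicity comparisons.
#' @export
hydrophobic_aa <- c("C", "F", "I", "L", "M", "V", "Y")

#' Maximum solvent accessibility in an extended Gly-X-Gly tripeptide
#'
#' Theoretical per-residue reference areas (Angstrom^2) used as the
#' denominator of relative solvent accessibility (RSA), after Tien et al.
#' (2013).
#'
#' @format Named numeric vector keyed by one-letter amino-acid code.
#' @export
gxg_reference_sasa <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

#' Fraction of residues that are hydrophobic
#'
#' @param aa character vector of one-letter amino-acid codes.
#' @return fraction in \[0, 1\] of residues in the 7-member hydrophobic set
#'   (C, F, I, L, M, V, Y).
#' @export
hydrophobic_fraction <- function(aa) {
  if (length(aa) == 0L) stop("empty residue set")
  mean(aa %in% hydrophobic_aa)
}
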