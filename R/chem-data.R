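# Element and residue chemistry tables used by the constraint-network and
# interaction modules. Radii are Bondi (vdW) and Cordero-style covalent radii.

.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
                FE = 2.00, ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75,
                CA = 2.31, MN = 2.00)
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
                FE = 1.32, ZN = 1.22, MG = 1.41)

vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

cov_radius <- function(element) {
  r <- .COV_RADII[toupper(element)]
  r[is.na(r)] <- 0.77
  unname(r)
}

# Side-chain heavy-atom bond templates (backbone N-CA, CA-C, C-O, C-OXT are
# added generically). Each entry is a 2-column matrix of atom-name pairs.
.SIDECHAIN_BONDS <- list(
  GLY = NULL,
  ALA = rbind(c("CA", "CB")),
  SER = rbind(c("CA", "CB"), c("CB", "OG")),
  CYS = rbind(c("CA", "CB"), c("CB", "SG")),
  THR = rbind(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  VAL = rbind(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")),
  LEU = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  ILE = rbind(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  MET = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PRO = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  PHE = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
              c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  TYR = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
              c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
              c("CZ", "OH")),
  TRP = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
              c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
              c("CD2", "CE3"), c("CE2", "CZ2"), c("CE3", "CZ3"),
              c("CZ2", "CH2"), c("CZ3", "CH2")),
  ASP = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  ASN = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  GLU = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
              c("CD", "OE2")),
  GLN = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
              c("CD", "NE2")),
  LYS = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
              c("CE", "NZ")),
  ARG = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
              c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  HIS = rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
              c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2"))
)

# Bonds with double / partial-double character (locked, 6 bars) beyond the
# generic peptide C-N and carbonyl C-O: aromatic rings, carboxylates,
# amides, the guanidinium group.
.LOCKED_SIDECHAIN_BONDS <- list(
  PHE = rbind(c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
              c("CE1", "CZ"), c("CE2", "CZ")),
  TYR = rbind(c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
              c("CE1", "CZ"), c("CE2", "CZ")),
  TRP = rbind(c("CG", "CD1"), c("CG", "CD2"), c("CD1", "NE1"), c("NE1", "CE2"),
              c("CD2", "CE2"), c("CD2", "CE3"), c("CE2", "CZ2"),
              c("CE3", "CZ3"), c("CZ2", "CH2"), c("CZ3", "CH2")),
  HIS = rbind(c("CG", "ND1"), c("CG", "CD2"), c("ND1", "CE1"), c("CD2", "NE2"),
              c("CE1", "NE2")),
  ASP = rbind(c("CG", "OD1"), c("CG", "OD2")),
  GLU = rbind(c("CD", "OE1"), c("CD", "OE2")),
  ASN = rbind(c("CG", "OD1"), c("CG", "ND2")),
  GLN = rbind(c("CD", "OE1"), c("CD", "NE2")),
  ARG = rbind(c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2"))
)

# H-bond donor heavy atoms (require an attached hydrogen) and acceptors,
# with hybridization of the heavy atom. Backbone N (donor, sp2) and O
# (acceptor, sp2) are handled generically.
.SIDECHAIN_DONORS <- list(
  SER = c(OG = "sp3"), THR = c(OG1 = "sp3"), TYR = c(OH = "sp2"),
  CYS = c(SG = "sp3"), LYS = c(NZ = "sp3"),
  ARG = c(NE = "sp2", NH1 = "sp2", NH2 = "sp2"),
  HIS = c(ND1 = "sp2", NE2 = "sp2"), TRP = c(NE1 = "sp2"),
  ASN = c(ND2 = "sp2"), GLN = c(NE2 = "sp2")
)
.SIDECHAIN_ACCEPTORS <- list(
  SER = c(OG = "sp3"), THR = c(OG1 = "sp3"), TYR = c(OH = "sp2"),
  CYS = c(SG = "sp3"), MET = c(SD = "sp3"),
  ASP = c(OD1 = "sp2", OD2 = "sp2"), GLU = c(OE1 = "sp2", OE2 = "sp2"),
  ASN = c(OD1 = "sp2"), GLN = c(OE1 = "sp2"),
  HIS = c(ND1 = "sp2", NE2 = "sp2")
)

# Charged-group atoms used for salt-bridge typing.
.SALT_DONOR_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                          HIS = c("ND1", "NE2"))
.SALT_ACCEPTOR_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Aromatic ring definitions for pi-pi detection.
.AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

.STANDARD_AA <- names(.SIDECHAIN_BONDS)

is_standard_aa <- function(res_name) toupper(res_name) %in% .STANDARD_AA

# Hybridization of a named heavy atom within a standard residue;
# unknown atoms default to sp3.
atom_hybridization <- function(res_name, atom_name) {
  res_name <- toupper(res_name)
  if (atom_name %in% c("N", "C", "O", "OXT")) return("sp2")
  d <- .SIDECHAIN_DONORS[[res_name]]
  if (!is.null(d) && atom_name %in% names(d)) return(unname(d[atom_name]))
  a <- .SIDECHAIN_ACCEPTORS[[res_name]]
  if (!is.null(a) && atom_name %in% names(a)) return(unname(a[atom_name]))
  "sp3"
}
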