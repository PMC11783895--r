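# Chemical templates for the 20 standard amino acids in their neutral free
# form (NH2 amine, COOH acid, neutral side chains, His in the Nd-protonated
# tautomer, Cys with S-H), plus dipeptide templates formed by peptide-bond
# condensation. Each template carries an ordered atom list, the covalent bond
# graph, and per-atom internal coordinates (Z-matrix rows) sufficient to
# rebuild Cartesian coordinates; heavy atoms precede hydrogens so that missing
# hydrogens/termini can be rebuilt from heavy-atom anchors.
#
# Ideal bond lengths and angles follow standard amino-acid geometry tables
# (Engh & Huber style values, rounded); they are implementation constants.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

# Neutral free amino-acid molecular formulas (independent element-count check).
.AA_FORMULA <- list(
  ALA = c(C = 3, H = 7, N = 1, O = 2),
  ARG = c(C = 6, H = 14, N = 4, O = 2),
  ASN = c(C = 4, H = 8, N = 2, O = 3),
  ASP = c(C = 4, H = 7, N = 1, O = 4),
  CYS = c(C = 3, H = 7, N = 1, O = 2, S = 1),
  GLN = c(C = 5, H = 10, N = 2, O = 3),
  GLU = c(C = 5, H = 9, N = 1, O = 4),
  GLY = c(C = 2, H = 5, N = 1, O = 2),
  HIS = c(C = 6, H = 9, N = 3, O = 2),
  ILE = c(C = 6, H = 13, N = 1, O = 2),
  LEU = c(C = 6, H = 13, N = 1, O = 2),
  LYS = c(C = 6, H = 14, N = 2, O = 2),
  MET = c(C = 5, H = 11, N = 1, O = 2, S = 1),
  PHE = c(C = 9, H = 11, N = 1, O = 2),
  PRO = c(C = 5, H = 9, N = 1, O = 2),
  SER = c(C = 3, H = 7, N = 1, O = 3),
  THR = c(C = 4, H = 9, N = 1, O = 3),
  TRP = c(C = 11, H = 12, N = 2, O = 2),
  TYR = c(C = 9, H = 11, N = 1, O = 3),
  VAL = c(C = 5, H = 11, N = 1, O = 2)
)

# Van der Waals radii (Angstrom) used by the surface builder.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# One Z-matrix row. p/a/d are atom names of the bonded parent, angle reference
# and torsion reference. dih is the torsion in degrees; if var is given the
# torsion is var + off with var a named rotatable (or build-time) dihedral.
.za <- function(name, elem, p, a, d, r, th, dih = 0, var = NA_character_,
                off = 0) {
  list(name = name, elem = elem, p = p, a = a, d = d,
       r = r, th = th, dih = dih, var = var, off = off)
}

# Shorthand for hydrogens.
.zh <- function(name, p, a, d, dih, r = 1.09, th = 109.5, var = NA, off = 0) {
  .za(name, "H", p, a, d, r, th, dih, var, off)
}

# Side-chain definitions. Each entry: rows (heavy atoms then hydrogens kept
# separate), ring-closure bonds, chi torsion names in order, and for each chi
# the defining 4-atom tuple. Backbone/alpha atoms are added by the assembler.
.sidechain_def <- function(code) {
  H2 <- function(pre, p, a, d) list(  # methylene pair
    .zh(paste0(pre, "2"), p, a, d, 120),
    .zh(paste0(pre, "3"), p, a, d, -120))
  H3 <- function(pre, p, a, d) list(  # methyl triple
    .zh(paste0(pre, "1"), p, a, d, 60),
    .zh(paste0(pre, "2"), p, a, d, 180),
    .zh(paste0(pre, "3"), p, a, d, -60))
  switch(code,
    GLY = list(heavy = list(), hyd = list(), closures = list(), chis = list()),
    ALA = list(
      heavy = list(),
      hyd = H3("HB", "CB", "CA", "N"),
      closures = list(), chis = list()),
    SER = list(
      heavy = list(.za("OG", "O", "CB", "CA", "N", 1.417, 110.8, var = "chi1")),
      hyd = c(H2("HB", "CB", "CA", "OG"),
              list(.zh("HG", "OG", "CB", "CA", 180, r = 0.96, th = 108.5))),
      closures = list(), chis = list(chi1 = c("N", "CA", "CB", "OG"))),
    CYS = list(
      heavy = list(.za("SG", "S", "CB", "CA", "N", 1.808, 113.8, var = "chi1")),
      hyd = c(H2("HB", "CB", "CA", "SG"),
              list(.zh("HG", "SG", "CB", "CA", 180, r = 1.34, th = 96.0))),
      closures = list(), chis = list(chi1 = c("N", "CA", "CB", "SG"))),
    THR = list(
      heavy = list(
        .za("OG1", "O", "CB", "CA", "N", 1.433, 109.6, var = "chi1"),
        .za("CG2", "C", "CB", "CA", "OG1", 1.521, 110.5, -121.5)),
      hyd = c(list(.zh("HB", "CB", "CA", "OG1", 121.5),
                   .zh("HG1", "OG1", "CB", "CA", 180, r = 0.96, th = 108.5)),
              H3("HG2", "CG2", "CB", "CA")),
      closures = list(), chis = list(chi1 = c("N", "CA", "CB", "OG1"))),
    VAL = list(
      heavy = list(
        .za("CG1", "C", "CB", "CA", "N", 1.521, 110.5, var = "chi1"),
        .za("CG2", "C", "CB", "CA", "CG1", 1.521, 110.5, 122.5)),
      hyd = c(list(.zh("HB", "CB", "CA", "CG1", -118.5)),
              H3("HG1", "CG1", "CB", "CA"), H3("HG2", "CG2", "CB", "CA")),
      closures = list(), chis = list(chi1 = c("N", "CA", "CB", "CG1"))),
    LEU = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.530, 116.3, var = "chi1"),
        .za("CD1", "C", "CG", "CB", "CA", 1.521, 110.7, var = "chi2"),
        .za("CD2", "C", "CG", "CB", "CD1", 1.521, 110.7, -122.5)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HG", "CG", "CB", "CD1", 118.5)),
              H3("HD1", "CD1", "CG", "CB"), H3("HD2", "CD2", "CG", "CB")),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD1"))),
    ILE = list(
      heavy = list(
        .za("CG1", "C", "CB", "CA", "N", 1.530, 110.4, var = "chi1"),
        .za("CG2", "C", "CB", "CA", "CG1", 1.521, 110.5, -122.5),
        .za("CD1", "C", "CG1", "CB", "CA", 1.513, 113.8, var = "chi2")),
      hyd = c(list(.zh("HB", "CB", "CA", "CG1", 118.5)),
              H2("HG1", "CG1", "CB", "CD1"), H3("HG2", "CG2", "CB", "CA"),
              H3("HD1", "CD1", "CG1", "CB")),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG1"),
                  chi2 = c("CA", "CB", "CG1", "CD1"))),
    MET = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.520, 114.1, var = "chi1"),
        .za("SD", "S", "CG", "CB", "CA", 1.803, 112.7, var = "chi2"),
        .za("CE", "C", "SD", "CG", "CB", 1.791, 100.9, var = "chi3")),
      hyd = c(H2("HB", "CB", "CA", "CG"), H2("HG", "CG", "CB", "SD"),
              H3("HE", "CE", "SD", "CG")),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "SD"),
                  chi3 = c("CB", "CG", "SD", "CE"))),
    PRO = list(
      # ring torsions fixed (Cg-endo-like pucker); values chosen so the
      # CD-N closure bond comes out near 1.47 A
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.492, 104.5, var = "chi1_fixed"),
        .za("CD", "C", "CG", "CB", "CA", 1.503, 106.1, var = "chi2_fixed")),
      hyd = c(H2("HB", "CB", "CA", "CG"), H2("HG", "CG", "CB", "CD"),
              H2("HD", "CD", "CG", "CB")),
      closures = list(c("CD", "N")),
      chis = list()),
    PHE = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.502, 113.8, var = "chi1"),
        .za("CD1", "C", "CG", "CB", "CA", 1.384, 120.8, var = "chi2"),
        .za("CD2", "C", "CG", "CD1", "CB", 1.384, 118.3, 180),
        .za("CE1", "C", "CD1", "CG", "CD2", 1.382, 120.8, 0),
        .za("CE2", "C", "CD2", "CG", "CD1", 1.382, 120.8, 0),
        .za("CZ", "C", "CE1", "CD1", "CG", 1.382, 120.0, 0)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HD1", "CD1", "CG", "CD2", 180, th = 119.6),
                   .zh("HD2", "CD2", "CG", "CD1", 180, th = 119.6),
                   .zh("HE1", "CE1", "CD1", "CG", 180, th = 119.6),
                   .zh("HE2", "CE2", "CD2", "CG", 180, th = 119.6),
                   .zh("HZ", "CZ", "CE1", "CD1", 180, th = 120.0))),
      closures = list(c("CZ", "CE2")),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD1"))),
    TYR = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.512, 113.9, var = "chi1"),
        .za("CD1", "C", "CG", "CB", "CA", 1.389, 120.8, var = "chi2"),
        .za("CD2", "C", "CG", "CD1", "CB", 1.389, 118.1, 180),
        .za("CE1", "C", "CD1", "CG", "CD2", 1.382, 121.2, 0),
        .za("CE2", "C", "CD2", "CG", "CD1", 1.382, 121.2, 0),
        .za("CZ", "C", "CE1", "CD1", "CG", 1.378, 119.6, 0),
        .za("OH", "O", "CZ", "CE1", "CD1", 1.376, 119.9, 180)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HD1", "CD1", "CG", "CD2", 180, th = 119.6),
                   .zh("HD2", "CD2", "CG", "CD1", 180, th = 119.6),
                   .zh("HE1", "CE1", "CD1", "CG", 180, th = 119.6),
                   .zh("HE2", "CE2", "CD2", "CG", 180, th = 119.6),
                   .zh("HH", "OH", "CZ", "CE1", 180, r = 0.96, th = 109.0))),
      closures = list(c("CZ", "CE2")),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD1"))),
    TRP = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.498, 113.6, var = "chi1"),
        .za("CD1", "C", "CG", "CB", "CA", 1.365, 126.9, var = "chi2"),
        .za("CD2", "C", "CG", "CD1", "CB", 1.433, 106.3, 180),
        .za("NE1", "N", "CD1", "CG", "CD2", 1.374, 110.2, 0),
        .za("CE2", "C", "NE1", "CD1", "CG", 1.370, 108.9, 0),
        .za("CE3", "C", "CD2", "CG", "CD1", 1.398, 133.9, 180),
        .za("CZ2", "C", "CE2", "NE1", "CD1", 1.394, 130.1, 180),
        .za("CZ3", "C", "CE3", "CD2", "CE2", 1.382, 118.8, 0),
        .za("CH2", "C", "CZ3", "CE3", "CD2", 1.368, 121.2, 0)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HD1", "CD1", "CG", "CD2", 180, th = 125.0),
                   .zh("HE1", "NE1", "CD1", "CG", 180, r = 1.01, th = 125.5),
                   .zh("HE3", "CE3", "CD2", "CE2", 180, th = 120.5),
                   .zh("HZ2", "CZ2", "CE2", "CD2", 180, th = 121.0),
                   .zh("HZ3", "CZ3", "CE3", "CD2", 180, th = 120.0),
                   .zh("HH2", "CH2", "CZ3", "CE3", 180, th = 119.5))),
      closures = list(c("CE2", "CD2"), c("CH2", "CZ2")),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD1"))),
    ASP = list(
      # neutral side-chain acid: OD1 carbonyl, OD2-HD2 hydroxyl
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.516, 112.6, var = "chi1"),
        .za("OD1", "O", "CG", "CB", "CA", 1.214, 120.9, var = "chi2"),
        .za("OD2", "O", "CG", "CB", "OD1", 1.355, 112.4, 180)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HD2", "OD2", "CG", "OD1", 0, r = 0.97, th = 106.0))),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "OD1"))),
    GLU = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.520, 114.1, var = "chi1"),
        .za("CD", "C", "CG", "CB", "CA", 1.516, 112.6, var = "chi2"),
        .za("OE1", "O", "CD", "CG", "CB", 1.214, 120.9, var = "chi3"),
        .za("OE2", "O", "CD", "CG", "OE1", 1.355, 112.4, 180)),
      hyd = c(H2("HB", "CB", "CA", "CG"), H2("HG", "CG", "CB", "CD"),
              list(.zh("HE2", "OE2", "CD", "OE1", 0, r = 0.97, th = 106.0))),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD"),
                  chi3 = c("CB", "CG", "CD", "OE1"))),
    ASN = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.516, 112.6, var = "chi1"),
        .za("OD1", "O", "CG", "CB", "CA", 1.231, 120.8, var = "chi2"),
        .za("ND2", "N", "CG", "CB", "OD1", 1.328, 116.4, 180)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HD21", "ND2", "CG", "OD1", 180, r = 1.01, th = 119.5),
                   .zh("HD22", "ND2", "CG", "OD1", 0, r = 1.01, th = 119.5))),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "OD1"))),
    GLN = list(
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.520, 114.1, var = "chi1"),
        .za("CD", "C", "CG", "CB", "CA", 1.516, 112.6, var = "chi2"),
        .za("OE1", "O", "CD", "CG", "CB", 1.231, 120.8, var = "chi3"),
        .za("NE2", "N", "CD", "CG", "OE1", 1.328, 116.4, 180)),
      hyd = c(H2("HB", "CB", "CA", "CG"), H2("HG", "CG", "CB", "CD"),
              list(.zh("HE21", "NE2", "CD", "OE1", 180, r = 1.01, th = 119.5),
                   .zh("HE22", "NE2", "CD", "OE1", 0, r = 1.01, th = 119.5))),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD"),
                  chi3 = c("CB", "CG", "CD", "OE1"))),
    LYS = list(
      # neutral amine NZ with two hydrogens
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.520, 114.1, var = "chi1"),
        .za("CD", "C", "CG", "CB", "CA", 1.520, 111.3, var = "chi2"),
        .za("CE", "C", "CD", "CG", "CB", 1.520, 111.3, var = "chi3"),
        .za("NZ", "N", "CE", "CD", "CG", 1.470, 110.5, var = "chi4")),
      hyd = c(H2("HB", "CB", "CA", "CG"), H2("HG", "CG", "CB", "CD"),
              H2("HD", "CD", "CG", "CE"), H2("HE", "CE", "CD", "NZ"),
              list(.zh("HZ1", "NZ", "CE", "CD", 60, r = 1.01, th = 109.5),
                   .zh("HZ2", "NZ", "CE", "CD", 180, r = 1.01, th = 109.5))),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD"),
                  chi3 = c("CB", "CG", "CD", "CE"),
                  chi4 = c("CG", "CD", "CE", "NZ"))),
    ARG = list(
      # neutral guanidine: NE-H, CZ=NH1 (one H), NH2 amine (two H)
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.520, 114.1, var = "chi1"),
        .za("CD", "C", "CG", "CB", "CA", 1.520, 111.3, var = "chi2"),
        .za("NE", "N", "CD", "CG", "CB", 1.461, 112.0, var = "chi3"),
        .za("CZ", "C", "NE", "CD", "CG", 1.330, 124.2, var = "chi4"),
        .za("NH1", "N", "CZ", "NE", "CD", 1.280, 121.5, 0),
        .za("NH2", "N", "CZ", "NE", "NH1", 1.375, 118.5, 180)),
      hyd = c(H2("HB", "CB", "CA", "CG"), H2("HG", "CG", "CB", "CD"),
              H2("HD", "CD", "CG", "NE"),
              list(.zh("HE", "NE", "CZ", "NH1", 180, r = 1.01, th = 118.5),
                   .zh("HH11", "NH1", "CZ", "NE", 180, r = 1.01, th = 111.0),
                   .zh("HH21", "NH2", "CZ", "NE", 0, r = 1.01, th = 119.5),
                   .zh("HH22", "NH2", "CZ", "NE", 180, r = 1.01, th = 119.5))),
      closures = list(),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "CD"),
                  chi3 = c("CB", "CG", "CD", "NE"),
                  chi4 = c("CG", "CD", "NE", "CZ"))),
    HIS = list(
      # neutral tautomer with the Nd (ND1) proton; NE2 bare
      heavy = list(
        .za("CG", "C", "CB", "CA", "N", 1.504, 113.8, var = "chi1"),
        .za("ND1", "N", "CG", "CB", "CA", 1.378, 122.7, var = "chi2"),
        .za("CD2", "C", "CG", "ND1", "CB", 1.356, 109.3, 180),
        .za("CE1", "C", "ND1", "CG", "CD2", 1.321, 109.0, 0),
        .za("NE2", "N", "CE1", "ND1", "CG", 1.314, 111.7, 0)),
      hyd = c(H2("HB", "CB", "CA", "CG"),
              list(.zh("HD1", "ND1", "CG", "CD2", 180, r = 1.01, th = 126.0),
                   .zh("HD2", "CD2", "CG", "ND1", 180, th = 128.5),
                   .zh("HE1", "CE1", "ND1", "CG", 180, th = 124.5))),
      closures = list(c("NE2", "CD2")),
      chis = list(chi1 = c("N", "CA", "CB", "CG"),
                  chi2 = c("CA", "CB", "CG", "ND1"))),
    stop("unknown residue code: ", code)
  )
}

# Fixed proline ring torsions (degrees) for the two Z-matrix variables above.
.PRO_RING <- c(chi1_fixed = 28.5, chi2_fixed = -38.2)

.norm_code <- function(code) {
  code <- toupper(trimws(code))
  if (!code %in% .AA3)
    stop("unknown residue code: ", code, call. = FALSE)
  code
}

# Assemble the full atom table (Z-matrix) for one residue in a given terminal
# context. ctx: "free" (both termini), "nterm" (free amine, carbonyl links on),
# "cterm" (peptide N, free acid). Returns rows with a residue slot index.
.residue_rows <- function(code, res = 1L) {
  sc <- .sidechain_def(code)
  is_gly <- code == "GLY"
  is_pro <- code == "PRO"
  heavy <- c(
    list(
      .za("N", "N", NA, NA, NA, NA, NA),
      .za("CA", "C", "N", NA, NA, 1.466, NA),
      .za("C", "C", "CA", "N", NA, 1.525, 111.2),
      # psi is the N-CA-C-O(XT)/N(next) rotation; O sits at psi + 180
      .za("O", "O", "C", "CA", "N", 1.231, 120.5, var = "psi", off = 180),
      .za("OXT", "O", "C", "CA", "O", 1.331, 117.0, 180)),
    if (!is_gly) list(.za("CB", "C", "CA", "N", "C", 1.530, 110.5, -122.5)),
    sc$heavy)
  hyd <- c(
    if (is_pro) list(.zh("H", "N", "CA", "C", -60.0, r = 1.01, th = 109.0))
    else list(.zh("H", "N", "CA", "C", 60, r = 1.01, th = 109.5),
              .zh("H2", "N", "CA", "C", -60, r = 1.01, th = 109.5)),
    if (is_gly) list(.zh("HA2", "CA", "N", "C", -122.5),
                     .zh("HA3", "CA", "N", "C", 119.0))
    else list(.zh("HA", "CA", "N", "C", 119.0)),
    sc$hyd,
    list(.zh("HXT", "OXT", "C", "O", 0, r = 0.97, th = 107.0)))
  rows <- c(heavy, hyd)
  for (i in seq_along(rows)) rows[[i]]$res <- res
  chis <- c(list(psi = c("N", "CA", "C", "OXT")), sc$chis)
  list(rows = rows, closures = sc$closures, chis = chis)
}

.rows_to_table <- function(rows) {
  data.frame(
    name = vapply(rows, `[[`, "", "name"),
    elem = vapply(rows, `[[`, "", "elem"),
    res = vapply(rows, function(r) as.integer(r$res), 0L),
    p = vapply(rows, function(r) as.character(r$p %||% NA), ""),
    a = vapply(rows, function(r) as.character(r$a %||% NA), ""),
    d = vapply(rows, function(r) as.character(r$d %||% NA), ""),
    r = vapply(rows, function(r) as.numeric(r$r %||% NA), 0),
    th = vapply(rows, function(r) as.numeric(r$th %||% NA), 0),
    dih = vapply(rows, function(r) as.numeric(r$dih %||% NA), 0),
    var = vapply(rows, function(r) as.character(r$var %||% NA), ""),
    off = vapply(rows, function(r) as.numeric(r$off %||% 0), 0),
    stringsAsFactors = FALSE)
}

# Atom key used to resolve references within multi-residue templates.
.atom_key <- function(name, res) paste0(name, "@", res)

.template_cache <- new.env(parent = emptyenv())

#' Retrieve the chemical template of a standard amino acid
#'
#' Returns the neutral free amino-acid form: NH2 amine, COOH carboxylic acid,
#' neutral side chains (Asp/Glu protonated acids, Lys neutral amine, Arg
#' neutral guanidine), histidine in the Nd-protonated tautomer and cysteine
#' with an S-H hydrogen.
#'
#' @param code 3-letter residue code (case-insensitive), e.g. `"ALA"`.
#' @return An object of class `residue_template` with components `code`,
#'   `one_letter`, `atoms` (data frame: name, elem, res, heavy flag and
#'   Z-matrix internal coordinates), `bonds` (2-column index matrix),
#'   `rotatable_dihedrals` (named list of 4 x 2 name/residue tuples) and
#'   `n_atoms`.
#' @examples
#' tpl <- get_template("HIS")
#' tpl$n_atoms  # 20
#' @export
get_template <- function(code) {
  code <- .norm_code(code)
  key <- paste0("S:", code)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  rr <- .residue_rows(code, 1L)
  at <- .rows_to_table(rr$rows)
  tpl <- .finalize_template(code, at, rr$closures, rr$chis,
                            res_of_closures = 1L, n_residues = 1L)
  .template_cache[[key]] <- tpl
  tpl
}

.finalize_template <- function(code, at, closures, chis, res_of_closures,
                               n_residues) {
  at$heavy <- at$elem != "H"
  if (is.null(at$res_p)) at$res_p <- at$res
  if (is.null(at$res_a)) at$res_a <- at$res
  if (is.null(at$res_d)) at$res_d <- at$res
  key <- .atom_key(at$name, at$res)
  if (anyDuplicated(key)) stop("internal: duplicate atom keys in template")
  idx <- function(k) match(k, key)
  # resolve Z-matrix references to row indices (NA for the root atoms)
  ref_idx <- function(nm, rs) {
    out <- rep(NA_integer_, length(nm))
    ok <- !is.na(nm) & nm != "NA"
    out[ok] <- idx(.atom_key(nm[ok], rs[ok]))
    out
  }
  at$ip <- ref_idx(at$p, at$res_p)
  at$ia <- ref_idx(at$a, at$res_a)
  at$id <- ref_idx(at$d, at$res_d)
  if (any(!is.na(at$ip) & at$ip >= seq_len(nrow(at))) ||
      any(!is.na(at$ia) & at$ia >= seq_len(nrow(at))) ||
      any(!is.na(at$id) & at$id >= seq_len(nrow(at))))
    stop("internal: forward Z-matrix reference in ", code)
  # bonds: parent edges + ring closures (closures carry their residue slot)
  bonds <- cbind(which(!is.na(at$ip)), at$ip[!is.na(at$ip)])
  if (length(closures)) {
    cl <- do.call(rbind, lapply(seq_along(closures), function(i) {
      rs <- res_of_closures[min(i, length(res_of_closures))]
      c(idx(.atom_key(closures[[i]][1], rs)), idx(.atom_key(closures[[i]][2], rs)))
    }))
    bonds <- rbind(bonds, cl)
  }
  if (anyNA(bonds)) stop("internal: unresolved bond reference in ", code)
  rot <- lapply(chis, function(tuple) {
    if (is.matrix(tuple)) tuple else cbind(tuple, rep(1L, 4))
  })
  structure(list(code = code,
                 one_letter = unname(.AA1[substr(code, 1, 3)] %||% NA),
                 atoms = at, bonds = bonds,
                 rotatable_dihedrals = rot,
                 n_atoms = nrow(at), n_residues = n_residues),
            class = "residue_template")
}

#' Number of atoms of a completed fragment class
#'
#' Hydrogens included; single residues count the neutral free amino-acid form,
#' 6-letter dipeptide codes count the free-dipeptide condensation product
#' (atom_count(a) + atom_count(b) - 3).
#'
#' @param code 3-letter residue code or 6-letter dipeptide code.
#' @return Integer atom count.
#' @examples
#' atom_count("MET")     # 20
#' atom_count("GLYGLY")  # 17
#' @export
atom_count <- function(code) {
  code <- toupper(trimws(code))
  if (nchar(code) == 6) {
    return(atom_count(substr(code, 1, 3)) + atom_count(substr(code, 4, 6)) - 3L)
  }
  get_template(code)$n_atoms
}

#' Dipeptide template by peptide-bond condensation
#'
#' Condenses two free amino-acid templates through a trans peptide bond:
#' residue 1 loses its OXT/HXT hydroxyl, residue 2 loses one amine hydrogen
#' (prolines lose their single one), for a net loss of one water equivalent.
#'
#' @param code1,code2 3-letter residue codes, N-terminal first.
#' @return A `residue_template` whose atoms carry residue slot 1 or 2; the
#'   label is the 6-letter concatenated code.
#' @examples
#' dipeptide_template("GLY", "GLY")$n_atoms  # 17
#' @export
dipeptide_template <- function(code1, code2) {
  code1 <- .norm_code(code1); code2 <- .norm_code(code2)
  key <- paste0("D:", code1, code2)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  r1 <- .residue_rows(code1, 1L)
  r2 <- .residue_rows(code2, 2L)
  drop1 <- c("OXT", "HXT")
  rows1 <- Filter(function(r) !r$name %in% drop1, r1$rows)
  # residue 1 heavy/hyd order is preserved; its O now takes the psi1 torsion;
  # side-chain torsion variables get per-residue suffixes
  for (i in seq_along(rows1)) {
    v <- rows1[[i]]$var
    if (rows1[[i]]$name == "O") { rows1[[i]]$var <- "psi1"; rows1[[i]]$off <- 180 }
    else if (!is.na(v) && grepl("^chi", v) && !grepl("_fixed$", v))
      rows1[[i]]$var <- paste0(v, "_1")
  }
  # peptide linkage atoms
  link <- list(
    .za("N", "N", "C", "CA", "O", 1.329, 116.2, 180),            # trans to O
    .za("CA", "C", "N", "C", "CA", 1.458, 121.7, 180))           # omega = 180
  link[[1]]$res <- 2L; link[[1]]$res_ref <- 1L                   # refs in res 1
  link[[2]]$res <- 2L; link[[2]]$res_ref <- NA                   # mixed refs
  drop2 <- if (code2 == "PRO") c("N", "CA", "H") else c("N", "CA", "H2")
  rows2 <- Filter(function(r) !r$name %in% drop2, r2$rows)
  for (i in seq_along(rows2)) {
    rw <- rows2[[i]]
    if (rw$name == "C") { rows2[[i]]$var <- "phi2"; rows2[[i]]$dih <- NA }
    if (identical(rw$var, "psi")) rows2[[i]]$var <- "psi2"
    else if (!is.na(rw$var) && grepl("^chi", rw$var) && !grepl("_fixed$", rw$var))
      rows2[[i]]$var <- paste0(rw$var, "_2")
    if (rw$name == "H" && code2 != "PRO") {
      # amide hydrogen, roughly cis to CA1 across the peptide bond
      rows2[[i]] <- .zh("H", "N", "C", "CA", 0, r = 1.01, th = 119.0)
      rows2[[i]]$res <- 2L; rows2[[i]]$res_ref <- 1L
    }
  }
  rows <- c(rows1, link, rows2)
  at <- .rows_to_table(rows)
  # resolve cross-residue references: by default refs live in the atom's own
  # residue; the linkage rows reference residue 1 explicitly
  at$res_ref <- at$res
  at$res_ref[at$res == 2L & at$name == "N"] <- 1L
  # CA of residue 2: parent N (res 2), angle ref C (res 1), torsion ref CA (res 1)
  # C of residue 2: parent CA (res 2), angle ref N (res 2), torsion ref C (res 1)
  # handled by per-column reference residues:
  at$res_p <- at$res_ref; at$res_a <- at$res_ref; at$res_d <- at$res_ref
  i_ca2 <- which(at$res == 2L & at$name == "CA")
  at$res_p[i_ca2] <- 2L; at$res_a[i_ca2] <- 1L; at$res_d[i_ca2] <- 1L
  i_c2 <- which(at$res == 2L & at$name == "C")
  at$d[i_c2] <- "C"  # phi2 torsion: C2-CA2-N2-C1
  at$res_p[i_c2] <- 2L; at$res_a[i_c2] <- 2L; at$res_d[i_c2] <- 1L
  i_h2 <- which(at$res == 2L & at$name == "H")
  if (length(i_h2) && code2 != "PRO") {
    at$res_p[i_h2] <- 2L; at$res_a[i_h2] <- 1L; at$res_d[i_h2] <- 1L
  }
  i_n2 <- which(at$res == 2L & at$name == "N")
  at$res_p[i_n2] <- 1L; at$res_a[i_n2] <- 1L; at$res_d[i_n2] <- 1L
  chis1 <- r1$chis[names(r1$chis) != "psi"]        # res-1 psi becomes psi1
  chis2 <- r2$chis[names(r2$chis) != "psi"]
  psi2_tu <- cbind(c("N", "CA", "C", "OXT"), rep(2L, 4))
  chis <- c(
    list(psi1 = cbind(c("N", "CA", "C", "N"), c(1L, 1L, 1L, 2L)),
         phi2 = cbind(c("C", "N", "CA", "C"), c(1L, 2L, 2L, 2L)),
         psi2 = psi2_tu),
    lapply(chis1, function(tu) cbind(tu, rep(1L, 4))),
    lapply(chis2, function(tu) cbind(tu, rep(2L, 4))))
  names(chis) <- c("psi1", "phi2", "psi2",
                   if (length(chis1)) paste0(names(chis1), "_1"),
                   if (length(chis2)) paste0(names(chis2), "_2"))
  closures <- c(r1$closures, r2$closures)
  res_cl <- c(rep(1L, length(r1$closures)), rep(2L, length(r2$closures)))
  tpl <- .finalize_template(paste0(code1, code2), at, closures, chis,
                            res_of_closures = res_cl, n_residues = 2L)
  tpl$one_letter <- paste0(.AA1[code1], .AA1[code2])
  .template_cache[[key]] <- tpl
  tpl
}

#' @export
print.residue_template <- function(x, ...) {
  cat(sprintf("<residue_template %s: %d atoms (%d heavy), %d bonds, %d rotatable dihedrals>\n",
              x$code, x$n_atoms, sum(x$atoms$heavy), nrow(x$bonds),
              length(x$rotatable_dihedrals)))
  invisible(x)
}

#' List the 20 standard residue codes
#' @return Character vector of 3-letter codes.
#' @export
standard_residues <- function() .AA3

#' Molecular formula of a residue template (element counts)
#' @param code 3-letter residue code.
#' @return Named integer vector of element counts.
#' @export
residue_formula <- function(code) .AA_FORMULA[[.norm_code(code)]]

#' Flat per-atom table of a template (plain-text friendly)
#'
#' One row per atom with element, heavy flag, residue slot and the internal
#' coordinates (parent/angle/torsion references, bond length, bond angle,
#' torsion or torsion variable). `write.table()` on the result gives a
#' self-contained plain-text record of the template; bonds are available as
#' a second data frame.
#'
#' @param code 3-letter residue code or 6-letter dipeptide code.
#' @return List with `atoms` (data frame) and `bonds` (data frame of 1-based
#'   atom index pairs).
#' @export
template_table <- function(code) {
  tpl <- if (nchar(toupper(trimws(code))) == 6)
    dipeptide_template(substr(code, 1, 3), substr(code, 4, 6))
  else get_template(code)
  at <- tpl$atoms[, c("name", "elem", "res", "heavy", "p", "a", "d",
                      "r", "th", "dih", "var", "off")]
  rownames(at) <- NULL
  list(atoms = at,
       bonds = data.frame(i = tpl$bonds[, 1], j = tpl$bonds[, 2]))
}
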