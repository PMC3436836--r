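#' @useDynLib mtdminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd dist
#' @importFrom utils read.table write.table head tail
NULL

# --- built-in chemistry tables ---------------------------------------------

#' Standard amino acids, three- and one-letter codes
#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

# Kyte-Doolittle hydropathy scale (Ile +4.5 ... Arg -4.5)
KD_SCALE <- c(
  ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
  MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
  TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
  GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5
)

# van der Waals radii by element (Angstrom); fallback 1.7
ELEMENT_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8,
                   P = 1.8, SE = 1.9)

# Side-chain atoms capable of hydrogen bonding (donor or acceptor), per
# residue; backbone N and O qualify for every residue.
HBOND_SIDECHAIN <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"), TRP = "NE1", CYS = "SG", MET = "SD"
)

# Coarse integer side-chain charges (pH 7), distributed over the terminal
# atoms named here when present. Structures lacking them (e.g. toy chains
# with a single pseudo side-chain atom) fall back to CB, then CA.
CHARGE_TABLE <- list(
  ARG = list(q = +1, atoms = c("NH1", "NH2")),
  LYS = list(q = +1, atoms = "NZ"),
  ASP = list(q = -1, atoms = c("OD1", "OD2")),
  GLU = list(q = -1, atoms = c("OE1", "OE2"))
)

aa_three_to_one <- function(res) {
  out <- unname(AA1[res])
  out[is.na(out)] <- "X"
  out
}
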