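# Residue-level chemistry tables shared by the interface and specificity
# modules: van der Waals radii, amino-acid codes, hydrogen-bond donor/acceptor
# templates and side-chain physicochemical properties. All geometry operates on
# heavy atoms only (crystal structures at ~2.4 A carry no reliable hydrogens).

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE)[1:20], AA_THREE_TO_ONE[1:20])

#' Van der Waals radii used for surface and clash geometry
#'
#' Chothia-style heavy-atom radii: C 1.70, N 1.55, O 1.52, S 1.80 angstrom
#' (P and Se included for completeness). Every geometric computation in the
#' package (solvent-accessible surface area, buried surface area, steric
#' clashes) looks radii up here; pass a modified copy to override.
#'
#' @return Named numeric vector of radii in angstrom, one entry per element.
#' @export
#' @examples
#' vdw_radii()["C"]
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90, H = 1.00)
}

lookup_radii <- function(element, radii = vdw_radii()) {
  r <- unname(radii[toupper(element)])
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    abort(paste0("No van der Waals radius for element(s): ",
                 paste(bad, collapse = ", ")))
  }
  r
}

# Hydrogen-bond donor heavy atoms per residue (N/O/S carrying at least one
# polar hydrogen in the standard protonation state). Backbone amide N is a
# donor for every residue except proline.
HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)

# Acceptor heavy atoms per residue; backbone carbonyl O (and terminal OXT)
# accepts for every residue.
HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

# Covalent antecedent of each polar atom, used for the heavy-atom angle proxy
# at the acceptor (donor -- acceptor -- antecedent).
HB_ANTECEDENT <- c(
  N = "CA", O = "C", OXT = "C",
  OD1 = "CG", OD2 = "CG", ND2 = "CG",
  OE1 = "CD", OE2 = "CD", NE2 = "CD",
  OG = "CB", OG1 = "CB", SG = "CB",
  OH = "CZ", NZ = "CE", NE = "CD", NH1 = "CZ", NH2 = "CZ",
  ND1 = "CG", NE1 = "CD1", SD = "CG"
)

# Side-chain groups carrying formal charge at physiological pH, for salt-bridge
# classification.
SALT_POSITIVE <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))
SALT_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Per-amino-acid physicochemical summaries driving the substitution-effect
# rules: formal side-chain charge, hydrophobic class, number of side-chain
# heavy atoms, and whether the side chain can donate/accept hydrogen bonds.
AA_PROPERTIES <- tibble::tibble(
  aa = c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V"),
  charge = c(0, 1, 0, -1, 0, 0, -1, 0, 1, 0,
             0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
  hydrophobic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                  FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                  FALSE, TRUE, TRUE, TRUE),
  side_chain_atoms = c(1, 7, 4, 4, 2, 5, 5, 0, 6, 4,
                       4, 5, 4, 7, 3, 2, 3, 10, 8, 3),
  polar_side_chain = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                       TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                       TRUE, TRUE, TRUE, FALSE)
)

aa_property <- function(aa, what) {
  idx <- match(aa, AA_PROPERTIES$aa)
  if (anyNA(idx)) {
    abort(paste0("Non-standard amino acid code: ",
                 paste(unique(aa[is.na(idx)]), collapse = ", ")))
  }
  AA_PROPERTIES[[what]][idx]
}
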