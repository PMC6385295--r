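# Fixtures and independent oracles built in code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand-written three-residue PDB fixture (chain A: Ala10, Gly11, Asp12).
mini_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A  10       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A  10       2.400   2.100   3.200  1.00 10.00           C",
    "ATOM      3  C   ALA A  10       3.100   3.400   3.100  1.00 10.00           C",
    "ATOM      4  O   ALA A  10       2.600   4.500   3.300  1.00 10.00           O",
    "ATOM      5  CB  ALA A  10       3.000   1.000   2.400  1.00 10.00           C",
    "ATOM      6  N   GLY A  11       4.400   3.300   2.800  1.00 10.00           N",
    "ATOM      7  CA  GLY A  11       5.300   4.400   2.600  1.00 10.00           C",
    "ATOM      8  C   GLY A  11       6.700   3.900   2.300  1.00 10.00           C",
    "ATOM      9  O   GLY A  11       7.000   2.700   2.400  1.00 10.00           O",
    "ATOM     10  N   ASP A  12       7.600   4.800   1.900  1.00 10.00           N",
    "ATOM     11  CA  ASP A  12       9.000   4.500   1.600  1.00 10.00           C",
    "ATOM     12  C   ASP A  12       9.900   5.700   1.400  1.00 10.00           C",
    "ATOM     13  O   ASP A  12       9.500   6.900   1.500  1.00 10.00           O",
    "ATOM     14  CB  ASP A  12       9.600   3.500   2.600  1.00 10.00           C",
    "ATOM     15  CG  ASP A  12       9.100   2.100   2.500  1.00 10.00           C",
    "ATOM     16  OD1 ASP A  12       8.000   1.900   1.900  1.00 10.00           O",
    "ATOM     17  OD2 ASP A  12       9.800   1.200   3.000  1.00 10.00           O",
    "END"
  )
}

write_mini_pdb <- function(path = tempfile(fileext = ".pdb"),
                           lines = mini_pdb_lines()) {
  writeLines(lines, path)
  path
}

# Minimal structure of free-standing atoms (one single-atom residue each),
# for geometric tests where only elements and coordinates matter.
atoms_structure <- function(xyz, element = "C", chain = "A",
                            aa = "G", atom = NULL) {
  n <- nrow(xyz)
  element <- rep_len(element, n)
  chain <- rep_len(chain, n)
  atom <- atom %||% ifelse(element == "C", "CA",
                           ifelse(element == "N", "N",
                                  ifelse(element == "O", "O", "SG")))
  as_structure(tibble::tibble(
    chain = chain, resno = ave(seq_len(n), chain, FUN = seq_along),
    aa = rep_len(aa, n), atom = rep_len(atom, n), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

# CA-only chain with arbitrary numbering, non-collinear by construction.
ca_chain <- function(positions, chain = "A", seed = 42) {
  set.seed(seed)
  n <- length(positions)
  t <- seq_len(n)
  as_structure(tibble::tibble(
    chain = chain, resno = positions, aa = "A", atom = "CA", element = "C",
    x = 3.8 * t, y = 2 * sin(t), z = 1.5 * cos(1.3 * t)
  ))
}

# Closed-form accessible area of sphere 1 (radius r1) partially occluded by
# sphere 2 (radius r2) at center distance d: the buried spherical cap has
# height r1 - x1 with x1 the signed distance to the intersection plane.
cap_accessible_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  2 * pi * r1 * (r1 + x1)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_move <- function(st, rotation, translation) {
  tr <- structure(list(rotation = rotation, translation = translation,
                       rmsd = 0, n_fit_atoms = 0), class = "rigid_transform")
  apply_transform(st, tr)
}

# One-time fetch of a wwPDB entry; cached in the session temp directory.
fetch_pdb_entry <- function(accession, timeout = 20) {
  dest <- file.path(tempdir(), paste0(tolower(accession), ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/",
                  toupper(accession), ".pdb")
    withr::local_options(timeout = timeout)
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}
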