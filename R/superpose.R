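# Rigid-body superposition (Kabsch) and steric-clash assessment, used to model
# co-engagement of immune receptors on an antibody-bound HLA molecule.

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `P` onto
#' `Q` via singular value decomposition of the cross-covariance, with the
#' reflection corrected to guarantee a rotation (determinant +1).
#'
#' @param P,Q Numeric n x 3 matrices of paired coordinates (n >= 3,
#'   non-degenerate).
#' @return List of class `rigid_transform`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd`, `n_fit_atoms`. The transform maps `P` onto `Q` as
#'   `P %*% t(rotation) + translation`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) != nrow(Q) || nrow(P) < 3) {
    abort("Need the same number (>= 3) of paired points.")
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) {
    abort("Degenerate (collinear or coincident) points: rotation undetermined.")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  moved <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(rowSums((moved - Q)^2))),
                 n_fit_atoms = nrow(P)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd ", signif(x$rmsd, 4), " A over ",
      x$n_fit_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x An n x 3 coordinate matrix or an `allo_structure`.
#' @param transform A `rigid_transform` from [kabsch()].
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "allo_structure") || is.data.frame(x)) {
    xyz <- atom_xyz(x) %*% t(transform$rotation) +
      matrix(transform$translation, nrow(x), 3, byrow = TRUE)
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    x
  } else {
    x %*% t(transform$rotation) +
      matrix(transform$translation, nrow(x), 3, byrow = TRUE)
  }
}

#' Superpose a mobile complex onto a target via a shared chain
#'
#' Fits the C-alpha atoms of the chain carrying `shared_role` in `mobile`
#' onto the corresponding atoms in `target`, restricted to `fit_positions`
#' present in both, and applies the resulting rigid transform to the whole
#' mobile structure. The default fit range covers the alpha-1/alpha-2
#' platform of a class-I HLA alpha chain.
#'
#' @param target,mobile `allo_structure`s, both containing `shared_role`.
#' @param shared_role Chain role common to both structures (default
#'   `"hla_alpha"`).
#' @param fit_positions Residue numbers used for the fit (default `1:180`).
#' @return List with `structure` (transformed mobile) and `transform`.
#' @export
superpose_structures <- function(target, mobile, shared_role = "hla_alpha",
                                 fit_positions = 1:180) {
  ca <- function(s) {
    side_atoms(s, shared_role) |>
      filter(.data$atom == "CA", .data$resno %in% fit_positions) |>
      distinct(.data$resno, .keep_all = TRUE)
  }
  ca_t <- ca(target)
  ca_m <- ca(mobile)
  shared <- intersect(ca_t$resno, ca_m$resno)
  if (length(shared) < 3) {
    abort("Fewer than 3 shared fit positions on the shared chain.")
  }
  tr <- kabsch(atom_xyz(ca_m[match(shared, ca_m$resno), ]),
               atom_xyz(ca_t[match(shared, ca_t$resno), ]))
  list(structure = apply_transform(mobile, tr), transform = tr)
}

#' Steric clashes between two chain sets in a common frame
#'
#' Reports heavy-atom pairs whose van der Waals overlap,
#' `r_a + r_b - distance`, exceeds `overlap_tolerance` -- the conventional
#' operationalization of steric hindrance.
#'
#' @param structure An `allo_structure` (or row-bound pair of structures)
#'   whose coordinates share one frame.
#' @param fixed,moved Chain sets (roles and/or chain ids) to compare.
#' @param overlap_tolerance Allowed overlap in angstrom (default 0.4).
#' @param radii Van der Waals radii table.
#' @return List of class `clash_report`: `clash_pairs` (tibble with atom
#'   identities, `dist`, `overlap`), `n_clashes`, `min_distance` (smallest
#'   cross-set atom distance, `Inf` if the sets are far apart).
#' @export
detect_clashes <- function(structure, fixed, moved, overlap_tolerance = 0.4,
                           radii = vdw_radii()) {
  at_f <- side_atoms(structure, fixed)
  at_m <- side_atoms(structure, moved)
  r_f <- lookup_radii(at_f$element, radii)
  r_m <- lookup_radii(at_m$element, radii)
  cutoff <- max(r_f) + max(r_m)
  n_f <- nrow(at_f)
  nb <- neighbor_pairs(rbind(atom_xyz(at_f), atom_xyz(at_m)), cutoff)
  nb <- nb[nb$i <= n_f & nb$j > n_f, , drop = FALSE]
  f_i <- nb$i
  m_i <- nb$j - n_f
  overlap <- r_f[f_i] + r_m[m_i] - nb$dist
  keep <- overlap > overlap_tolerance
  pairs <- tibble(
    chain_a = at_f$chain[f_i], resno_a = at_f$resno[f_i],
    atom_a = at_f$atom[f_i],
    chain_b = at_m$chain[m_i], resno_b = at_m$resno[m_i],
    atom_b = at_m$atom[m_i],
    dist = nb$dist, overlap = overlap
  )[keep, ] |> arrange(dplyr::desc(.data$overlap))
  structure(list(
    clash_pairs = pairs,
    n_clashes = sum(keep),
    min_distance = if (nrow(nb) > 0) min(nb$dist) else Inf,
    overlap_tolerance = overlap_tolerance
  ), class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat("<clash_report> ", x$n_clashes, " clash(es) at overlap tolerance ",
      x$overlap_tolerance, " A; closest approach ",
      signif(x$min_distance, 4), " A\n", sep = "")
  invisible(x)
}
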