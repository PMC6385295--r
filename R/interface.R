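# Antibody-antigen interface quantification: buried surface area and its
# chain-pair decomposition, residue contacts, hydrogen bonds, the epitope
# footprint with its discontinuous segments, and binding-induced backbone
# displacement.

#' Hydrogen-bond geometric criteria
#'
#' Heavy-atom criteria (no hydrogens are modeled): donor--acceptor distance
#' cutoff and a minimum donor--acceptor--antecedent angle proxy evaluated at
#' the acceptor.
#'
#' @param max_distance Donor-acceptor heavy-atom distance cutoff, angstrom;
#'   must lie in (2.2, 4.0]. Default 3.5.
#' @param min_angle Minimum angle (degrees) between the acceptor-to-donor and
#'   acceptor-to-antecedent directions. Default 90.
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 90) {
  stopifnot(max_distance > 2.2, max_distance <= 4.0,
            min_angle >= 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

side_atoms <- function(structure, side) {
  ch <- resolve_chains(structure, side)
  filter(polymer_heavy(structure), .data$chain %in% ch)
}

#' Buried surface area of one side of a complex
#'
#' Computes the solvent-accessible surface area change of `side_a` upon
#' complexation: SASA of `side_a` alone minus SASA of the `side_a` atoms
#' within the `side_a` + `side_b` complex.
#'
#' @param structure An `allo_structure`.
#' @param side_a,side_b Disjoint chain sets (roles and/or chain ids).
#' @param params [sasa_params()].
#' @return Buried area in angstrom squared (non-negative up to lattice
#'   resolution).
#' @export
buried_surface_area <- function(structure, side_a, side_b,
                                params = sasa_params()) {
  ch_a <- resolve_chains(structure, side_a)
  ch_b <- resolve_chains(structure, side_b)
  if (length(intersect(ch_a, ch_b)) > 0) abort("Sides must be disjoint.")
  at <- filter(polymer_heavy(structure), .data$chain %in% c(ch_a, ch_b))
  if (!any(at$chain %in% ch_a) || !any(at$chain %in% ch_b)) {
    abort("Empty side.")
  }
  rad <- lookup_radii(at$element, params$radii) + params$probe_radius
  # one canonical frame from the union, so the isolated and complexed
  # states share the identical point lattice and their difference is exact
  xyz <- canonical_coords(atom_xyz(at))
  pts <- sphere_points(params$n_sphere_points)
  in_a <- at$chain %in% ch_a
  frac_alone <- accessible_fraction(xyz[in_a, , drop = FALSE], rad[in_a], pts)
  frac_both <- accessible_fraction(xyz, rad, pts)
  area <- 4 * pi * rad[in_a]^2
  sum(area * frac_alone) - sum(area * frac_both[in_a])
}

#' Chain-pair decomposition of the antibody footprint
#'
#' Attributes every surface point of the antigen side that is buried on
#' complexation to the antibody chain occluding it (ties broken toward the
#' deeper overlap, then chain order), so the per-pair areas sum to the total
#' footprint exactly by construction -- the convention under which the
#' published per-chain interface areas are additive.
#'
#' @param structure An `allo_structure` with roles assigned.
#' @param antigen_side Roles/chains forming the antigen (HLA) side; the
#'   peptide is excluded by default because the footprint is reported on the
#'   alpha chain and beta-2-microglobulin.
#' @param antibody_side Roles/chains forming the antibody side.
#' @param params [sasa_params()].
#' @return Tibble with one row per (antigen chain, antibody chain) pair:
#'   `chain_a`, `role_a`, `chain_b`, `role_b`, `bsa`. The total footprint is
#'   attached as attribute `total_footprint` (equal to `sum(bsa)`).
#' @export
pairwise_bsa <- function(structure,
                         antigen_side = c("hla_alpha", "b2m"),
                         antibody_side = c("fab_heavy", "fab_light"),
                         params = sasa_params()) {
  ch_a <- resolve_chains(structure, antigen_side)
  ch_b <- resolve_chains(structure, antibody_side)
  if (length(intersect(ch_a, ch_b)) > 0) abort("Sides must be disjoint.")
  at_a <- filter(polymer_heavy(structure), .data$chain %in% ch_a)
  at_b <- filter(polymer_heavy(structure), .data$chain %in% ch_b)
  rad_a <- lookup_radii(at_a$element, params$radii) + params$probe_radius
  rad_b <- lookup_radii(at_b$element, params$radii) + params$probe_radius
  # joint canonical frame (as in buried_surface_area) so the attribution
  # totals coincide exactly with the one-sided buried area
  xyz_joint <- canonical_coords(rbind(atom_xyz(at_a), atom_xyz(at_b)))
  xyz_a <- xyz_joint[seq_len(nrow(at_a)), , drop = FALSE]
  xyz_b <- xyz_joint[-seq_len(nrow(at_a)), , drop = FALSE]
  pts <- sphere_points(params$n_sphere_points)
  n_a <- nrow(at_a)

  # neighbors among antigen atoms (self-occlusion) and across to antibody
  max_cut <- 2 * max(c(rad_a, rad_b))
  nb_aa <- neighbor_pairs(xyz_a, max_cut)
  nb_aa <- nb_aa[nb_aa$dist < rad_a[nb_aa$i] + rad_a[nb_aa$j], , drop = FALSE]
  xyz_all <- rbind(xyz_a, xyz_b)
  nb_all <- neighbor_pairs(xyz_all, max_cut)
  cross <- nb_all[nb_all$i <= n_a & nb_all$j > n_a, , drop = FALSE]
  cross$j <- cross$j - n_a
  cross <- cross[cross$dist < rad_a[cross$i] + rad_b[cross$j], , drop = FALSE]

  chains_b <- sort(unique(at_b$chain))
  acc <- matrix(0, nrow = n_a, ncol = length(chains_b),
                dimnames = list(NULL, chains_b))
  point_area <- 4 * pi * rad_a^2 / params$n_sphere_points
  for (a in seq_len(n_a)) {
    p <- sweep(pts * rad_a[a], 2, xyz_a[a, ], "+")
    free <- rep(TRUE, nrow(p))
    for (o in c(nb_aa$j[nb_aa$i == a], nb_aa$i[nb_aa$j == a])) {
      if (!any(free)) break
      db2 <- (p[free, 1] - xyz_a[o, 1])^2 + (p[free, 2] - xyz_a[o, 2])^2 +
        (p[free, 3] - xyz_a[o, 3])^2
      free[free] <- db2 >= rad_a[o]^2
    }
    occl <- cross$j[cross$i == a]
    if (length(occl) == 0 || !any(free)) next
    idx <- which(free)
    depth <- matrix(-Inf, nrow = length(idx), ncol = length(chains_b))
    for (b in occl) {
      db <- sqrt((p[idx, 1] - xyz_b[b, 1])^2 + (p[idx, 2] - xyz_b[b, 2])^2 +
                   (p[idx, 3] - xyz_b[b, 3])^2)
      col <- match(at_b$chain[b], chains_b)
      depth[, col] <- pmax(depth[, col], rad_b[b] - db)
    }
    buried <- apply(depth, 1, max) > 0
    if (!any(buried)) next
    winner <- apply(depth[buried, , drop = FALSE], 1, which.max)
    tab <- tabulate(winner, nbins = length(chains_b))
    acc[a, ] <- acc[a, ] + tab * point_area[a]
  }
  role_of <- function(ch) {
    r <- unique(structure$role[structure$chain == ch])
    r <- r[!is.na(r)]
    if (length(r)) r[1] else NA_character_
  }
  out <- expand.grid(chain_a = sort(unique(at_a$chain)), chain_b = chains_b,
                     stringsAsFactors = FALSE) |>
    as_tibble() |>
    mutate(
      role_a = purrr::map_chr(.data$chain_a, role_of),
      role_b = purrr::map_chr(.data$chain_b, role_of),
      bsa = purrr::map2_dbl(.data$chain_a, .data$chain_b, function(ca, cb) {
        sum(acc[at_a$chain == ca, cb])
      })
    ) |>
    select("chain_a", "role_a", "chain_b", "role_b", "bsa") |>
    arrange(.data$chain_a, .data$chain_b)
  attr(out, "total_footprint") <- sum(out$bsa)
  out
}

#' Total antibody footprint on the antigen surface
#' @inheritParams pairwise_bsa
#' @return Area in angstrom squared.
#' @export
total_footprint <- function(structure,
                            antigen_side = c("hla_alpha", "b2m"),
                            antibody_side = c("fab_heavy", "fab_light"),
                            params = sasa_params()) {
  buried_surface_area(structure, antigen_side, antibody_side, params)
}

#' Cross-interface residue contacts
#'
#' Lists every residue pair across the interface whose minimum heavy-atom
#' distance is at or below `cutoff`, found with the cell-list neighbor search.
#' Each contact is classified as `salt_bridge` (opposite formally charged
#' side-chain groups in range), `hbond` (a donor-acceptor pair satisfying
#' `criteria`), or `nonbonded`.
#'
#' @param structure An `allo_structure` with roles assigned.
#' @param side_a,side_b Chain sets (roles and/or chain ids).
#' @param cutoff Heavy-atom distance cutoff, angstrom (default 4.0).
#' @param criteria [hbond_criteria()] used for the `hbond` classification.
#' @return Tibble with one row per residue pair: chain/position/residue for
#'   both sides, `min_dist`, `kind`.
#' @export
find_contacts <- function(structure,
                          side_a = c("hla_alpha", "b2m"),
                          side_b = c("fab_heavy", "fab_light"),
                          cutoff = 4.0, criteria = hbond_criteria()) {
  stopifnot(cutoff > 0)
  at_a <- side_atoms(structure, side_a)
  at_b <- side_atoms(structure, side_b)
  n_a <- nrow(at_a)
  xyz <- rbind(atom_xyz(at_a), atom_xyz(at_b))
  nb <- neighbor_pairs(xyz, cutoff)
  nb <- nb[nb$i <= n_a & nb$j > n_a, , drop = FALSE]
  if (nrow(nb) == 0) {
    return(tibble(chain_a = character(), resno_a = integer(),
                  aa_a = character(), role_a = character(),
                  chain_b = character(), resno_b = integer(),
                  aa_b = character(), role_b = character(),
                  min_dist = numeric(), kind = character()))
  }
  a_idx <- nb$i
  b_idx <- nb$j - n_a
  pairs <- tibble(
    chain_a = at_a$chain[a_idx], resno_a = at_a$resno[a_idx],
    aa_a = at_a$aa[a_idx], role_a = at_a$role[a_idx],
    resid_a = at_a$resid[a_idx], atom_a = at_a$atom[a_idx],
    chain_b = at_b$chain[b_idx], resno_b = at_b$resno[b_idx],
    aa_b = at_b$aa[b_idx], role_b = at_b$role[b_idx],
    resid_b = at_b$resid[b_idx], atom_b = at_b$atom[b_idx],
    dist = nb$dist
  )
  salt <- pairs |>
    filter(purrr::map2_lgl(.data$resid_a, .data$atom_a, atom_is_charged,
                           sign = "+") &
             purrr::map2_lgl(.data$resid_b, .data$atom_b, atom_is_charged,
                             sign = "-") |
             purrr::map2_lgl(.data$resid_a, .data$atom_a, atom_is_charged,
                             sign = "-") &
             purrr::map2_lgl(.data$resid_b, .data$atom_b, atom_is_charged,
                             sign = "+")) |>
    distinct(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b)
  hb <- detect_hbonds(structure, side_a, side_b, criteria)
  hb_res <- hb |>
    mutate(
      a_is_donor = .data$donor_chain %in% unique(at_a$chain),
      chain_a = ifelse(.data$a_is_donor, .data$donor_chain, .data$acceptor_chain),
      resno_a = ifelse(.data$a_is_donor, .data$donor_resno, .data$acceptor_resno),
      chain_b = ifelse(.data$a_is_donor, .data$acceptor_chain, .data$donor_chain),
      resno_b = ifelse(.data$a_is_donor, .data$acceptor_resno, .data$donor_resno)
    ) |>
    distinct(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b)
  pairs |>
    group_by(.data$chain_a, .data$resno_a, .data$aa_a, .data$role_a,
             .data$chain_b, .data$resno_b, .data$aa_b, .data$role_b) |>
    summarise(min_dist = min(.data$dist), .groups = "drop") |>
    mutate(
      is_salt = paste(.data$chain_a, .data$resno_a, .data$chain_b,
                      .data$resno_b) %in%
        paste(salt$chain_a, salt$resno_a, salt$chain_b, salt$resno_b),
      is_hb = paste(.data$chain_a, .data$resno_a, .data$chain_b,
                    .data$resno_b) %in%
        paste(hb_res$chain_a, hb_res$resno_a, hb_res$chain_b, hb_res$resno_b),
      kind = dplyr::case_when(.data$is_salt ~ "salt_bridge",
                              .data$is_hb ~ "hbond",
                              TRUE ~ "nonbonded")
    ) |>
    select(-"is_salt", -"is_hb") |>
    arrange(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b)
}

atom_is_charged <- function(resid, atom, sign) {
  tab <- if (sign == "+") SALT_POSITIVE else SALT_NEGATIVE
  !is.null(tab[[resid]]) && atom %in% tab[[resid]]
}

#' Cross-interface hydrogen bonds from heavy-atom geometry
#'
#' Pairs every donor heavy atom on one side with every acceptor heavy atom on
#' the other (both directions) and keeps pairs satisfying the distance and
#' acceptor-angle criteria. Donor/acceptor chemistry comes from per-residue
#' templates (backbone amide N donates except in proline; backbone carbonyl O
#' always accepts; side-chain polar atoms per residue type). Deduplicated per
#' donor-acceptor atom pair.
#'
#' @inheritParams find_contacts
#' @return Tibble with donor and acceptor chain/position/residue/atom columns,
#'   `dist` and `angle` (degrees; `NA` when the acceptor antecedent atom is
#'   absent, in which case the bond is kept on distance alone).
#' @export
detect_hbonds <- function(structure,
                          side_a = c("hla_alpha", "b2m"),
                          side_b = c("fab_heavy", "fab_light"),
                          criteria = hbond_criteria()) {
  at_a <- side_atoms(structure, side_a)
  at_b <- side_atoms(structure, side_b)
  hb_for <- function(don, acc_side) {
    donors <- filter(don, purrr::map2_lgl(.data$resid, .data$atom, is_donor))
    acceptors <- filter(acc_side,
                        purrr::map2_lgl(.data$resid, .data$atom, is_acceptor))
    if (nrow(donors) == 0 || nrow(acceptors) == 0) return(NULL)
    xyz <- rbind(atom_xyz(donors), atom_xyz(acceptors))
    nd <- nrow(donors)
    nb <- neighbor_pairs(xyz, criteria$max_distance)
    nb <- nb[nb$i <= nd & nb$j > nd, , drop = FALSE]
    if (nrow(nb) == 0) return(NULL)
    d_i <- nb$i
    a_i <- nb$j - nd
    ante <- purrr::map2(acceptors$atom[a_i], seq_along(a_i), function(atm, k) {
      ante_name <- HB_ANTECEDENT[atm]
      if (is.na(ante_name)) return(c(NA_real_, NA_real_, NA_real_))
      row <- acc_side |>
        filter(.data$chain == acceptors$chain[a_i[k]],
               .data$resno == acceptors$resno[a_i[k]],
               .data$atom == ante_name)
      if (nrow(row) == 0) return(c(NA_real_, NA_real_, NA_real_))
      c(row$x[1], row$y[1], row$z[1])
    })
    ante <- do.call(rbind, ante)
    av <- atom_xyz(acceptors)[a_i, , drop = FALSE]
    dv <- atom_xyz(donors)[d_i, , drop = FALSE]
    ang <- vec_angle(dv - av, ante - av)
    keep <- is.na(ang) | ang >= criteria$min_angle
    tibble(
      donor_chain = donors$chain[d_i], donor_resno = donors$resno[d_i],
      donor_aa = donors$aa[d_i], donor_atom = donors$atom[d_i],
      acceptor_chain = acceptors$chain[a_i],
      acceptor_resno = acceptors$resno[a_i],
      acceptor_aa = acceptors$aa[a_i], acceptor_atom = acceptors$atom[a_i],
      dist = nb$dist, angle = ang
    )[keep, ]
  }
  empty_hb <- tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_aa = character(), donor_atom = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_aa = character(), acceptor_atom = character(),
    dist = numeric(), angle = numeric())
  out <- bind_rows(empty_hb, hb_for(at_a, at_b), hb_for(at_b, at_a))
  if (nrow(out) == 0) return(out)
  out |>
    distinct(.data$donor_chain, .data$donor_resno, .data$donor_atom,
             .data$acceptor_chain, .data$acceptor_resno, .data$acceptor_atom,
             .keep_all = TRUE) |>
    arrange(.data$donor_chain, .data$donor_resno, .data$acceptor_chain,
            .data$acceptor_resno)
}

is_donor <- function(resid, atom) {
  (atom == "N" && resid != "PRO") ||
    (!is.null(HB_DONORS[[resid]]) && atom %in% HB_DONORS[[resid]])
}

is_acceptor <- function(resid, atom) {
  atom %in% c("O", "OXT") ||
    (!is.null(HB_ACCEPTORS[[resid]]) && atom %in% HB_ACCEPTORS[[resid]])
}

#' Epitope footprint and its discontinuous segments
#'
#' The epitope is the set of antigen-side residues appearing in at least one
#' cross-interface contact. Alpha-chain epitope positions are partitioned into
#' maximal runs in which consecutive positions differ by at most
#' `gap_tolerance`; each run is one segment of the (possibly discontinuous)
#' epitope.
#'
#' @param contacts Contact table from [find_contacts()] with the antigen on
#'   side a.
#' @param gap_tolerance Maximum numbering gap bridged within one segment
#'   (default 3).
#' @param segment_role Role whose positions are segmented (default
#'   `"hla_alpha"`).
#' @return List of class `allo_footprint` with elements `epitope` (tibble of
#'   residues) and `segments` (tibble with `segment`, `start`, `end`,
#'   `n_positions`).
#' @export
epitope_footprint <- function(contacts, gap_tolerance = 3,
                              segment_role = "hla_alpha") {
  epitope <- contacts |>
    distinct(.data$chain_a, .data$resno_a, .data$aa_a, .data$role_a) |>
    rename(chain = "chain_a", position = "resno_a", aa = "aa_a",
           role = "role_a") |>
    arrange(.data$chain, .data$position)
  pos <- sort(unique(epitope$position[!is.na(epitope$role) &
                                        epitope$role == segment_role]))
  segments <- if (length(pos) == 0) {
    tibble(segment = integer(), start = integer(), end = integer(),
           n_positions = integer())
  } else {
    brk <- cumsum(c(0, diff(pos) > gap_tolerance))
    tibble(position = pos, segment = brk + 1L) |>
      group_by(.data$segment) |>
      summarise(start = min(.data$position), end = max(.data$position),
                n_positions = n(), .groups = "drop")
  }
  structure(list(epitope = epitope, segments = segments,
                 gap_tolerance = gap_tolerance),
            class = "allo_footprint")
}

#' @export
print.allo_footprint <- function(x, ...) {
  cat("<allo_footprint> ", nrow(x$epitope), " epitope residue(s), ",
      nrow(x$segments), " segment(s) (gap tolerance ", x$gap_tolerance,
      ")\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Per-residue C-alpha displacement between bound and unbound structures
#'
#' Superposes the unbound structure onto the bound one on the C-alpha atoms of
#' `align_on` (shared positions of the chain carrying `role`) and reports the
#' residual C-alpha--C-alpha distance at every shared position, exposing local
#' binding-induced conformational change.
#'
#' @param bound,unbound `allo_structure`s sharing the chain numbering.
#' @param role Chain role compared (default `"hla_alpha"`).
#' @param align_on Positions used for the rigid fit (default: all shared
#'   positions).
#' @return Tibble with columns `position`, `displacement` (angstrom).
#' @export
residue_displacement <- function(bound, unbound, role = "hla_alpha",
                                 align_on = NULL) {
  ca <- function(s) {
    side_atoms(s, role) |>
      filter(.data$atom == "CA") |>
      distinct(.data$resno, .keep_all = TRUE)
  }
  ca_b <- ca(bound)
  ca_u <- ca(unbound)
  shared <- intersect(ca_b$resno, ca_u$resno)
  fit_pos <- if (is.null(align_on)) shared else intersect(align_on, shared)
  if (length(fit_pos) < 3) abort("Fewer than 3 shared alignment positions.")
  P <- atom_xyz(ca_u[match(fit_pos, ca_u$resno), ])
  Q <- atom_xyz(ca_b[match(fit_pos, ca_b$resno), ])
  tr <- kabsch(P, Q)
  moved <- apply_transform(atom_xyz(ca_u[match(shared, ca_u$resno), ]), tr)
  ref <- atom_xyz(ca_b[match(shared, ca_b$resno), ])
  tibble(position = shared,
         displacement = sqrt(rowSums((moved - ref)^2))) |>
    arrange(.data$position)
}
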