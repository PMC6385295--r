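# Structure input/output. A macromolecular structure is represented as a tidy
# atom table (one row per heavy atom) so every downstream operation is an
# ordinary data-frame computation. Parsing of the standard PDB/mmCIF dialects
# is delegated to bio3d; this layer normalizes altlocs, occupancies, element
# symbols, residue numbering and chain roles.

CORE_ROLES <- c("hla_alpha", "b2m", "peptide", "fab_heavy", "fab_light")
ALL_ROLES <- c(CORE_ROLES, "receptor", "other")

new_structure <- function(atoms, id = "structure") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("chain", "resno", "resid", "aa", "atom", "element",
                  "x", "y", "z", "occ", "polymer", "role") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Non-finite atomic coordinates.")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)) {
    abort("Occupancies must lie in [0, 1].")
  }
  attr(atoms, "structure_id") <- id
  class(atoms) <- c("allo_structure", class(atoms))
  atoms
}

#' @export
print.allo_structure <- function(x, ...) {
  cat("<allo_structure> ", structure_id(x), ": ",
      length(unique(x$chain[x$polymer])), " polymer chain(s), ",
      sum(x$polymer), " polymer atoms\n", sep = "")
  NextMethod()
}

#' Identifier of a parsed structure
#' @param structure An atom table from [read_structure()].
#' @return Character scalar.
#' @export
structure_id <- function(structure) {
  attr(structure, "structure_id") %||% "structure"
}

guess_element <- function(elety) {
  e <- gsub("[0-9']", "", toupper(elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "CL", "BR", "NA"), two, one)
}

#' Read a macromolecular structure into a tidy atom table
#'
#' Parses a PDB or mmCIF file into one row per atom with columns `chain`,
#' `resno`, `ins`, `resid` (three-letter), `aa` (one-letter), `atom`,
#' `element`, `x`, `y`, `z`, `occ`, `polymer`, `role`. Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken by altloc
#' identifier order), zero-occupancy records are dropped, and waters and
#' small-molecule heteroatoms are kept but flagged `polymer = FALSE` so that
#' geometric analyses, which operate on polymer heavy atoms, ignore them.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param numbering_offset Optional named numeric vector of per-chain offsets
#'   added to author residue numbers, to reconcile the deposited numbering
#'   with mature-protein numbering (e.g. `c(A = -24)`). Default: no offset.
#' @param id Identifier stored on the returned table; defaults to the file
#'   base name.
#' @return An `allo_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           numbering_offset = NULL, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) abort(paste0("Failed to parse ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- as_tibble(parsed$atom)
  if (nrow(at) == 0) abort("Empty structure: no atom records.")
  at$o[is.na(at$o)] <- 1
  at <- filter(at, .data$o > 0)
  elesy <- if ("elesy" %in% names(at)) at$elesy else NA_character_
  atoms <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = toupper(as.character(at$resid)),
    atom = as.character(at$elety),
    element = ifelse(is.na(elesy) | !nzchar(trimws(elesy)),
                     guess_element(at$elety), toupper(trimws(elesy))),
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    type = as.character(at$type)
  )
  # altloc: keep the highest-occupancy conformer, ties by altloc letter
  atoms <- atoms |>
    arrange(.data$chain, .data$resno, .data$ins, .data$atom,
            dplyr::desc(.data$occ), .data$alt) |>
    distinct(.data$chain, .data$resno, .data$ins, .data$atom, .keep_all = TRUE)
  atoms <- atoms |>
    mutate(
      aa = unname(AA_THREE_TO_ONE[.data$resid]),
      polymer = !is.na(.data$aa) &
        !(.data$resid %in% c("HOH", "WAT", "DOD")) &
        (.data$type == "ATOM" | .data$resid == "MSE"),
      aa = ifelse(is.na(.data$aa), "X", .data$aa),
      role = NA_character_
    ) |>
    select(-"alt", -"type")
  if (!any(atoms$polymer)) abort("Empty polymer: no standard protein residues.")
  if (!is.null(numbering_offset)) {
    stopifnot(!is.null(names(numbering_offset)))
    off <- numbering_offset[atoms$chain]
    off[is.na(off)] <- 0
    atoms$resno <- atoms$resno + as.integer(off)
  }
  new_structure(atoms, id = id %||% sub("\\.(pdb|cif)(\\.gz)?$", "",
                                        basename(path), ignore.case = TRUE))
}

chain_lengths <- function(structure) {
  structure |>
    filter(.data$polymer) |>
    distinct(.data$chain, .data$resno, .data$ins) |>
    dplyr::count(.data$chain, name = "n_res")
}

#' Assign biological roles to chains
#'
#' Populates the `role` column with one of `hla_alpha`, `b2m`, `peptide`,
#' `fab_heavy`, `fab_light`, `receptor`, `other`. With an explicit mapping the
#' assignment is taken as given (validated). In `"auto"` mode chains are
#' binned by residue count: a peptide-length chain (<= 15 residues) becomes
#' `peptide`, a beta-2-microglobulin-length chain (60-150) becomes `b2m`, a
#' chain above 250 residues becomes `hla_alpha`; Fab-length chains (150-250)
#' are never guessed as heavy versus light -- supply them via `fab`.
#'
#' @param structure An `allo_structure`.
#' @param roles Named character vector `c(chain = role, ...)`, or `"auto"`.
#' @param fab Optional named vector disambiguating Fab chains in auto mode,
#'   e.g. `c(H = "fab_heavy", L = "fab_light")`.
#' @return The structure with `role` filled in.
#' @export
assign_roles <- function(structure, roles = "auto", fab = NULL) {
  lens <- chain_lengths(structure)
  if (identical(roles, "auto")) {
    roles <- character(0)
    if (!is.null(fab)) roles <- fab
    auto <- setdiff(lens$chain, names(roles))
    for (band in list(
      list(role = "peptide",   sel = lens$n_res <= 15),
      list(role = "b2m",       sel = lens$n_res > 60 & lens$n_res <= 150),
      list(role = "hla_alpha", sel = lens$n_res > 250)
    )) {
      cand <- intersect(lens$chain[band$sel], auto)
      if (length(cand) > 1) {
        abort(paste0("Ambiguous auto role assignment for '", band$role,
                     "': candidate chains ", paste(cand, collapse = ", "),
                     ". Provide an explicit mapping."))
      }
      if (length(cand) == 1) roles[cand] <- band$role
    }
    fab_cand <- setdiff(
      lens$chain[lens$n_res > 150 & lens$n_res <= 250], names(roles))
    if (length(fab_cand) > 0) {
      abort(paste0("Fab-length chain(s) ", paste(fab_cand, collapse = ", "),
                   " cannot be auto-assigned heavy vs light; pass `fab = ",
                   "c(<chain> = \"fab_heavy\", <chain> = \"fab_light\")`."))
    }
  }
  roles <- unlist(roles)
  bad_role <- setdiff(roles, ALL_ROLES)
  if (length(bad_role)) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  bad_chain <- setdiff(names(roles), unique(structure$chain))
  if (length(bad_chain)) {
    abort(paste0("Role mapping names missing chain(s): ",
                 paste(bad_chain, collapse = ", ")))
  }
  dup <- roles[roles %in% CORE_ROLES][duplicated(roles[roles %in% CORE_ROLES])]
  if (length(dup)) {
    abort(paste0("More than one chain assigned to core role(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  structure$role <- unname(roles[structure$chain])
  structure
}

#' Chain identifiers carrying the given roles
#' @param structure An `allo_structure` with roles assigned.
#' @param side Character vector of roles and/or chain identifiers.
#' @return Character vector of chain identifiers.
#' @export
resolve_chains <- function(structure, side) {
  chains <- unique(structure$chain)
  out <- unique(c(
    chains[chains %in% side],
    unique(structure$chain[!is.na(structure$role) & structure$role %in% side])
  ))
  if (length(out) == 0) {
    abort(paste0("No chains match side specification: ",
                 paste(side, collapse = ", ")))
  }
  out
}

#' Extract a chain's sequence with explicit numbering
#'
#' Returns one row per position over the full numbering range of the chain,
#' with `aa = NA` at positions absent from the model, so numbering gaps are
#' explicit.
#'
#' @param structure An `allo_structure`.
#' @param chain Chain identifier.
#' @return Tibble with columns `position`, `aa`.
#' @export
chain_sequence <- function(structure, chain) {
  res <- structure |>
    filter(.data$polymer, .data$chain == .env$chain) |>
    distinct(.data$resno, .data$aa)
  if (nrow(res) == 0) abort(paste0("No such polymer chain: ", chain))
  tibble(position = seq(min(res$resno), max(res$resno))) |>
    left_join(res, by = c(position = "resno"))
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-width ATOM records (heavy atoms, resolved conformer
#' only) via bio3d, suitable for round-tripping fixtures and exporting
#' superposed models.
#'
#' @param structure An `allo_structure`.
#' @param path Output file path.
#' @param polymer_only Drop waters/heteroatoms (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, polymer_only = TRUE) {
  at <- if (polymer_only) filter(structure, .data$polymer) else structure
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(at)),
    resno = at$resno,
    resid = at$resid,
    eleno = seq_len(nrow(at)),
    elety = at$atom,
    chain = at$chain,
    insert = ifelse(nzchar(at$ins), at$ins, NA),
    o = at$occ,
    b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(path)
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

polymer_heavy <- function(structure) {
  filter(structure, .data$polymer, .data$element != "H")
}
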