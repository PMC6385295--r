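# Allele-reactivity rationalization: align panel sequences at epitope
# positions, classify substitution effects against the structural context,
# predict reactive/nonreactive per allele, and score concordance with
# single-antigen-bead mean fluorescence intensities.

#' Rules mapping epitope-position substitutions to predicted reactivity
#'
#' Critical positions are those whose disruption abrogates binding (the
#' eplet position 90 and the charged heavy-chain anchors 14 and 17);
#' weakening positions reduce but do not abolish binding (19, 39). All
#' positions use mature alpha-chain numbering. The observed-class boundary on
#' bead assays is `mfi_threshold` fluorescence units.
#'
#' @param critical_positions Integer vector (default `c(90, 14, 17)`).
#' @param weakening_positions Integer vector (default `c(19, 39)`).
#' @param mfi_threshold Numeric (default 500).
#' @return List of class `reactivity_rules`.
#' @export
reactivity_rules <- function(critical_positions = c(90, 14, 17),
                             weakening_positions = c(19, 39),
                             mfi_threshold = 500) {
  structure(list(critical_positions = as.integer(critical_positions),
                 weakening_positions = as.integer(weakening_positions),
                 mfi_threshold = mfi_threshold),
            class = "reactivity_rules")
}

normalize_allele <- function(x) {
  toupper(gsub("^HLA-", "", trimws(x)))
}

#' Build an allele panel from sequences and bead fluorescence
#'
#' @param sequences Named character vector of mature alpha-chain sequences
#'   (names are allele designations such as `"A*11:01"`, with or without an
#'   `"HLA-"` prefix), pre-aligned to a common numbering.
#' @param mfi Named numeric vector of mean fluorescence intensities; alleles
#'   without a value are retained with `NA` (with a warning).
#' @return Tibble with columns `allele`, `sequence`, `mfi`.
#' @export
allele_panel <- function(sequences, mfi = NULL) {
  alleles <- normalize_allele(names(sequences))
  if (anyDuplicated(alleles)) {
    abort(paste0("Duplicate allele(s): ",
                 paste(unique(alleles[duplicated(alleles)]), collapse = ", ")))
  }
  panel <- tibble(allele = alleles,
                  sequence = toupper(unname(sequences)),
                  mfi = NA_real_)
  if (!is.null(mfi)) {
    names(mfi) <- normalize_allele(names(mfi))
    panel$mfi <- unname(mfi[panel$allele])
    missing_mfi <- panel$allele[is.na(panel$mfi)]
    if (length(missing_mfi)) {
      warn(paste0("No MFI for allele(s): ",
                  paste(missing_mfi, collapse = ", "),
                  " (retained with NA)."))
    }
    extra <- setdiff(names(mfi), panel$allele)
    if (length(extra)) {
      warn(paste0("MFI entries with no sequence: ",
                  paste(extra, collapse = ", "), " (dropped)."))
    }
  }
  panel
}

#' Read an allele panel from FASTA sequences and an MFI table
#'
#' @param fasta Path to a FASTA file of aligned mature alpha-chain sequences,
#'   one record per allele.
#' @param mfi_csv Path to a CSV with columns `allele` and `mfi`.
#' @return Tibble as in [allele_panel()].
#' @export
read_allele_panel <- function(fasta, mfi_csv = NULL) {
  seqs <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  seqs <- setNames(toupper(unlist(seqs)), names(seqs))
  mfi <- NULL
  if (!is.null(mfi_csv)) {
    tab <- readr::read_csv(mfi_csv, show_col_types = FALSE)
    mfi <- setNames(tab$mfi, tab$allele)
  }
  allele_panel(seqs, mfi)
}

aa_at <- function(sequence, position) {
  if (any(position > nchar(sequence) | position < 1)) {
    abort("Epitope position outside sequence range.")
  }
  substring(sequence, position, position)
}

#' Epitope-position differences of each allele from a reference
#'
#' @param panel Tibble from [allele_panel()].
#' @param reference Reference allele name present in the panel.
#' @param positions Epitope positions (mature numbering) to compare.
#' @return Tibble with columns `allele`, `position`, `ref_aa`, `alt_aa`; one
#'   row per differing position (alleles identical to the reference over the
#'   positions contribute no rows).
#' @export
epitope_variants <- function(panel, reference, positions) {
  reference <- normalize_allele(reference)
  ref_row <- filter(panel, .data$allele == reference)
  if (nrow(ref_row) == 0) abort(paste0("Reference allele not in panel: ",
                                       reference))
  positions <- sort(unique(as.integer(positions)))
  ref_aa <- vapply(positions, function(p) aa_at(ref_row$sequence[1], p), "")
  panel |>
    select("allele", "sequence") |>
    tidyr::crossing(tibble(position = positions,
                           ref_aa = ref_aa)) |>
    mutate(alt_aa = purrr::map2_chr(.data$sequence, .data$position, aa_at)) |>
    filter(.data$alt_aa != .data$ref_aa) |>
    select("allele", "position", "ref_aa", "alt_aa") |>
    arrange(.data$allele, .data$position)
}

#' Classify the structural effect of epitope-position substitutions
#'
#' Applies a rule table to each substitution, in order: loss of a
#' hydrogen-bonding side chain (the reference residue is hydrogen bonded
#' across the interface and the variant cannot support the bond, through loss
#' of polar chemistry or a shorter side chain) -> `hbond_loss`; formal charge
#' sign flip -> `charge_reversal`; charged to hydrophobic ->
#' `charge_to_hydrophobic`; loss of three or more side-chain heavy atoms ->
#' `side_chain_truncation`; otherwise `conservative`. Predicted impact is
#' `abrogating` for hydrogen-bond loss or any charge-class change at a
#' critical position, `weakening` for any change at a weakening position,
#' `tolerated` otherwise.
#'
#' @param variants Tibble with columns `position`, `ref_aa`, `alt_aa` (as
#'   from [epitope_variants()]; an `allele` column is carried through).
#' @param hbonded_positions Positions whose reference residue donates or
#'   accepts an interface hydrogen bond (from [detect_hbonds()] on the
#'   complex).
#' @param rules [reactivity_rules()].
#' @return Input with added `effect_class` and `predicted_impact` columns.
#' @export
classify_substitutions <- function(variants, hbonded_positions,
                                   rules = reactivity_rules()) {
  if (nrow(variants) == 0) {
    return(mutate(variants, effect_class = character(0),
                  predicted_impact = character(0)))
  }
  ref <- variants$ref_aa
  alt <- variants$alt_aa
  ref_charge <- aa_property(ref, "charge")
  alt_charge <- aa_property(alt, "charge")
  ref_atoms <- aa_property(ref, "side_chain_atoms")
  alt_atoms <- aa_property(alt, "side_chain_atoms")
  alt_polar <- aa_property(alt, "polar_side_chain")
  alt_hydro <- aa_property(alt, "hydrophobic")
  hbonded <- variants$position %in% hbonded_positions
  effect <- dplyr::case_when(
    ref == alt ~ "none",
    hbonded & (!alt_polar | alt_atoms < ref_atoms) ~ "hbond_loss",
    ref_charge * alt_charge < 0 ~ "charge_reversal",
    ref_charge != 0 & alt_hydro ~ "charge_to_hydrophobic",
    ref_atoms - alt_atoms >= 3 ~ "side_chain_truncation",
    TRUE ~ "conservative"
  )
  critical <- variants$position %in% rules$critical_positions
  weakening <- variants$position %in% rules$weakening_positions
  charge_change <- effect %in% c("charge_reversal", "charge_to_hydrophobic")
  impact <- dplyr::case_when(
    effect == "none" ~ "tolerated",
    critical & (effect == "hbond_loss" | charge_change) ~ "abrogating",
    weakening ~ "weakening",
    TRUE ~ "tolerated"
  )
  mutate(variants, effect_class = effect, predicted_impact = impact)
}

#' Predict per-allele reactivity from epitope-position substitutions
#'
#' An allele is predicted `nonreactive` if it carries at least one abrogating
#' substitution relative to the reference; `reactive` otherwise (alleles
#' identical to the reference at every epitope position are always
#' `reactive`). The classified substitutions are attached per allele as the
#' structural reasons for the call.
#'
#' @param panel Tibble from [allele_panel()].
#' @param reference Reference (immunizing) allele name.
#' @param epitope_positions Epitope positions in mature numbering.
#' @param hbonded_positions Subset of positions hydrogen bonded across the
#'   interface in the reference complex.
#' @param rules [reactivity_rules()].
#' @return Tibble with columns `allele`, `predicted`, `n_abrogating`,
#'   `n_weakening`, and a `reasons` list-column of classified substitutions.
#' @export
predict_reactivity <- function(panel, reference, epitope_positions,
                               hbonded_positions,
                               rules = reactivity_rules()) {
  variants <- epitope_variants(panel, reference, epitope_positions) |>
    classify_substitutions(hbonded_positions, rules)
  per <- variants |>
    group_by(.data$allele) |>
    summarise(n_abrogating = sum(.data$predicted_impact == "abrogating"),
              n_weakening = sum(.data$predicted_impact == "weakening"),
              .groups = "drop")
  panel |>
    select("allele") |>
    left_join(per, by = "allele") |>
    mutate(
      n_abrogating = tidyr::replace_na(.data$n_abrogating, 0L),
      n_weakening = tidyr::replace_na(.data$n_weakening, 0L),
      predicted = ifelse(.data$n_abrogating > 0, "nonreactive", "reactive"),
      reasons = purrr::map(.data$allele, function(a) {
        filter(variants, .data$allele == a)
      })
    ) |>
    select("allele", "predicted", "n_abrogating", "n_weakening", "reasons")
}

#' Concordance of predicted reactivity with bead-assay fluorescence
#'
#' The observed class is `reactive` when MFI is at or above the rules'
#' threshold. Returns the 2 x 2 confusion counts (predicted reactive and
#' observed reactive = TP) and lists discordant alleles. Alleles without MFI
#' are excluded from scoring.
#'
#' @param prediction Output of [predict_reactivity()].
#' @param panel Tibble from [allele_panel()] carrying `mfi`.
#' @param rules [reactivity_rules()].
#' @return List of class `concordance_report`: `confusion` (one-row tibble
#'   with `tp`, `fp`, `tn`, `fn`, `n_scored`, `concordance`), `discordant`
#'   (tibble of alleles with predicted and observed classes).
#' @export
evaluate_concordance <- function(prediction, panel,
                                 rules = reactivity_rules()) {
  scored <- prediction |>
    inner_join(select(panel, "allele", "mfi"), by = "allele") |>
    filter(!is.na(.data$mfi)) |>
    mutate(observed = ifelse(.data$mfi >= rules$mfi_threshold,
                             "reactive", "nonreactive"))
  confusion <- scored |>
    summarise(
      tp = sum(.data$predicted == "reactive" & .data$observed == "reactive"),
      fp = sum(.data$predicted == "reactive" & .data$observed == "nonreactive"),
      tn = sum(.data$predicted == "nonreactive" &
                 .data$observed == "nonreactive"),
      fn = sum(.data$predicted == "nonreactive" & .data$observed == "reactive"),
      n_scored = n()
    ) |>
    mutate(concordance = ifelse(.data$n_scored > 0,
                                (.data$tp + .data$tn) / .data$n_scored, NA_real_))
  discordant <- scored |>
    filter(.data$predicted != .data$observed) |>
    select("allele", "predicted", "observed", "mfi")
  structure(list(confusion = confusion, discordant = discordant),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> concordance ",
      signif(100 * x$confusion$concordance, 4), "% over ",
      x$confusion$n_scored, " allele(s); ", nrow(x$discordant),
      " discordant\n", sep = "")
  invisible(x)
}
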