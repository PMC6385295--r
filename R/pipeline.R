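# End-to-end orchestration: structure -> footprint -> reactivity ->
# co-engagement, collected into one machine-readable report with every
# tunable parameter echoed for provenance.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage: ", name, "] ", conditionMessage(e)))
  })
}

#' Run the footprint -> reactivity -> co-engagement pipeline
#'
#' Computes the interface report (pairwise buried areas, total footprint,
#' contacts, hydrogen bonds, epitope segments) on an antibody-antigen
#' complex; if an allele panel is supplied, predicts per-allele reactivity
#' from the structurally derived epitope and scores concordance against the
#' panel's MFI; if receptor complexes are supplied, superposes each onto the
#' target via the shared HLA chain and reports steric clashes against the
#' antibody. Every tunable parameter is echoed in the report.
#'
#' @param structure An `allo_structure` with roles assigned (the
#'   antibody-antigen complex).
#' @param panel Optional allele panel tibble ([allele_panel()]); when `NULL`
#'   the reactivity stage is marked skipped.
#' @param reference Reference allele for the reactivity stage.
#' @param receptors Optional named list of `allo_structure`s, each containing
#'   the shared `hla_alpha` chain plus receptor chains.
#' @param antigen_side,antibody_side Chain sets (roles) of the two sides.
#' @param params [sasa_params()].
#' @param criteria [hbond_criteria()].
#' @param rules [reactivity_rules()].
#' @param contact_cutoff Contact distance cutoff, angstrom.
#' @param gap_tolerance Epitope segment gap tolerance.
#' @param fit_positions Residue range for receptor superposition.
#' @param overlap_tolerance Clash overlap tolerance, angstrom.
#' @return A list of class `allo_report` with elements `interface`,
#'   `reactivity`, `coengagement`, `parameters`.
#' @export
run_footprint_pipeline <- function(structure, panel = NULL,
                                   reference = "A*11:01", receptors = NULL,
                                   antigen_side = c("hla_alpha", "b2m"),
                                   antibody_side = c("fab_heavy", "fab_light"),
                                   params = sasa_params(),
                                   criteria = hbond_criteria(),
                                   rules = reactivity_rules(),
                                   contact_cutoff = 4.0, gap_tolerance = 3,
                                   fit_positions = 1:180,
                                   overlap_tolerance = 0.4) {
  antigen_side <- intersect(antigen_side,
                            c(structure$role, unique(structure$chain)))
  antibody_side <- intersect(antibody_side,
                             c(structure$role, unique(structure$chain)))
  interface <- stage("interface", {
    pair <- pairwise_bsa(structure, antigen_side, antibody_side, params)
    contacts <- find_contacts(structure, antigen_side, antibody_side,
                              contact_cutoff, criteria)
    hbonds <- detect_hbonds(structure, antigen_side, antibody_side, criteria)
    fp <- epitope_footprint(contacts, gap_tolerance)
    list(pair_bsa = pair,
         total_footprint = attr(pair, "total_footprint"),
         contacts = contacts, hbonds = hbonds,
         epitope = fp$epitope, segments = fp$segments)
  })
  reactivity <- if (is.null(panel)) {
    list(status = "skipped")
  } else {
    stage("reactivity", {
      alpha_chain <- resolve_chains(structure, "hla_alpha")
      epi_pos <- interface$epitope |>
        filter(.data$role == "hla_alpha") |>
        pull("position")
      hb_pos <- unique(c(
        interface$hbonds$donor_resno[
          interface$hbonds$donor_chain %in% alpha_chain],
        interface$hbonds$acceptor_resno[
          interface$hbonds$acceptor_chain %in% alpha_chain]
      ))
      hb_pos <- intersect(hb_pos, epi_pos)
      pred <- predict_reactivity(panel, reference, epi_pos, hb_pos, rules)
      conc <- evaluate_concordance(pred, panel, rules)
      list(status = "completed", prediction = pred,
           concordance = conc$confusion, discordant = conc$discordant)
    })
  }
  coengagement <- if (is.null(receptors)) {
    list(status = "skipped")
  } else {
    stage("coengagement", {
      res <- purrr::imap(receptors, function(rec, name) {
        sup <- superpose_structures(structure, rec,
                                    shared_role = "hla_alpha",
                                    fit_positions = fit_positions)
        rec_chains <- setdiff(unique(sup$structure$chain),
                              resolve_chains(sup$structure, "hla_alpha"))
        combined <- bind_rows(
          filter(structure, .data$role %in% antibody_side |
                   .data$chain %in% antibody_side),
          filter(sup$structure, .data$chain %in% rec_chains)
        )
        class(combined) <- class(structure)
        clashes <- detect_clashes(combined, antibody_side, rec_chains,
                                  overlap_tolerance)
        list(receptor = name, fit_rmsd = sup$transform$rmsd,
             n_fit_atoms = sup$transform$n_fit_atoms,
             n_clashes = clashes$n_clashes,
             min_distance = clashes$min_distance)
      })
      list(status = "completed", receptors = unname(res))
    })
  }
  structure(list(
    interface = interface,
    reactivity = reactivity,
    coengagement = coengagement,
    parameters = list(
      structure_id = structure_id(structure),
      antigen_side = antigen_side, antibody_side = antibody_side,
      probe_radius = params$probe_radius,
      n_sphere_points = params$n_sphere_points,
      contact_cutoff = contact_cutoff,
      hbond_max_distance = criteria$max_distance,
      hbond_min_angle = criteria$min_angle,
      gap_tolerance = gap_tolerance,
      critical_positions = rules$critical_positions,
      weakening_positions = rules$weakening_positions,
      mfi_threshold = rules$mfi_threshold,
      fit_positions = range(fit_positions),
      overlap_tolerance = overlap_tolerance,
      schema_version = "1.0"
    )
  ), class = "allo_report")
}

#' @export
print.allo_report <- function(x, ...) {
  cat("<allo_report> footprint ", round(x$interface$total_footprint, 1),
      " A^2 over ", nrow(x$interface$epitope), " epitope residue(s), ",
      nrow(x$interface$segments), " segment(s); reactivity: ",
      x$reactivity$status %||% "completed", "; co-engagement: ",
      x$coengagement$status %||% "completed", "\n", sep = "")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Deterministic serialization (no timestamps): rerunning the pipeline with
#' the same inputs yields byte-identical output.
#'
#' @param report An `allo_report` (or any list of tibbles/scalars).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = 8, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    return(lapply(x, unclass_deep))
  }
  x
}
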