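# Seed-deterministic synthetic generators for every input class the pipeline
# consumes: toy multi-chain structures with analytically known contact and
# hydrogen-bond ground truth, allele panels with planted epitope variants and
# band-separated MFI, SCK sensorgram collections, and cytotoxicity replicate
# tables. Toys use idealized residue templates (fixed internal geometry), not
# fragment libraries: sufficient for exact geometric ground truth.

#' Build an atom table from a plain data frame
#'
#' Convenience constructor for hand-built fixtures: missing columns are
#' filled with defaults (`ins = ""`, `occ = 1`, `polymer = TRUE`,
#' `role = NA`, `resid` from `aa`, `element` from the atom name).
#'
#' @param df Data frame with at least `chain`, `resno`, `atom`, `x`, `y`,
#'   `z`; optionally `aa`/`resid`, `element`, `occ`, `role`.
#' @param id Structure identifier.
#' @return An `allo_structure`.
#' @export
as_structure <- function(df, id = "structure") {
  df <- as_tibble(df)
  has <- function(col) col %in% names(df)
  if (!has("aa")) df$aa <- "G"
  if (!has("resid")) df$resid <- unname(AA_ONE_TO_THREE[df$aa])
  if (!has("element")) df$element <- guess_element(df$atom)
  if (!has("ins")) df$ins <- ""
  if (!has("occ")) df$occ <- 1
  if (!has("polymer")) df$polymer <- TRUE
  if (!has("role")) df$role <- NA_character_
  df$resno <- as.integer(df$resno)
  new_structure(df, id = id)
}

# Idealized residue template: backbone-like heavy atoms with the carbonyl
# oxygen displaced toward +y so that stacking chains along y places an
# O...N pair at exactly (gap - 1.23) angstrom for aligned residues.
TOY_TEMPLATE <- tibble::tibble(
  atom = c("N", "CA", "C", "O"),
  element = c("N", "C", "C", "O"),
  dx = c(0, 1.5, 3.0, 0),
  dy = c(0, 0, 0, 1.23),
  dz = c(0, 0, 0, 0)
)

TOY_O_LIFT <- 1.23     # y offset of the template O above the chain axis
TOY_RES_SPACING <- 5   # x spacing between residues

#' Toy multi-chain complex with exact contact/H-bond ground truth
#'
#' Chains are straight runs of idealized glycine-like residues
#' (`r TOY_RES_SPACING` angstrom apart along x), stacked along y with the
#' given inter-chain gaps. By construction the closest cross-chain atom pair
#' for aligned residues i--i of adjacent chains is the lower chain's carbonyl
#' O against the upper chain's amide N at exactly `gap - 1.23` angstrom, with
#' an acceptor-angle of about 112 degrees, so the planted contacts and
#' hydrogen bonds are known analytically. Buried-area ground truth is
#' attached from the quadrature SASA oracle.
#'
#' @param n_res Residues per chain (default 5).
#' @param gaps Numeric vector of gaps (angstrom) between consecutive chains;
#'   `length(gaps) + 1` chains are built (default one gap of 4.0).
#' @param roles Named role map; default assigns `hla_alpha` (+ `b2m` for
#'   three chains) to the lower chains and `fab_heavy` to the top chain.
#' @param contact_cutoff,hbond_max Cutoffs used to derive the planted ground
#'   truth (defaults 4.0 and 3.5).
#' @param compute_bsa Attach quadrature buried-area truth (default `TRUE`).
#' @return List: `structure`, and `truth` with elements `contacts` (tibble of
#'   chain pairs and aligned positions in contact), `hbonds`, and
#'   `total_bsa`/`antigen_side`/`antibody_side` when `compute_bsa`.
#' @export
make_toy_complex <- function(n_res = 5, gaps = 4.0, roles = NULL,
                             contact_cutoff = 4.0, hbond_max = 3.5,
                             compute_bsa = TRUE) {
  stopifnot(n_res >= 1, all(gaps > TOY_O_LIFT))
  n_chains <- length(gaps) + 1
  if (n_chains > 26) abort("Too many chains for single-letter identifiers.")
  chain_ids <- LETTERS[seq_len(n_chains)]
  y_off <- cumsum(c(0, gaps))
  atoms <- purrr::map_dfr(seq_len(n_chains), function(k) {
    purrr::map_dfr(seq_len(n_res), function(i) {
      mutate(TOY_TEMPLATE,
             chain = chain_ids[k], resno = i, aa = "G",
             x = .data$dx + TOY_RES_SPACING * (i - 1),
             y = .data$dy + y_off[k],
             # CA atoms get a per-residue z wiggle so each chain's CA trace
             # is non-collinear (superposable); CA is never the closest
             # cross-chain atom, so contact/H-bond ground truth is untouched
             z = .data$dz + ifelse(.data$atom == "CA", 0.4 * cos(i), 0))
    })
  }) |> select("chain", "resno", "aa", "atom", "element", "x", "y", "z")
  if (is.null(roles)) {
    roles <- if (n_chains == 1) {
      setNames("hla_alpha", chain_ids)
    } else if (n_chains == 2) {
      setNames(c("hla_alpha", "fab_heavy"), chain_ids)
    } else {
      setNames(c("hla_alpha", "b2m",
                 rep("other", n_chains - 3), "fab_heavy"), chain_ids)
    }
  }
  st <- as_structure(atoms, id = "toy_complex") |> assign_roles(roles)
  # closed-form cross-chain distances for adjacent chains at gap g:
  # aligned residues i-i meet at the O...N pair, d = g - 1.23; the next
  # diagonal (i+1)-i pair meets at the O...C pair, d = sqrt(4 + (g - 1.23)^2)
  truth_contacts <- purrr::map_dfr(seq_along(gaps), function(k) {
    d_aligned <- gaps[k] - TOY_O_LIFT
    d_diag <- sqrt(4 + d_aligned^2)
    bind_rows(
      if (d_aligned <= contact_cutoff)
        tibble(chain_a = chain_ids[k], chain_b = chain_ids[k + 1],
               resno_a = seq_len(n_res), resno_b = seq_len(n_res),
               min_dist = d_aligned),
      if (d_diag <= contact_cutoff && n_res > 1)
        tibble(chain_a = chain_ids[k], chain_b = chain_ids[k + 1],
               resno_a = seq_len(n_res - 1) + 1L,
               resno_b = seq_len(n_res - 1),
               min_dist = d_diag)
    )
  })
  hb_pairs <- which(gaps - TOY_O_LIFT <= hbond_max)
  truth_hbonds <- purrr::map_dfr(hb_pairs, function(k) {
    tibble(acceptor_chain = chain_ids[k], donor_chain = chain_ids[k + 1],
           position = seq_len(n_res),
           dist = gaps[k] - TOY_O_LIFT)
  })
  truth <- list(contacts = truth_contacts, hbonds = truth_hbonds)
  if (compute_bsa && n_chains >= 2) {
    antigen <- chain_ids[-n_chains]
    antibody <- chain_ids[n_chains]
    params <- sasa_params()
    alone <- sasa_quadrature(st, params, chains = antigen)
    both <- sasa_quadrature(st, params, chains = c(antigen, antibody))
    truth$total_bsa <- sum(alone$sasa) -
      sum(both$sasa[both$chain %in% antigen])
    truth$antigen_side <- antigen
    truth$antibody_side <- antibody
  }
  list(structure = st, truth = truth)
}

#' Synthetic allele panel with planted epitope variants
#'
#' Builds a reference allele (named `A*11:01`-style but with a SYNTHETIC
#' random-background sequence carrying the canonical epitope-position
#' residues Arg14, Arg17, Glu19, Asp39, Asp90) plus variant alleles: some
#' with one planted abrogating substitution (Asp90Ala, Arg14Trp or
#' Arg17Ser), some with one weakening substitution (Glu19Lys or Asp39Tyr),
#' the rest identical over the epitope. Optionally includes a synthetic
#' `A*66:01`/`A*66:02`-style pair differing only at positions 90 and 163
#' (the latter outside the epitope). MFI values are drawn uniformly from a
#' band consistent with each allele's truth label, so the bands straddle the
#' observed-class threshold by construction.
#'
#' @param n_identical,n_abrogating,n_weakening Counts of planted allele
#'   classes (defaults 4, 3, 2).
#' @param seed Integer seed; all randomness derives from it.
#' @param include_position90_pair Add the two-allele pair split only by the
#'   eplet position (default `TRUE`).
#' @param mfi_bands List with `nonreactive` and `reactive` ranges (defaults
#'   0-400 and 600-20000, straddling the 500 threshold).
#' @param seq_length Sequence length (default 275, a mature class-I alpha
#'   chain ectodomain).
#' @return List: `panel` (tibble `allele`, `sequence`, `mfi`), `truth`
#'   (tibble `allele`, `label`), `reference`, `epitope_positions`,
#'   `hbonded_positions`.
#' @export
make_allele_panel <- function(n_identical = 4, n_abrogating = 3,
                              n_weakening = 2, seed = 1,
                              include_position90_pair = TRUE,
                              mfi_bands = list(nonreactive = c(0, 400),
                                               reactive = c(600, 20000)),
                              seq_length = 275) {
  stopifnot(seq_length >= 170)
  set.seed(seed)
  epitope_positions <- c(14L, 16L, 17L, 18L, 19L, 39L, 90L)
  hbonded_positions <- c(14L, 17L, 90L)
  aa20 <- AA_PROPERTIES$aa
  ref <- sample(aa20, seq_length, replace = TRUE)
  ref[c(14, 17, 19, 39, 90)] <- c("R", "R", "E", "D", "D")
  seq_str <- function(v) paste(v, collapse = "")
  abro_menu <- list(c(90, "A"), c(14, "W"), c(17, "S"))
  weak_menu <- list(c(19, "K"), c(39, "Y"))
  alleles <- list()
  labels <- character()
  add <- function(name, seqv, label) {
    alleles[[name]] <<- seq_str(seqv)
    labels[name] <<- label
  }
  add("A*11:01", ref, "reactive")
  for (i in seq_len(n_identical)) {
    v <- ref
    # mutate a position far outside the epitope region
    p <- 200 + i
    v[p] <- sample(setdiff(aa20, v[p]), 1)
    add(sprintf("S*%02d:01", i), v, "reactive")
  }
  for (i in seq_len(n_abrogating)) {
    m <- abro_menu[[(i - 1) %% length(abro_menu) + 1]]
    v <- ref
    v[as.integer(m[1])] <- m[2]
    add(sprintf("S*%02d:02", i), v, "nonreactive")
  }
  for (i in seq_len(n_weakening)) {
    m <- weak_menu[[(i - 1) %% length(weak_menu) + 1]]
    v <- ref
    v[as.integer(m[1])] <- m[2]
    add(sprintf("S*%02d:03", i), v, "reactive")
  }
  if (include_position90_pair) {
    v1 <- ref
    v1[163] <- sample(setdiff(aa20, v1[163]), 1)
    add("A*66:01", v1, "reactive")
    v2 <- v1
    v2[90] <- "A"
    add("A*66:02", v2, "nonreactive")
  }
  nm <- names(alleles)
  mfi <- vapply(nm, function(a) {
    band <- mfi_bands[[if (labels[a] == "reactive") "reactive"
                       else "nonreactive"]]
    runif(1, band[1], band[2])
  }, numeric(1))
  panel <- allele_panel(unlist(alleles), mfi)
  list(panel = panel,
       truth = tibble(allele = normalize_allele(nm),
                      label = unname(labels)),
       reference = "A*11:01",
       epitope_positions = epitope_positions,
       hbonded_positions = hbonded_positions)
}

#' Write an allele panel to FASTA + CSV
#'
#' @param panel Tibble from [allele_panel()].
#' @param fasta,mfi_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_allele_panel <- function(panel, fasta, mfi_csv) {
  seqinr::write.fasta(as.list(panel$sequence), names = panel$allele,
                      file.out = fasta)
  readr::write_csv(select(panel, "allele", "mfi"), mfi_csv)
  invisible(c(fasta = fasta, mfi_csv = mfi_csv))
}

#' Collection of simulated SCK sensorgrams with attached truth
#'
#' @inheritParams simulate_sck
#' @param n_seeds Number of replicate noisy simulations.
#' @param base_seed Seed for the first replicate; replicate k uses
#'   `base_seed + k - 1`.
#' @return Tibble with columns `seed` and a `sensorgram` list-column; the
#'   true parameters are attached as attribute `params`.
#' @export
make_sensorgram_set <- function(ka, kd, Rmax, schedule = sck_schedule(),
                                noise_sd = 0, n_seeds = 1, base_seed = 1) {
  out <- tibble(
    seed = base_seed + seq_len(n_seeds) - 1,
    sensorgram = purrr::map(base_seed + seq_len(n_seeds) - 1, function(s) {
      simulate_sck(ka, kd, Rmax, schedule, noise_sd = noise_sd, seed = s)
    })
  )
  attr(out, "params") <- c(ka = ka, kd = kd, Rmax = Rmax)
  out
}

#' Synthetic cytotoxicity replicate tables
#'
#' Draws gated death fractions per condition from beta-family distributions.
#' Scenarios: `"separation"` (a treated and an isotype-control condition with
#' disjoint experimental-death ranges, so the exact rank test sits at the
#' complete-separation boundary), `"null"` (both conditions identically
#' distributed), `"subclasses"` (four antibody-subclass conditions with
#' graded effect, emulating a four-group comparison design).
#'
#' @param scenario One of `"separation"`, `"null"`, `"subclasses"`.
#' @param n_replicates Replicates per condition (>= 2; default 4).
#' @param seed Integer seed.
#' @return Tibble with columns `condition`, `replicate`, `experimental`,
#'   `baseline`, `maximum`.
#' @export
make_cytotox_experiment <- function(scenario = c("separation", "null",
                                                 "subclasses"),
                                    n_replicates = 4, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_replicates < 2) abort("Need at least 2 replicates per condition.")
  set.seed(seed)
  draw <- function(cond, lo, hi) {
    tibble(condition = cond, replicate = seq_len(n_replicates),
           experimental = lo + (hi - lo) * rbeta(n_replicates, 2, 2),
           baseline = runif(n_replicates, 0.04, 0.08),
           maximum = runif(n_replicates, 0.85, 0.95))
  }
  switch(scenario,
    separation = bind_rows(draw("treated", 0.50, 0.80),
                           draw("isotype", 0.09, 0.15)),
    null = bind_rows(draw("treated", 0.20, 0.40),
                     draw("isotype", 0.20, 0.40)),
    subclasses = bind_rows(draw("IgG1", 0.55, 0.75),
                           draw("IgG2", 0.35, 0.55),
                           draw("IgG3", 0.55, 0.75),
                           draw("IgG4", 0.08, 0.18))
  )
}
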