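---
title: "Methods: quantifying an alloantibody's footprint on HLA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying an alloantibody's footprint on HLA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allofoot)
```

`allofoot` quantifies how an antibody Fab engages a class-I HLA molecule —
the epitope footprint, its consequences for allele reactivity, the
geometric compatibility with other immune receptors, the 1:1 binding
kinetics, and the statistics of downstream cytotoxicity assays. This
vignette records the models, conventions and numerical choices behind each
stage, in enough detail that a reader could reimplement them.

## Structures as tidy atom tables

A structure is a tibble with one row per heavy atom (`chain`, `resno`,
`ins`, `resid`, `aa`, `atom`, `element`, `x`, `y`, `z`, `occ`, `polymer`,
`role`). Parsing of PDB/mmCIF is delegated to bio3d; this layer then

* resolves alternate locations to the highest-occupancy conformer, ties
  broken by altloc letter (deterministic and conventional);
* drops zero-occupancy records and flags waters and small-molecule
  heteroatoms `polymer = FALSE`, so geometry ignores them;
* optionally applies a per-chain numbering offset so that epitope
  positions can always be quoted in mature-protein numbering regardless of
  the deposition's convention (validated in practice by checking the
  expected residue identity at a landmark position, e.g. Asp at α90);
* assigns biological roles (`hla_alpha`, `b2m`, `peptide`, `fab_heavy`,
  `fab_light`, `receptor`). Auto-assignment bins chains by residue count
  (peptide ≤ 15, β2m 60–150, α chain > 250); Fab-length chains (150–250)
  are *never* guessed heavy versus light, because chain length cannot
  distinguish them — the caller must say. Analyses run on a single
  user-selected complex copy when the asymmetric unit contains several.

Crystal structures at typical resolutions carry no reliable hydrogens, so
**all geometric criteria use heavy atoms only**.

## Solvent-accessible surface area

SASA is computed by the Shrake–Rupley method: each atom's van der Waals
sphere (Chothia-style radii — C 1.70, N 1.55, O 1.52, S 1.80 Å,
overridable) is inflated by the probe radius (default 1.4 Å, water) and
sampled with a deterministic golden-spiral lattice (default 960 points;
the accessible fraction of points outside every other inflated sphere
converts to area). Neighbor lookup uses a cubic cell list whose output is
tested for exact equality against brute force.

Two numerical choices matter:

* **Determinism** — the golden-spiral construction is a fixed function of
  the point count, so areas are bit-reproducible.
* **Canonical orientation** — a point lattice fixed in the laboratory
  frame makes areas drift by ~1–2 Å² when the complex is merely rotated.
  Coordinates are therefore rotated into a canonical frame (principal axes
  of the atom cloud; eigenvector signs fixed by the third central moment
  along each axis, +1 if it vanishes; third axis completing a right-handed
  frame) before the lattice is laid down. Surface areas are then invariant
  under rigid motion and atom reordering to floating-point precision. The
  construction degrades only for inputs with exactly degenerate principal
  axes or vanishing skewness (e.g. perfectly symmetric artificial
  clusters), where sign choices cannot track the rotation; real molecules
  are never symmetric to machine precision.

An independent cross-check, `sasa_quadrature()`, integrates the same
accessibility indicator on a latitude–longitude grid with cos(latitude)
weights (default 64 × 128 nodes). It shares neither point construction nor
integration rule with the production path; both are anchored to closed
forms (isolated sphere, two-sphere spherical-cap occlusion) and agree
within 2% on random clusters.

## Buried surface area and its chain-pair decomposition

The footprint is the one-sided ΔSASA of the antigen: SASA of the HLA side
alone minus its SASA in the complex. Both states are evaluated in a single
canonical frame from the union of atoms, so they share the identical
lattice and their difference is exact, not a difference of two noisy
estimates.

Published per-chain interface areas for antibody–antigen complexes are
typically additive — the α-chain/heavy, α-chain/light and β2m/heavy areas
sum to the total. A naive "ΔSASA induced by each antibody chain alone"
does not guarantee this (two antibody chains can shadow the same surface
patch). The decomposition here is therefore defined at the level of
individual lattice points: every antigen surface point accessible in the
antigen-alone state but occluded in the complex is attributed to the
antibody chain occluding it most deeply (ties to the first chain in
order). Pair areas then sum to the total footprint *by construction*, and
the total equals the one-sided ΔSASA exactly. The peptide is excluded from
the antigen side by default — a laterally binding alloantibody buries α
chain and β2m, not peptide — with a flag to include it.

The symmetric quantities (ΔSASA of the antibody side; the PISA-style
half-buried mean) are exposed for cross-checking but are not the headline
numbers.

## Contacts, hydrogen bonds, epitope segments, displacement

* **Contacts**: all cross-interface residue pairs with minimum heavy-atom
  distance ≤ cutoff (default 4.0 Å), classified as `salt_bridge`
  (formally charged side-chain groups of opposite sign in range), `hbond`,
  or `nonbonded`. Larger cutoffs strictly grow the contact set (tested).
* **Hydrogen bonds**: donor and acceptor heavy atoms from per-residue
  templates (backbone N donates except proline; backbone O always
  accepts; side-chain polar atoms per residue type). A bond requires
  donor–acceptor distance ≤ 3.5 Å (criteria must lie in (2.2, 4.0]) and a
  donor–acceptor–antecedent angle at the acceptor ≥ 90° — a heavy-atom
  proxy for hydrogen geometry, since no hydrogens are modeled. If the
  antecedent atom is missing from the model the bond is kept on distance
  alone. Bonds are deduplicated per donor–acceptor atom pair.
* **Epitope segments**: the α-chain epitope positions are partitioned into
  maximal runs where consecutive positions differ by at most the gap
  tolerance (default 3 — small numbering gaps inside one surface patch do
  not break a segment, while tens-of-residues gaps do). An empty contact
  set yields zero segments.
* **Backbone displacement**: after a Kabsch fit of unbound onto bound
  Cα atoms over a caller-chosen alignment range, the per-position Cα–Cα
  residual exposes local binding-induced conformational change. At least
  three shared alignment positions are required.

## Receptor co-engagement

Whether an antibody and a T-cell receptor, KIR, or CD8 can engage the same
HLA molecule simultaneously is assessed purely sterically: the receptor
complex is superposed onto the antibody complex via the shared α chain
(Kabsch on Cα atoms of the α1/α2 platform, default positions 1–180;
α-only rather than α+β2m because β2m's position varies more between
complexes — both are supported), and heavy-atom pairs between the Fab and
the receptor with van der Waals overlap `r_a + r_b − d` exceeding 0.4 Å
are counted as clashes — the common steric-clash convention. The Kabsch
implementation enforces a proper rotation (reflection corrected via the
SVD determinant) and rejects degenerate (collinear) point sets. Only the
~50 kDa Fab is modeled on the antibody side; whole-IgG geometry is out of
scope.

## Allele reactivity from the epitope

Panel sequences are assumed pre-aligned to mature α-chain numbering
(class-I α chains are length-conserved over the epitope region), so no
internal alignment is performed. For each allele, the residues at the
structurally derived epitope positions are compared with the immunizing
reference; each difference is classified by an ordered rule table:

1. `hbond_loss` — the reference residue is hydrogen-bonded across the
   interface and the variant cannot support the bond (loses polar
   chemistry or has a shorter side chain);
2. `charge_reversal` — formal side-chain charge flips sign;
3. `charge_to_hydrophobic` — a charged residue becomes hydrophobic;
4. `side_chain_truncation` — three or more side-chain heavy atoms lost;
5. `conservative` — anything else.

Predicted impact is `abrogating` for hydrogen-bond loss or a charge-class
change at a *critical* position (defaults {90, 14, 17}: the eplet position
and the charged heavy-chain anchors), `weakening` at a *weakening*
position (defaults {19, 39}), else `tolerated`. An allele is predicted
nonreactive iff it carries at least one abrogating substitution; weakening
changes leave it reactive (possibly at reduced signal) — this mapping is a
deliberate rule choice, overridable through `reactivity_rules()`. β2m is
monomorphic and takes no part in the rules. Observed classes come from
bead MFI at a threshold of 500 units, and concordance is reported as a
2×2 confusion table plus the discordant allele list. Prediction is a pure
function of epitope-position residues, and adding an abrogating
substitution can never flip a call back to reactive (both properties are
tested).

## 1:1 single-cycle kinetics

Within any phase at constant analyte concentration C, the 1:1 Langmuir
model has the closed-form solution

R(t) = R_eq + (R₀ − R_eq)·exp(−(ka·C + kd)·(t − t₀)),  R_eq = Rmax·C/(C + KD),

with pure exponential decay at C = 0. Sensorgrams are therefore simulated
as continuous piecewise exponentials (exact, no ODE integration), with
optional Gaussian noise under a caller seed. The default single-cycle
schedule uses five geometrically spaced injections from 2.5 to 20 nM
(ratio ≈ 1.68), 105 s each, followed by 600 s of dissociation — a
standard SCK titration design for nM-affinity IgG on a biosensor.

Fitting minimizes squared residuals of the piecewise model over
(ka, kd, Rmax), parameterized on the log scale (positivity without
constraints), by Levenberg–Marquardt with tight tolerances (ftol = ptol =
1e-15, so noiseless data are recovered to ~1e-6 relative). The automatic
initial guess takes kd from a log-linear regression of the final
dissociation tail and ka from the early association slope dR/dt ≈
ka·C·Rmax. A dissociation-only input is rejected: ka is unidentifiable
without an association phase. The equilibrium constant is always reported
as the ratio kd/ka. When a measured equilibrium estimate (e.g. from an
ELISA isotherm, signal = Bmax·C/(KD + C), fitted the same way) disagrees
with the rate ratio — a common situation for high-affinity interactions,
where both numbers strain the instruments — the package reports both
as-is and does not reconcile them.

## Cytotoxicity and exact statistics

Cytotoxicity % = (experimental − baseline)/(maximum − baseline) × 100,
taken on gated death fractions; values below baseline are reported
negative, and the ratio is invariant to a common rescaling of counts.
Gating itself is instrument- and operator-defined and is not reimplemented.

For the small replicate counts typical of these assays (N = 3–4), normal
approximations are meaningless, so the two-group comparison enumerates all
C(n₁+n₂, n₁) assignments of the combined mid-ranks — ties handled exactly
over the observed tie pattern — and doubles the smaller tail, capped at 1.
Complete separation at 4 vs 4 gives p = 2/70 ≈ 0.0286, and at 3 vs 3
p = 2/20 = 0.10: the attainable floors of the design. Above 20 combined
observations the tie-corrected normal approximation takes over and the
result is flagged non-exact. Kruskal–Wallis (tie-corrected H, chi-square
p) is delegated to `stats::kruskal.test()`; Dunn's pairwise z statistics
use the tie-corrected pooled variance (N(N+1)/12 − Σ(t³−t)/(12(N−1)))
(1/nᵢ + 1/nⱼ) with Bonferroni family-wise adjustment by default (the
correction family behind "Dunn's multiple comparison test" in common
software is not standardized; any `p.adjust` method is accepted).

## Synthetic data: what it emulates, what it does not

The generators produce every input class with known ground truth:

* **Toy complexes** — straight chains of idealized glycine-like residues
  (four heavy atoms on a fixed template; Cα atoms carry a per-residue z
  wiggle so chain traces are non-collinear and superposable), stacked at
  controlled gaps so the closest cross-chain approach is an O···N pair at
  exactly `gap − 1.23` Å with a ~112° acceptor angle. Contact and
  hydrogen-bond ground truth is closed-form; buried-area truth comes from
  the quadrature oracle. These validate geometry exactly but look nothing
  like folded proteins: no packing, no side chains, no burial gradients.
* **Allele panels** — a reference allele with a random background sequence
  carrying the canonical epitope-position residues (Arg14, Arg17, Glu19,
  Asp39, Asp90), variants with planted abrogating or weakening
  substitutions, an allele pair differing only at position 90 (plus one
  change outside the epitope), and MFI drawn from bands (0–400 nonreactive,
  600–20000 reactive) that straddle the 500 threshold with margin. Panel
  sequences are synthetic, not database alleles; concordance on them tests
  the logic, not real serology.
* **Sensorgrams and cytotoxicity tables** — exact model plus Gaussian
  noise; beta-distributed death fractions with disjoint ranges in the
  separation scenario (pinning the exact test to its boundary), identical
  distributions under the null, and four graded conditions in the
  subclass scenario. Real instrument noise is neither white nor Gaussian;
  passing recovery bounds here does not certify behavior on drifting
  baselines or mass-transport-limited data, which the 1:1 model excludes
  by assumption.

Everything is byte-deterministic in the seed.

## Problem sizes and runtime choices

The test suite and the acceptance script run on deliberately small
problems: toy complexes of 2–3 chains × 4–6 residues, 50 random clusters
of 5–10 atoms for the SASA cross-check, 20 noisy sensorgrams for recovery
statistics, 400–2000 simulations for the test-level checks. These sizes
keep the full suite under a minute while exercising every code path; the
same functions scale to full Fab–HLA complexes (~6,500 heavy atoms), where
a SASA evaluation takes on the order of a minute in pure R.

## Known limitations

* No energetics: the interface analysis is purely geometric — no
  electrostatics, no ΔΔG, no water-mediated bonds.
* Substitution rules are coarse-grained chemistry, not free-energy
  predictions; they encode the observed abrogation pattern class, not a
  general mutational scanner, and alleles absent from a panel are not
  modeled.
* The clash criterion ignores side-chain flexibility; a handful of
  nominal overlaps can vanish under minimal rearrangement.
* The 1:1 kinetic model excludes avidity of bivalent IgG and mass
  transport; rate constants from such data are effective parameters.
* Auto role assignment is length-based and refuses rather than guesses
  when lengths are ambiguous.
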