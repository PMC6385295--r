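two_residue_structure <- function(d) {
  # chain A: one carbonyl O; chain B: one amide N at distance d
  st <- as_structure(tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 1L), aa = "G",
    atom = c("O", "N"), element = c("O", "N"),
    x = c(0, d), y = 0, z = 0
  ))
  assign_roles(st, c(A = "hla_alpha", B = "fab_heavy"))
}

test_that("contacts respect the heavy-atom distance cutoff", {
  expect_equal(nrow(find_contacts(two_residue_structure(3.9), cutoff = 4.0)), 1)
  expect_equal(nrow(find_contacts(two_residue_structure(4.1), cutoff = 4.0)), 0)
})

test_that("cell-list neighbor search equals brute force exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:120, 1)
    xyz <- matrix(runif(3 * n, 0, sample(5:30, 1)), ncol = 3)
    cutoff <- runif(1, 1, 8)
    expect_identical(neighbor_pairs(xyz, cutoff)[, c("i", "j")],
                     brute_force_pairs(xyz, cutoff)[, c("i", "j")])
  }
})

test_that("contact sets are monotone in the cutoff", {
  toy <- make_toy_complex(n_res = 6, gaps = 4.5, compute_bsa = FALSE)
  key <- function(ct) paste(ct$chain_a, ct$resno_a, ct$chain_b, ct$resno_b)
  c1 <- find_contacts(toy$structure, "hla_alpha", "fab_heavy", cutoff = 3.5)
  c2 <- find_contacts(toy$structure, "hla_alpha", "fab_heavy", cutoff = 5.0)
  expect_true(all(key(c1) %in% key(c2)))
  h1 <- detect_hbonds(toy$structure, "hla_alpha", "fab_heavy",
                      hbond_criteria(max_distance = 3.3))
  h2 <- detect_hbonds(toy$structure, "hla_alpha", "fab_heavy",
                      hbond_criteria(max_distance = 3.5))
  expect_true(nrow(h1) <= nrow(h2))
})

test_that("hydrogen bonds require distance and acceptor-angle geometry", {
  # donor N approaching a carbonyl O along +y; antecedent C placed to set
  # the donor-acceptor-antecedent angle
  hb_case <- function(d, c_pos) {
    st <- as_structure(tibble::tibble(
      chain = c("A", "A", "B"), resno = c(1L, 1L, 1L), aa = "G",
      atom = c("O", "C", "N"), element = c("O", "C", "N"),
      x = c(0, c_pos[1], 0), y = c(0, c_pos[2], d), z = 0
    ))
    st <- assign_roles(st, c(A = "hla_alpha", B = "fab_heavy"))
    detect_hbonds(st, "hla_alpha", "fab_heavy")
  }
  expect_equal(nrow(hb_case(2.9, c(1.23, -0.8))), 1)   # angle ~ 123 deg
  expect_equal(nrow(hb_case(3.8, c(1.23, -0.8))), 0)   # beyond 3.5 A
  expect_equal(nrow(hb_case(2.9, c(0.3, 1.4))), 0)     # angle ~ 12 deg
})

test_that("hydrogen bonds deduplicate per donor-acceptor atom pair", {
  toy <- make_toy_complex(n_res = 4, gaps = 4.0, compute_bsa = FALSE)
  hb <- detect_hbonds(toy$structure, "hla_alpha", "fab_heavy")
  expect_equal(nrow(hb), nrow(dplyr::distinct(
    hb, donor_chain, donor_resno, donor_atom,
    acceptor_chain, acceptor_resno, acceptor_atom)))
  expect_equal(nrow(hb), 4)  # one planted O...N bond per aligned residue
})

test_that("buried surface area is zero for separated chains", {
  st <- assign_roles(atoms_structure(rbind(c(0, 0, 0), c(100, 0, 0)),
                                     chain = c("A", "B")),
                     c(A = "hla_alpha", B = "fab_heavy"))
  expect_equal(buried_surface_area(st, "hla_alpha", "fab_heavy"), 0)
  expect_error(buried_surface_area(st, "hla_alpha", "hla_alpha"), "disjoint")
})

test_that("pairwise decomposition sums to the total footprint by construction", {
  toy <- make_toy_complex(n_res = 5, gaps = c(4.0, 4.0))
  pair <- pairwise_bsa(toy$structure, c("hla_alpha", "b2m"), "fab_heavy")
  total <- buried_surface_area(toy$structure, c("hla_alpha", "b2m"),
                               "fab_heavy")
  expect_equal(sum(pair$bsa), attr(pair, "total_footprint"))
  expect_lt(abs(sum(pair$bsa) - total), 0.1)
  # quadrature-oracle ground truth from the generator
  expect_equal(total, toy$truth$total_bsa, tolerance = 0.02)
})

test_that("non-touching chain pairs get exactly zero buried area", {
  toy <- make_toy_complex(n_res = 5, gaps = c(100, 4.0))
  pair <- pairwise_bsa(toy$structure, c("hla_alpha", "b2m"), "fab_heavy")
  far <- pair$bsa[pair$role_a == "hla_alpha"]
  near <- pair$bsa[pair$role_a == "b2m"]
  expect_identical(far, 0)
  expect_gt(near, 0)
})

test_that("both one-sided buried areas and their PISA-style mean are exposed", {
  toy <- make_toy_complex(n_res = 5, gaps = 4.0, compute_bsa = FALSE)
  dA <- buried_surface_area(toy$structure, "hla_alpha", "fab_heavy")
  dB <- buried_surface_area(toy$structure, "fab_heavy", "hla_alpha")
  expect_gt(dA, 0)
  expect_gt(dB, 0)
  half <- (dA + dB) / 2
  expect_true(half >= min(dA, dB) && half <= max(dA, dB))
})

test_that("the footprint is invariant to rigid motion and chain order", {
  toy <- make_toy_complex(n_res = 4, gaps = 4.0, compute_bsa = FALSE)
  t1 <- buried_surface_area(toy$structure, "hla_alpha", "fab_heavy")
  moved <- rigid_move(toy$structure, random_rotation(3), c(11.3, -4.2, 7.9))
  t2 <- buried_surface_area(moved, "hla_alpha", "fab_heavy")
  expect_lt(abs(t1 - t2), 0.1)
  shuffled <- dplyr::arrange(toy$structure, dplyr::desc(chain), resno)
  class(shuffled) <- class(toy$structure)
  t3 <- buried_surface_area(shuffled, "hla_alpha", "fab_heavy")
  expect_lt(abs(t1 - t3), 0.1)
})

test_that("epitope segmentation merges runs within the gap tolerance", {
  fake_contacts <- function(positions) {
    tibble::tibble(chain_a = "A", resno_a = as.integer(positions),
                   aa_a = "A", role_a = "hla_alpha",
                   chain_b = "H", resno_b = 1L, aa_b = "G",
                   role_b = "fab_heavy", min_dist = 3.5, kind = "nonbonded")
  }
  fp <- epitope_footprint(fake_contacts(c(14, 16, 17, 18, 19, 39, 90)))
  expect_equal(nrow(fp$segments), 3)
  expect_equal(fp$segments$start, c(14, 39, 90))
  expect_equal(fp$segments$end, c(19, 39, 90))
  expect_equal(nrow(epitope_footprint(fake_contacts(10))$segments), 1)
  empty <- epitope_footprint(fake_contacts(integer(0)))
  expect_equal(nrow(empty$segments), 0)
  expect_equal(nrow(empty$epitope), 0)
  # with a generous tolerance the 19 -> 39 gap still splits, 14..19 merges
  fp2 <- epitope_footprint(fake_contacts(c(14, 18, 19, 39, 90)),
                           gap_tolerance = 4)
  expect_equal(nrow(fp2$segments), 3)
})

test_that("every epitope residue appears in at least one contact", {
  toy <- make_toy_complex(n_res = 5, gaps = 4.0, compute_bsa = FALSE)
  ct <- find_contacts(toy$structure, "hla_alpha", "fab_heavy")
  fp <- epitope_footprint(ct)
  expect_true(all(paste(fp$epitope$chain, fp$epitope$position) %in%
                    paste(ct$chain_a, ct$resno_a)))
})

test_that("per-residue displacement recovers a planted local shift", {
  bound <- assign_roles(ca_chain(10:30), c(A = "hla_alpha"))
  expect_equal(max(residue_displacement(bound, bound)$displacement), 0,
               tolerance = 1e-9)
  shifted <- bound
  sel <- shifted$resno == 17
  shifted$z[sel] <- shifted$z[sel] + 2
  disp <- residue_displacement(bound, shifted,
                               align_on = setdiff(10:30, 16:19))
  expect_equal(disp$displacement[disp$position == 17], 2, tolerance = 1e-6)
  expect_lt(max(disp$displacement[!disp$position %in% 16:19]), 1e-6)
  expect_error(residue_displacement(bound, shifted, align_on = 10:11),
               "Fewer than 3")
})
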