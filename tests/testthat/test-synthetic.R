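test_that("toy complexes reproduce their planted contact ground truth", {
  for (gap in c(3.6, 4.0, 4.6)) {
    toy <- make_toy_complex(n_res = 5, gaps = gap, compute_bsa = FALSE)
    ct <- find_contacts(toy$structure, "hla_alpha", "fab_heavy", cutoff = 4.0)
    truth <- toy$truth$contacts
    expect_setequal(paste(ct$resno_a, ct$resno_b),
                    paste(truth$resno_a, truth$resno_b))
    got <- dplyr::arrange(ct, resno_a, resno_b)$min_dist
    want <- dplyr::arrange(truth, resno_a, resno_b)$min_dist
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("toy complexes reproduce their planted hydrogen bonds", {
  toy <- make_toy_complex(n_res = 6, gaps = 4.5, compute_bsa = FALSE)
  hb <- detect_hbonds(toy$structure, "hla_alpha", "fab_heavy")
  truth <- toy$truth$hbonds
  expect_equal(nrow(hb), nrow(truth))
  expect_setequal(hb$acceptor_resno, truth$position)
  expect_equal(sort(unique(hb$dist)), sort(unique(truth$dist)),
               tolerance = 1e-9)
  # widen the gap beyond the donor-acceptor cutoff: no bonds planted or found
  far <- make_toy_complex(n_res = 6, gaps = 4.9, compute_bsa = FALSE)
  expect_equal(nrow(far$truth$hbonds), 0)
  expect_equal(nrow(detect_hbonds(far$structure, "hla_alpha", "fab_heavy")), 0)
})

test_that("separated toy chains have no contacts and zero buried area", {
  toy <- make_toy_complex(n_res = 5, gaps = 100)
  expect_equal(nrow(toy$truth$contacts), 0)
  expect_equal(toy$truth$total_bsa, 0, tolerance = 1e-9)
  expect_equal(nrow(find_contacts(toy$structure, "hla_alpha", "fab_heavy")), 0)
})

test_that("toy generation is seed-free deterministic and writable as PDB", {
  t1 <- make_toy_complex(n_res = 4, gaps = 4.0, compute_bsa = FALSE)
  t2 <- make_toy_complex(n_res = 4, gaps = 4.0, compute_bsa = FALSE)
  expect_identical(as.data.frame(t1$structure), as.data.frame(t2$structure))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(t1$structure, p)
  back <- read_structure(p)
  expect_equal(nrow(back), nrow(t1$structure))
  expect_error(make_toy_complex(gaps = 1.0), "gaps")
})

test_that("allele panels plant variants consistent with their truth labels", {
  gen <- make_allele_panel(seed = 7)
  pred <- predict_reactivity(gen$panel, gen$reference, gen$epitope_positions,
                             gen$hbonded_positions)
  joined <- dplyr::inner_join(pred, gen$truth, by = "allele")
  expect_equal(joined$predicted, joined$label)
  # MFI bands straddle the threshold: concordance is 100% by construction
  conc <- evaluate_concordance(pred, gen$panel)
  expect_equal(conc$confusion$concordance, 1)
  expect_equal(nrow(conc$discordant), 0)
  # and at any threshold between the bands
  for (thr in c(450, 500, 550)) {
    cc <- evaluate_concordance(pred, gen$panel,
                               reactivity_rules(mfi_threshold = thr))
    expect_equal(cc$confusion$concordance, 1)
  }
})

test_that("panels with no planted variants are wholly reactive", {
  gen <- make_allele_panel(n_abrogating = 0, n_weakening = 0,
                           include_position90_pair = FALSE, seed = 2)
  pred <- predict_reactivity(gen$panel, gen$reference, gen$epitope_positions,
                             gen$hbonded_positions)
  expect_true(all(pred$predicted == "reactive"))
})

test_that("panel generation is byte-deterministic in the seed", {
  g1 <- make_allele_panel(seed = 11)
  g2 <- make_allele_panel(seed = 11)
  g3 <- make_allele_panel(seed = 12)
  expect_identical(g1$panel, g2$panel)
  expect_false(identical(g1$panel$mfi, g3$panel$mfi))
})

test_that("sensorgram sets are reproducible by seed with attached truth", {
  s1 <- make_sensorgram_set(1e5, 3e-4, 100, noise_sd = 1, n_seeds = 3,
                            base_seed = 5)
  s2 <- make_sensorgram_set(1e5, 3e-4, 100, noise_sd = 1, n_seeds = 3,
                            base_seed = 5)
  expect_identical(s1$sensorgram[[2]]$response, s2$sensorgram[[2]]$response)
  expect_equal(attr(s1, "params"), c(ka = 1e5, kd = 3e-4, Rmax = 100))
  expect_false(identical(s1$sensorgram[[1]]$response,
                         s1$sensorgram[[2]]$response))
})

test_that("the separation scenario pins the exact test at its boundary", {
  tab <- make_cytotox_experiment("separation", n_replicates = 4, seed = 21) |>
    cytotoxicity()
  p <- exact_mann_whitney(tab$cytotoxicity[tab$condition == "treated"],
                          tab$cytotoxicity[tab$condition == "isotype"])$p_value
  expect_equal(p, 2 / 70)
  expect_error(make_cytotox_experiment("separation", n_replicates = 1),
               "at least 2")
})

test_that("null-scenario rejection rate sits at the attainable level", {
  rej <- purrr::map_lgl(1:400, function(s) {
    tab <- make_cytotox_experiment("null", n_replicates = 4, seed = s) |>
      cytotoxicity()
    exact_mann_whitney(tab$cytotoxicity[tab$condition == "treated"],
                       tab$cytotoxicity[tab$condition == "isotype"])$p_value <= 0.05
  })
  attainable <- 2 / 70
  se <- sqrt(attainable * (1 - attainable) / length(rej))
  expect_lte(mean(rej), 0.05)
  expect_lt(abs(mean(rej) - attainable), 3 * se + 0.01)
})

test_that("the subclass scenario yields four graded conditions", {
  tab <- make_cytotox_experiment("subclasses", seed = 3) |> cytotoxicity()
  expect_setequal(unique(tab$condition), c("IgG1", "IgG2", "IgG3", "IgG4"))
  means <- tapply(tab$cytotoxicity, tab$condition, mean)
  expect_lt(means[["IgG4"]], means[["IgG1"]])
  res <- kruskal_wallis(tab, value = "cytotoxicity", group = "condition")
  expect_lt(res$p_value, 0.05)
  dunn <- dunns_test(tab, value = "cytotoxicity", group = "condition")
  expect_equal(nrow(dunn), 6)
})
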