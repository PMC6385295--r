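PAPER_KA <- 1.04e5
PAPER_KD <- 3.3e-4

test_that("KD is the ratio of the rate constants", {
  expect_equal(kd_from_rates(1e5, 1e-4), 1e-9)
  expect_equal(kd_from_rates(PAPER_KA, PAPER_KD), PAPER_KD / PAPER_KA)
  expect_equal(kd_from_rates(2e5, 0), 0)
  expect_error(kd_from_rates(0, 1e-4), "positive")
})

test_that("association approaches the Langmuir steady state", {
  sched <- sck_schedule(concentrations = 5e-9, injection_time = 2e5,
                        dissociation_time = 10)
  sg <- simulate_sck(ka = 1e5, kd = 3e-4, Rmax = 100, schedule = sched,
                     sampling_rate = 0.01)
  KD <- 3e-4 / 1e5
  req <- 100 * 5e-9 / (5e-9 + KD)
  plateau <- sg$response[sg$time == 2e5]
  expect_equal(plateau, req, tolerance = 1e-3)
  # kd = 0 at C >> KD saturates monotonically to Rmax
  sg0 <- simulate_sck(ka = 1e6, kd = 0, Rmax = 100,
                      schedule = sck_schedule(1e-6, 5000, 10),
                      sampling_rate = 0.1)
  expect_true(all(diff(sg0$response) >= -1e-12))
  expect_equal(max(sg0$response), 100, tolerance = 1e-3)
})

test_that("dissociation half-life equals ln(2)/kd analytically", {
  half <- log(2) / PAPER_KD  # about 2100 s
  # drive the association to steady state R_eq = 100, then release
  conc <- 1e-8
  KD <- PAPER_KD / PAPER_KA
  rmax <- 100 * (conc + KD) / conc
  sched <- tibble::tibble(phase = c(1L, 2L),
                          start = c(0, 1e6), end = c(1e6, 1e6 + 3 * half),
                          conc = c(conc, 0))
  r <- sck_response(1e6 + c(0, half, 2100), PAPER_KA, PAPER_KD, rmax, sched)
  expect_equal(r[1], 100, tolerance = 1e-6)
  expect_equal(r[2], 50, tolerance = 1e-6)
  expect_equal(r[3], 100 * exp(-PAPER_KD * 2100), tolerance = 1e-9)
  expect_equal(r[3], 50.0, tolerance = 1e-3)
})

test_that("simulated sensorgrams are continuous across phase boundaries", {
  sched <- sck_schedule()
  sg <- simulate_sck(PAPER_KA, PAPER_KD, 120, sched, sampling_rate = 10)
  for (b in sched$start[-1]) {
    left <- sck_response(b - 1e-10, PAPER_KA, PAPER_KD, 120, sched)
    right <- sck_response(b + 1e-10, PAPER_KA, PAPER_KD, 120, sched)
    expect_lt(abs(left - right), 1e-9)
  }
  expect_true(all(is.finite(sg$response)))
  # stepwise-rising association, slow decay after the last injection
  last_assoc <- max(sched$start)
  expect_gt(sg$response[sg$time == last_assoc], 0)
  diss <- sg$response[sg$time >= last_assoc]
  expect_true(all(diff(diss) <= 1e-9))
})

test_that("noiseless parameter recovery is exact to 1e-6 relative", {
  sg <- simulate_sck(PAPER_KA, PAPER_KD, 90, sck_schedule(), noise_sd = 0)
  fit <- fit_sck(sg)
  expect_equal(unname(fit$estimate["ka"]), PAPER_KA, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["kd"]), PAPER_KD, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["Rmax"]), 90, tolerance = 1e-6)
  expect_equal(fit$KD, PAPER_KD / PAPER_KA, tolerance = 1e-6)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "KD"], fit$KD)
  expect_true(glance(fit)$converged)
})

test_that("rates are recovered within 5% median error at 1% noise", {
  rmax <- 100
  set <- make_sensorgram_set(PAPER_KA, PAPER_KD, rmax,
                             noise_sd = 0.01 * rmax, n_seeds = 20,
                             base_seed = 101)
  errs <- purrr::map_dfr(set$sensorgram, function(sg) {
    fit <- fit_sck(sg)
    tibble::tibble(ka = abs(fit$estimate["ka"] - PAPER_KA) / PAPER_KA,
                   kd = abs(fit$estimate["kd"] - PAPER_KD) / PAPER_KD)
  })
  expect_lt(median(errs$ka), 0.05)
  expect_lt(median(errs$kd), 0.05)
})

test_that("dissociation-only sensorgrams are rejected as unidentifiable", {
  sched <- tibble::tibble(phase = 1L, start = 0, end = 600, conc = 0)
  sg <- simulate_sck(1e5, 3e-4, 100, sched)
  expect_error(fit_sck(sg), "unidentifiable")
  expect_error(simulate_sck(1e5, 3e-4, 100,
                            tibble::tibble(phase = 1L, start = 0, end = 10,
                                           conc = -1e-9)),
               "Negative")
})

test_that("Langmuir isotherm fits recover exact synthetic titrations", {
  conc <- c(0.05, 0.2, 0.5, 1, 2, 5, 20) * 1e-9
  sig <- 2.0 * conc / (1e-9 + conc)
  fit <- fit_langmuir(tibble::tibble(concentration = conc, signal = sig))
  expect_equal(unname(fit$estimate["KD"]), 1e-9, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["Bmax"]), 2.0, tolerance = 1e-6)
  # half-saturation at C = KD
  half <- 2.0 * 1e-9 / (1e-9 + 1e-9)
  expect_equal(half, 2.0 / 2)
  expect_error(fit_langmuir(tibble::tibble(concentration = conc,
                                           signal = rep(1, 7))),
               "unidentifiable")
  expect_error(fit_langmuir(tibble::tibble(concentration = c(1e-9, 1e-9, 1e-9),
                                           signal = c(1, 1.1, 1.2))),
               "distinct")
})

test_that("noisy Langmuir titrations recover KD within 10% median error", {
  conc <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8, 20) * 1e-9
  errs <- purrr::map_dbl(1:20, function(seed) {
    set.seed(seed)
    sig <- 2.0 * conc / (1e-9 + conc) * (1 + rnorm(length(conc), 0, 0.05))
    fit <- fit_langmuir(tibble::tibble(concentration = conc, signal = sig))
    abs(fit$estimate["KD"] - 1e-9) / 1e-9
  })
  expect_lt(median(errs), 0.10)
})

test_that("sensorgram and fit autoplots build without error", {
  sg <- simulate_sck(PAPER_KA, PAPER_KD, 90, sck_schedule(), noise_sd = 0.5,
                     seed = 1)
  expect_s3_class(autoplot(sg), "ggplot")
  expect_s3_class(autoplot(fit_sck(sg)), "ggplot")
  conc <- c(0.1, 0.5, 1, 2, 5) * 1e-9
  lf <- fit_langmuir(tibble::tibble(concentration = conc,
                                    signal = 2 * conc / (1e-9 + conc)))
  expect_s3_class(autoplot(lf), "ggplot")
})
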