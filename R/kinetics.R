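# 1:1 Langmuir binding kinetics: closed-form piecewise simulation of
# single-cycle-kinetics (SCK) sensorgrams, nonlinear least-squares recovery of
# (ka, kd, Rmax), and equilibrium affinity from saturation-binding isotherms.

#' Single-cycle-kinetics injection schedule
#'
#' Contiguous association phases at non-decreasing analyte concentrations
#' followed by one dissociation phase at zero concentration, mirroring an SCK
#' titration (sequential injections without regeneration).
#'
#' @param concentrations Analyte concentrations in M, one per injection,
#'   non-decreasing. Default: five geometric steps from 2.5 to 20 nM.
#' @param injection_time Duration of each injection, s (default 105).
#' @param dissociation_time Final buffer phase, s (default 600).
#' @return Tibble with columns `phase`, `start`, `end`, `conc`.
#' @export
sck_schedule <- function(concentrations = 2.5e-9 * (20 / 2.5)^(0:4 / 4),
                         injection_time = 105, dissociation_time = 600) {
  if (any(concentrations < 0)) abort("Negative analyte concentration.")
  if (is.unsorted(concentrations)) {
    abort("SCK concentrations must be non-decreasing.")
  }
  n <- length(concentrations)
  starts <- (seq_len(n) - 1) * injection_time
  tibble(
    phase = c(seq_len(n), n + 1L),
    start = c(starts, n * injection_time),
    end = c(starts + injection_time, n * injection_time + dissociation_time),
    conc = c(concentrations, 0)
  )
}

#' Noise-free 1:1 response at given times
#'
#' Evaluates the closed-form piecewise-exponential solution of the 1:1
#' Langmuir model over a schedule: within a phase at concentration C the
#' response relaxes toward `Rmax * C / (C + KD)` with observed rate
#' `ka * C + kd` (pure exponential decay at C = 0), continuous across phase
#' boundaries.
#'
#' @param time Numeric vector of times (s) within the schedule span.
#' @param ka Association rate constant, 1/(M s).
#' @param kd Dissociation rate constant, 1/s.
#' @param Rmax Saturation response, instrument units.
#' @param schedule Tibble from [sck_schedule()].
#' @return Numeric response vector.
#' @export
sck_response <- function(time, ka, kd, Rmax, schedule) {
  resp <- numeric(length(time))
  r0 <- 0
  for (p in seq_len(nrow(schedule))) {
    c_p <- schedule$conc[p]
    t0 <- schedule$start[p]
    kobs <- ka * c_p + kd
    req <- if (c_p > 0) Rmax / (1 + kd / (ka * c_p))
           else if (kd > 0) 0 else r0
    in_phase <- time >= t0 &
      (time < schedule$end[p] | p == nrow(schedule))
    dt <- time[in_phase] - t0
    resp[in_phase] <- req + (r0 - req) * exp(-kobs * dt)
    span <- schedule$end[p] - t0
    r0 <- req + (r0 - req) * exp(-kobs * span)
  }
  resp
}

#' Simulate a single-cycle-kinetics sensorgram
#'
#' @inheritParams sck_response
#' @param sampling_rate Samples per second (default 1).
#' @param noise_sd Standard deviation of additive Gaussian noise, instrument
#'   units (0 gives the noiseless curve).
#' @param seed Optional integer seed for the noise.
#' @return Tibble of class `allo_sensorgram` with columns `time`, `response`;
#'   the schedule and true parameters are attached as attributes.
#' @export
simulate_sck <- function(ka, kd, Rmax, schedule = sck_schedule(),
                         sampling_rate = 1, noise_sd = 0, seed = NULL) {
  stopifnot(ka > 0, kd >= 0, Rmax > 0, sampling_rate > 0)
  if (any(schedule$conc < 0)) abort("Negative analyte concentration.")
  time <- seq(min(schedule$start), max(schedule$end), by = 1 / sampling_rate)
  response <- sck_response(time, ka, kd, Rmax, schedule)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    response <- response + rnorm(length(time), 0, noise_sd)
  }
  out <- tibble(time = time, response = response)
  attr(out, "schedule") <- schedule
  attr(out, "params") <- c(ka = ka, kd = kd, Rmax = Rmax)
  class(out) <- c("allo_sensorgram", class(out))
  out
}

#' Fit 1:1 kinetics to an SCK sensorgram
#'
#' Nonlinear least squares over (ka, kd, Rmax), parameterized on the log
#' scale, minimizing squared residuals of the piecewise 1:1 model
#' (Levenberg-Marquardt). The automatic initial guess takes kd from a
#' log-linear regression of the dissociation tail and ka from the initial
#' association slope `dR/dt ~ ka * C * Rmax`.
#'
#' @param sensorgram Tibble with columns `time`, `response` (an
#'   `allo_sensorgram` or equivalent).
#' @param schedule Injection schedule; defaults to the one attached to the
#'   sensorgram.
#' @param start `"auto"` or a named vector `c(ka=, kd=, Rmax=)`.
#' @return Object of class `sck_fit` supporting [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_sck <- function(sensorgram, schedule = NULL, start = "auto") {
  schedule <- schedule %||% attr(sensorgram, "schedule")
  if (is.null(schedule)) abort("No injection schedule supplied.")
  assoc <- schedule[schedule$conc > 0, ]
  if (nrow(assoc) == 0) {
    abort("Dissociation-only input: ka unidentifiable.")
  }
  t <- sensorgram$time
  r <- sensorgram$response
  if (identical(start, "auto")) {
    # kd from log-linear decay of the final dissociation tail
    dis <- schedule[nrow(schedule), ]
    tail_sel <- t >= dis$start & r > 0
    kd0 <- if (sum(tail_sel) >= 3) {
      fit <- lm(log(r[tail_sel]) ~ t[tail_sel])
      max(1e-6, -coef(fit)[2])
    } else 1e-3
    rmax0 <- 2 * max(r)
    first <- schedule[1, ]
    early <- t >= first$start & t <= first$start + 0.2 * (first$end - first$start)
    slope <- if (sum(early) >= 2) {
      coef(lm(r[early] ~ t[early]))[2]
    } else NA_real_
    ka0 <- if (is.finite(slope) && slope > 0) {
      slope / (first$conc * rmax0)
    } else 1e5
    start <- c(ka = unname(ka0), kd = unname(kd0), Rmax = unname(rmax0))
  }
  resid_fn <- function(logp) {
    logp <- pmin(pmax(logp, -60), 60)  # keep rates finite during line search
    r - sck_response(t, exp(logp[1]), exp(logp[2]), exp(logp[3]), schedule)
  }
  fit <- minpack.lm::nls.lm(
    par = log(unname(start[c("ka", "kd", "Rmax")])),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (fit$info == 0 || fit$info == 9) {
    abort(paste0("SCK fit did not converge (info ", fit$info,
                 "); last iterate ka=", signif(exp(fit$par[1]), 4),
                 " kd=", signif(exp(fit$par[2]), 4)))
  }
  est <- exp(fit$par)
  names(est) <- c("ka", "kd", "Rmax")
  structure(list(
    estimate = est,
    KD = unname(est["kd"] / est["ka"]),
    rss = sum(fit$fvec^2),
    n = length(t),
    convergence_info = fit$info,
    data = tibble(time = t, response = r,
                  fitted = sck_response(t, est["ka"], est["kd"], est["Rmax"],
                                        schedule)),
    schedule = schedule
  ), class = "sck_fit")
}

#' @export
print.sck_fit <- function(x, ...) {
  cat("<sck_fit> ka = ", signif(x$estimate["ka"], 4),
      " /M/s, kd = ", signif(x$estimate["kd"], 4),
      " /s, KD = ", signif(x$KD, 4), " M (Rmax = ",
      signif(x$estimate["Rmax"], 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_sck
#' @param x An `sck_fit` object.
#' @param ... Unused.
#' @export
tidy.sck_fit <- function(x, ...) {
  tibble(term = c("ka", "kd", "Rmax", "KD"),
         estimate = c(unname(x$estimate), x$KD),
         unit = c("1/(M s)", "1/s", "RU", "M"))
}

#' @rdname fit_sck
#' @export
glance.sck_fit <- function(x, ...) {
  tibble(KD = x$KD, rss = x$rss, sigma = sqrt(x$rss / x$n), n = x$n,
         converged = TRUE)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate constant, 1/(M s); must be positive.
#' @param kd Dissociation rate constant, 1/s.
#' @return KD = kd / ka, in M.
#' @export
kd_from_rates <- function(ka, kd) {
  if (any(ka <= 0)) abort("ka must be positive.")
  kd / ka
}

#' Fit a Langmuir saturation isotherm
#'
#' Least-squares fit of `signal = Bmax * C / (KD + C)` to an equilibrium
#' titration (e.g. an ELISA dilution series), initialized at `Bmax =
#' max(signal)` and `KD =` the concentration nearest half-saturation.
#'
#' @param data Data frame with columns `concentration` (M) and `signal`.
#' @return Object of class `langmuir_fit` supporting [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_langmuir <- function(data) {
  stopifnot(all(c("concentration", "signal") %in% names(data)))
  conc <- data$concentration
  sig <- data$signal
  if (length(unique(conc)) < 3) abort("Need >= 3 distinct concentrations.")
  if (diff(range(sig)) == 0) abort("All signals equal: KD unidentifiable.")
  bmax0 <- max(sig)
  kd0 <- conc[which.min(abs(sig - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- median(conc[conc > 0])
  fit <- minpack.lm::nlsLM(
    signal ~ Bmax * concentration / (KD + concentration),
    data = tibble(concentration = conc, signal = sig),
    start = list(Bmax = bmax0, KD = kd0),
    lower = c(Bmax = 0, KD = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  est <- coef(fit)
  structure(list(
    estimate = c(KD = unname(est["KD"]), Bmax = unname(est["Bmax"])),
    rss = sum(stats::resid(fit)^2),
    n = length(conc),
    data = tibble(concentration = conc, signal = sig,
                  fitted = stats::fitted(fit))
  ), class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("<langmuir_fit> KD = ", signif(x$estimate["KD"], 4), " M, Bmax = ",
      signif(x$estimate["Bmax"], 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_langmuir
#' @param x A `langmuir_fit` object.
#' @param ... Unused.
#' @export
tidy.langmuir_fit <- function(x, ...) {
  tibble(term = c("KD", "Bmax"), estimate = unname(x$estimate),
         unit = c("M", "signal"))
}

#' @rdname fit_langmuir
#' @export
glance.langmuir_fit <- function(x, ...) {
  tibble(KD = unname(x$estimate["KD"]), rss = x$rss,
         sigma = sqrt(x$rss / x$n), n = x$n)
}
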