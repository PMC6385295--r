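# Cytotoxicity percentages from gated dead/dying fractions and the
# nonparametric statistics used for small-replicate cytotoxicity designs:
# an exact (full-enumeration) two-tailed Mann-Whitney test, Kruskal-Wallis
# with the chi-square approximation, and Dunn's pairwise comparisons.

#' Specific cytotoxicity percentage
#'
#' `(experimental - baseline) / (maximum - baseline) * 100`, the standard
#' normalization of cell death against the spontaneous (baseline) and total
#' (maximum, e.g. detergent) lysis controls. Negative values (experimental
#' death below baseline) are reported as-is.
#'
#' @param experimental,baseline,maximum Death fractions in `[0, 1]`
#'   (vectorized).
#' @return Percentage vector.
#' @export
#' @examples
#' cytotoxicity_percent(0.30, 0.10, 0.90)  # 25
cytotoxicity_percent <- function(experimental, baseline, maximum) {
  if (any(maximum <= baseline)) {
    abort("Maximum cell death must exceed baseline cell death.")
  }
  (experimental - baseline) / (maximum - baseline) * 100
}

#' Add cytotoxicity percentages to a replicate table
#'
#' @param data Data frame with columns `experimental`, `baseline`, `maximum`
#'   (death fractions per replicate).
#' @return `data` with an added `cytotoxicity` column (percent).
#' @export
cytotoxicity <- function(data) {
  stopifnot(all(c("experimental", "baseline", "maximum") %in% names(data)))
  mutate(as_tibble(data),
         cytotoxicity = cytotoxicity_percent(.data$experimental,
                                             .data$baseline, .data$maximum))
}

#' Exact two-tailed Mann-Whitney test by full enumeration
#'
#' Enumerates all `choose(n1 + n2, n1)` assignments of the combined mid-ranks
#' to the first sample (so ties are handled exactly over the observed tie
#' pattern) and computes the two-tailed p as `min(1, 2 * min(P(U <= u),
#' P(U >= u)))` -- the doubled-one-tail convention under which complete
#' separation at 4 vs 4 gives p = 2/70 = 0.0286. Above `exact_limit` combined
#' observations the tie-corrected normal approximation is used and the
#' `exact` flag is `FALSE`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_limit Largest `n1 + n2` for full enumeration (default 20).
#' @return One-row tibble: `statistic` (U of `x`), `p_value`, `method`,
#'   `exact`, `n1`, `n2`.
#' @export
#' @examples
#' exact_mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_value  # 2/70
exact_mann_whitney <- function(x, y, exact_limit = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  if (n <= exact_limit) {
    idx <- combn(n, n1)
    u_all <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(u_all <= u_obs + eps)
    p_ge <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
    method <- "Exact two-tailed Mann-Whitney (full enumeration)"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
    method <- "Mann-Whitney (normal approximation, tie corrected)"
  }
  tibble(statistic = u_obs, p_value = p, method = method, exact = exact,
         n1 = n1, n2 = n2)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation for the
#' p-value (the "Gaussian approximated" p reported by common statistics
#' software), delegated to [stats::kruskal.test()]. Returns p = 1 when all
#' values are identical.
#'
#' @param data Data frame in long format.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- factor(data[[group]])
  stopifnot(nlevels(g) >= 2, all(table(g) >= 1))
  if (diff(range(v)) == 0) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                  method = "Kruskal-Wallis rank sum test"))
  }
  kt <- stats::kruskal.test(v, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Dunn's pairwise multiple-comparison test
#'
#' Post-hoc pairwise z statistics on mean ranks after a Kruskal-Wallis test,
#' with the tie-corrected pooled variance
#' `(N(N+1)/12 - T) * (1/ni + 1/nj)` where `T = sum(t^3 - t) / (12 (N - 1))`,
#' and family-wise adjustment of the two-sided p-values (default Bonferroni
#' over all pairs; any [stats::p.adjust()] method is accepted).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiple-comparison adjustment method (default
#'   `"bonferroni"`).
#' @return Tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunns_test <- function(data, value = "value", group = "group",
                       adjust = "bonferroni") {
  v <- data[[value]]
  g <- factor(data[[group]])
  n_tot <- length(v)
  rk <- rank(v)
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lv <- levels(g)
  pairs <- combn(lv, 2)
  all_tied <- diff(range(v)) == 0
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (all_tied || se == 0) 0 else
      (mean_rank[[a]] - mean_rank[[b]]) / se
    tibble(group1 = a, group2 = b, z = z,
           p_value = min(1, 2 * pnorm(-abs(z))))
  })
  mutate(out, p_adjusted = stats::p.adjust(.data$p_value, method = adjust))
}
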