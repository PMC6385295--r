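test_that("cytotoxicity percentage normalizes against the lysis controls", {
  expect_equal(cytotoxicity_percent(0.30, 0.10, 0.90), 25)
  expect_equal(cytotoxicity_percent(0.10, 0.10, 0.90), 0)
  expect_equal(cytotoxicity_percent(0.90, 0.10, 0.90), 100)
  expect_equal(cytotoxicity_percent(0.05, 0.10, 0.90), -6.25)  # reported as-is
  expect_error(cytotoxicity_percent(0.3, 0.5, 0.5), "exceed")
  tab <- cytotoxicity(tibble::tibble(experimental = c(0.3, 0.5),
                                     baseline = 0.1, maximum = 0.9))
  expect_equal(tab$cytotoxicity, c(25, 50))
})

test_that("cytotoxicity is invariant to a common count rescaling", {
  # fractions derived from counts scale out of the ratio
  counts <- c(experimental = 300, baseline = 100, maximum = 900)
  for (total in c(1000, 5000, 12345)) {
    f <- counts / total
    expect_equal(unname(cytotoxicity_percent(f[1], f[2], f[3])), 25)
  }
})

test_that("complete separation at 4 vs 4 gives the exact p of 2/70", {
  res <- exact_mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 70)
  expect_equal(round(res$p_value, 4), 0.0286)
  # direction-symmetric
  res2 <- exact_mann_whitney(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(res2$p_value, 2 / 70)
})

test_that("complete separation at 3 vs 3 gives the exact p of 0.10", {
  res <- exact_mann_whitney(c(10, 11, 12), c(20, 21, 22))
  expect_equal(res$p_value, 2 / 20)
  expect_equal(res$p_value, 0.10)
})

test_that("maximal ties give p = 1", {
  res <- exact_mann_whitney(rep(5, 4), rep(5, 4))
  expect_equal(res$p_value, 1)
})

test_that("exact enumeration matches the tie-free distribution oracle", {
  # wilcox.test's exact p (valid without ties) as the independent oracle
  for (seed in 1:15) {
    set.seed(seed)
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous, no ties
    ours <- exact_mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("tied samples agree with a permutation oracle", {
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 3, 4)
  ours <- exact_mann_whitney(x, y)
  # independent oracle: direct enumeration over value permutations
  pooled <- c(x, y)
  idx <- combn(8, 4)
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(x, y)
  u_all <- apply(idx, 2, function(s) u_of(pooled[s], pooled[-s]))
  p_ref <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                          mean(u_all >= u_obs - 1e-9)))
  expect_equal(ours$p_value, p_ref, tolerance = 1e-12)
  expect_true(ours$exact)
})

test_that("enumeration matches a win-counting oracle across size pairs", {
  # independent oracle: U as pairwise win count (+ half-wins for ties),
  # enumerated over all assignments -- no ranks involved
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  set.seed(31)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- sample(1:4, n1, replace = TRUE)  # tie-rich integer data
    y <- sample(1:4, n2, replace = TRUE)
    pooled <- c(x, y)
    idx <- combn(n1 + n2, n1)
    u_obs <- u_of(x, y)
    u_all <- apply(idx, 2, function(s) u_of(pooled[s], pooled[-s]))
    p_ref <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                            mean(u_all >= u_obs - 1e-9)))
    expect_equal(exact_mann_whitney(x, y)$p_value, p_ref, tolerance = 1e-12)
  }
})

test_that("large samples fall back to the normal approximation", {
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15, 1)
  res <- exact_mann_whitney(x, y)
  expect_false(res$exact)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 0.05)
})

test_that("the exact test holds its level under the null", {
  # attainable level at alpha = 0.05 for 4 vs 4 is P(U in {0,16}) = 2/70
  set.seed(99)
  n_sim <- 2000
  rej <- 0
  for (k in seq_len(n_sim)) {
    x <- rnorm(4); y <- rnorm(4)
    if (exact_mann_whitney(x, y)$p_value <= 0.05) rej <- rej + 1
  }
  attainable <- 2 / 70
  se <- sqrt(attainable * (1 - attainable) / n_sim)
  expect_lte(rej / n_sim, 0.05)
  expect_lt(abs(rej / n_sim - attainable), 3 * se + 1e-9)
})

test_that("Kruskal-Wallis H matches direct rank-sum arithmetic", {
  df <- tibble::tibble(value = c(1, 2, 3, 4, 5, 6),
                       group = rep(c("a", "b", "c"), each = 2))
  res <- kruskal_wallis(df)
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 with no ties
  rbar <- c(1.5, 3.5, 5.5)
  H <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(H, 2, lower.tail = FALSE))
  # degenerate input: identical values
  same <- tibble::tibble(value = rep(7, 9), group = rep(c("a", "b", "c"), 3))
  expect_equal(kruskal_wallis(same)$p_value, 1)
})

test_that("Kruskal-Wallis chi-square p agrees with a permutation oracle", {
  set.seed(5)
  df <- tibble::tibble(value = c(rnorm(5), rnorm(5, 1.5), rnorm(5, 3)),
                       group = rep(c("a", "b", "c"), each = 5))
  res <- kruskal_wallis(df)
  h_stat <- function(v, g) {
    unname(stats::kruskal.test(v, g)$statistic)
  }
  h_obs <- h_stat(df$value, factor(df$group))
  perm <- replicate(4000, h_stat(sample(df$value), factor(df$group)))
  p_perm <- mean(perm >= h_obs - 1e-12)
  expect_lt(abs(res$p_value - p_perm), 0.02 + 3 * sqrt(p_perm * (1 - p_perm) / 4000))
})

test_that("Dunn's test orders pairs sensibly and adjustment is monotone", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 4, 21, 22, 23, 24, 10, 11, 12, 13, 10.5, 11.5, 12.5, 13.5),
    group = rep(c("low", "high", "mid1", "mid2"), each = 4))
  res <- dunns_test(df)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  best <- res[which.min(res$p_adjusted), ]
  expect_setequal(c(best$group1, best$group2), c("low", "high"))
  # identical groups: all adjusted p = 1
  same <- tibble::tibble(value = rep(3, 12), group = rep(c("a", "b", "c"), 4))
  expect_true(all(dunns_test(same)$p_adjusted == 1))
})
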