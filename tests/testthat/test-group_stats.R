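test_that("Mann-Whitney U and exact p match the textbook cases", {
  out <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(out$method, "exact")

  same <- mann_whitney_u(1:6, 1:6)
  expect_equal(same$statistic, 36 / 2)
  expect_gte(same$p_value, 0.9)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation reproduces the U = 281 reference p", {
  # samples engineered to give U = 281 with n = (32, 34), no ties
  x <- c(1:23, 33, 59:66)      # 32 values
  y <- setdiff(1:66, x)        # 34 values
  r <- rank(c(x, y))
  u_x <- sum(r[1:32]) - 32 * 33 / 2
  expect_equal(min(u_x, 32 * 34 - u_x), 281)
  out <- mann_whitney_u(x, y, exact = FALSE)
  expect_equal(out$statistic, 281)
  expect_lt(abs(out$p_value - 6e-4), 2e-4)
})

test_that("exact Mann-Whitney equals full enumeration on random samples", {
  set.seed(42)
  for (i in 1:200) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    repeat {
      x <- round(runif(nx, 0, 100), 3)
      y <- round(runif(ny, 0, 100), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    got <- mann_whitney_u(x, y)
    want <- oracle_mw_exact(x, y)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree closely", {
  set.seed(7)
  for (i in 1:200) {
    nx <- sample(5:7, 1)
    ny <- sample(5:7, 1)
    repeat {
      x <- runif(nx); y <- runif(ny)
      if (!anyDuplicated(c(x, y))) break
    }
    pe <- mann_whitney_u(x, y, exact = TRUE)$p_value
    pa <- mann_whitney_u(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.03)
  }
})

test_that("signed-rank W uses the signed-sum convention", {
  pre <- 1:10
  post <- pre - seq(0.5, 5, 0.5)       # all decreased
  out <- wilcoxon_signed_rank(pre, post)
  expect_equal(out$statistic, -55)     # -(1 + ... + 10)
  expect_equal(out$p_value, 2 / 1024, tolerance = 1e-12)

  # antisymmetric differences cancel
  d <- c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5)
  anti <- wilcoxon_signed_rank(rep(0, 6), d)
  expect_equal(anti$statistic, 0)

  # 18 pairs, 17 negative and the smallest-rank one positive: W = -169
  d18 <- -(2:18)
  d18 <- c(0.5, d18)                   # positive difference with rank 1
  out18 <- wilcoxon_signed_rank(rep(0, 18), d18)
  expect_equal(out18$statistic, 1 - 170)
  expect_lt(out18$p_value, 0.001)

  degen <- wilcoxon_signed_rank(1:4, 1:4)
  expect_equal(degen$p_value, 1)

  # extreme case: all-same-sign differences of size n give n(n+1)/2
  for (n in c(5, 9, 14)) {
    w <- wilcoxon_signed_rank(rep(0, n), seq_len(n))$statistic
    expect_equal(abs(w), n * (n + 1) / 2)
  }
})

test_that("median CIs come from binomial order statistics", {
  out <- median_with_ci(1:100)
  expect_equal(out$median, 50.5)
  expect_equal(out$ci, c(40, 61))      # 40th and 61st order statistics
  expect_gte(out$coverage, 0.95)

  const <- median_with_ci(rep(3.3, 12))
  expect_equal(const$ci, c(3.3, 3.3))

  small <- median_with_ci(1:5)
  expect_true(small$under_coverage)
  expect_equal(small$ci, c(1, 5))
})

test_that("bootstrap median difference recovers shifts, deterministically", {
  set.seed(1)
  x <- rnorm(40)
  y <- x + 2.5
  b1 <- bootstrap_median_difference(x, y, n_boot = 1000, seed = 3)
  expect_equal(b1$diff, 2.5, tolerance = 1e-12)
  expect_true(b1$ci[1] <= 2.5 && 2.5 <= b1$ci[2])
  b2 <- bootstrap_median_difference(x, y, n_boot = 1000, seed = 3)
  expect_identical(b1$ci, b2$ci)
  expect_true(bootstrap_median_difference(x[1:4], y[1:4], 100,
                                          seed = 1)$under_coverage)
})

test_that("bootstrap CI coverage sits near the nominal level", {
  # heavy-tailed shift alternatives; percentile CI should cover the true
  # median shift in roughly 93-97% of trials
  shift <- 1
  hits <- 0L
  n_trials <- 400
  for (i in seq_len(n_trials)) {
    set.seed(i)
    x <- rt(30, df = 3)
    y <- rt(30, df = 3) + shift
    ci <- bootstrap_median_difference(x, y, n_boot = 400, seed = i)$ci
    if (ci[1] <= shift && shift <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.92)
  expect_lte(hits / n_trials, 0.98)
})

test_that("eta-squared reproduces the reported rank-test effect sizes", {
  expect_equal(eta_squared_from_z(2, 41)$eta_sq, 0.1, tolerance = 1e-12)
  expect_equal(eta_squared_from_z(0, 10)$eta_sq, 0)
  expect_equal(eta_squared_from_z(0.4, 26)$size_class, "negligible")
  expect_equal(eta_squared_from_z(2.2, 30)$size_class, "large")

  # printed (U, n1, n2, eta^2) bundles from the reference comparisons
  printed <- list(
    list(u = 281, n1 = 32, n2 = 34, eta = 0.17),
    list(u = 296, n1 = 30, n2 = 33, eta = 0.12),
    list(u = 380, n1 = 33, n2 = 35, eta = 0.09),
    list(u = 87,  n1 = 18, n2 = 18, eta = 0.16),
    list(u = 287, n1 = 31, n2 = 32, eta = 0.13),
    list(u = 397, n1 = 34, n2 = 35, eta = 0.08),
    list(u = 393, n1 = 33, n2 = 34, eta = 0.07))
  for (pp in printed) {
    got <- eta_squared_from_u(pp$u, pp$n1, pp$n2)$eta_sq
    expect_lt(abs(got - pp$eta), 0.015)
  }
})

test_that("Spearman rho handles monotone, antitone and constant input", {
  x <- 1:8
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  out <- spearman_rho(x, rep(1, 8))
  expect_true(is.na(out$rho))
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30, 0, 0.4)
  s <- spearman_rho(a, b)
  expect_gt(s$rho, 0.5)
  expect_lt(s$p_value, 0.01)
})

test_that("sample-size formula reproduces the planning result", {
  expect_identical(sample_size_two_sample_t(delta = 20, sd = 20), 16L)
  expect_identical(sample_size_two_sample_t(delta = 2, sd = 1), 4L)
  expect_identical(sample_size_two_sample_t(delta = 1000, sd = 1), 1L)
  expect_gte(sample_size_two_sample_t(delta = 20, sd = 20,
                                      method = "exact_t"), 16L)
  expect_error(sample_size_two_sample_t(delta = 0, sd = 1), "non-zero")
})

test_that("two-group bundles report eta^2 only when significant", {
  set.seed(9)
  x <- rnorm(20)
  cmp_null <- compare_two_groups(x, rnorm(20), n_boot = 200, seed = 1)
  if (cmp_null$p_value >= 0.05) expect_true(is.na(cmp_null$eta_sq))
  cmp_sig <- compare_two_groups(x, rnorm(20) + 3, n_boot = 200, seed = 1)
  expect_lt(cmp_sig$p_value, 0.05)
  expect_false(is.na(cmp_sig$eta_sq))
  expect_true(cmp_sig$eta_sq >= 0 && cmp_sig$eta_sq <= 1)
})
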