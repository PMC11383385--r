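#' Mann-Whitney U test for two independent samples
#'
#' The statistic is U = min(U_x, U_y) computed from midranks. The exact
#' two-sided p-value (from the full permutation distribution of U) is
#' used for small tie-free samples; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) p; `NULL`
#'   (default) chooses exact when `length(x) + length(y) <= 16` and no
#'   ties are present.
#' @return List of class `ep_test`: `statistic` (U), `p_value`, `n_x`,
#'   `n_y`, `method` (`"exact"` or `"normal_approx"`), `z` (normal
#'   deviate without continuity correction, for effect sizes; `NA` when
#'   degenerate).
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x
  u <- min(u_x, u_y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (nx + ny <= 16) && !ties
  mu <- nx * ny / 2
  tie_tab <- table(c(x, y))
  n <- nx + ny
  sig2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z_raw <- if (sig2 > 0) (u_x - mu) / sqrt(sig2) else NA_real_
  if (exact) {
    p <- min(1, 2 * pwilcox(u, nx, ny))
    method <- "exact"
  } else {
    if (sig2 <= 0) {
      p <- 1
    } else {
      zc <- (u - mu + 0.5) / sqrt(sig2)  # continuity correction toward center
      p <- min(1, 2 * pnorm(zc))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u, p_value = p, n_x = nx, n_y = ny,
                 method = method, z = z_raw),
            class = "ep_test")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed-rank-sum convention: W is the sum of the ranks of the absolute
#' differences, each carrying the sign of its difference (`post - pre`),
#' so W is negative when the measure decreases after treatment; an
#' all-decrease sample of n pairs gives W = -n(n+1)/2. Zero differences
#' are dropped before ranking. Exact p for n <= 15 (tie-free), otherwise
#' normal approximation with continuity correction.
#'
#' @param pre,post Paired numeric samples of equal length.
#' @param exact Force exact (`TRUE`) / approximate (`FALSE`); `NULL`
#'   auto-selects.
#' @return List of class `ep_test`: `statistic` (signed W), `p_value`,
#'   `n` (non-zero pairs), `method`, `z`. All-zero differences give a
#'   degenerate result with p = 1.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact = NULL) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  d <- post - pre
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, p_value = 1, n = 0L,
                          method = "degenerate", z = NA_real_),
                     class = "ep_test"))
  r <- rank(abs(d))
  w <- sum(sign(d) * r)
  v <- sum(r[d > 0])  # positive-rank sum, the classical V statistic
  ties <- anyDuplicated(abs(d)) > 0
  if (is.null(exact)) exact <- n <= 15 && !ties
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z_raw <- if (sig2 > 0) (v - mu) / sqrt(sig2) else NA_real_
  if (exact && sig2 > 0) {
    p <- min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
    method <- "exact"
  } else if (sig2 > 0) {
    zc <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(zc)))
    method <- "normal_approx"
  } else {
    p <- 1
    method <- "degenerate"
  }
  structure(list(statistic = w, p_value = p, n = n, method = method,
                 z = z_raw),
            class = "ep_test")
}

#' @export
print.ep_test <- function(x, ...) {
  cat(sprintf("<ep_test> statistic = %g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Median with a distribution-free confidence interval
#'
#' The CI comes from binomial order statistics: the smallest symmetric
#' order-statistic pair whose coverage reaches the requested level. For
#' n < 6 no such pair exists at 95%, so the sample range is returned with
#' an under-coverage flag.
#'
#' @param x Numeric sample.
#' @param level Confidence level.
#' @return List: `median`, `ci` (length 2), `coverage` (achieved),
#'   `under_coverage` (logical), `n`.
#' @export
median_with_ci <- function(x, level = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 1) stop("empty sample", call. = FALSE)
  med <- median(x)
  alpha <- 1 - level
  k <- qbinom(alpha / 2, n, 0.5)
  while (k > 0 && pbinom(k - 1, n, 0.5) > alpha / 2) k <- k - 1
  if (k < 1) {
    # no symmetric order-statistic pair reaches the level: report the range
    return(list(median = med, ci = c(x[1], x[n]),
                coverage = 1 - 2 * 0.5^n,
                under_coverage = TRUE, n = n))
  }
  cov <- 1 - 2 * pbinom(k - 1, n, 0.5)
  list(median = med, ci = c(x[k], x[n + 1 - k]), coverage = cov,
       under_coverage = cov < level, n = n)
}

#' Bootstrap median difference with percentile CI
#'
#' The estimation-statistics quantity: `median(y) - median(x)` (group x
#' is the reference) with a seeded percentile bootstrap CI; the full
#' bootstrap distribution is kept for plotting.
#'
#' @param x,y Numeric samples (reference first).
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed.
#' @param level Confidence level.
#' @return List: `diff`, `ci`, `boot` (resampled differences),
#'   `under_coverage` flag for tiny samples (n < 5 in either group).
#' @export
bootstrap_median_difference <- function(x, y, n_boot = 5000, seed = 1,
                                        level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  set.seed(as.integer(seed %% .Machine$integer.max))
  boot <- vapply(seq_len(n_boot), function(b)
    median(sample(y, replace = TRUE)) - median(sample(x, replace = TRUE)),
    0)
  alpha <- 1 - level
  list(diff = median(y) - median(x),
       ci = unname(quantile(boot, c(alpha / 2, 1 - alpha / 2))),
       boot = boot,
       under_coverage = length(x) < 5 || length(y) < 5)
}

#' Eta-squared effect size for rank tests
#'
#' For a rank test summarised by a standard-normal deviate z on N total
#' observations, eta^2 = z^2 / (N - 1): the fraction of variance
#' attributable to the group difference. Size classes use the
#' conventional cutoffs 0.01 (small), 0.06 (medium), 0.14 (large).
#'
#' @param z Normal deviate.
#' @param n_total Total observations across both groups (>= 2).
#' @return List: `eta_sq`, `size_class`.
#' @export
eta_squared_from_z <- function(z, n_total) {
  stopifnot(n_total >= 2)
  eta <- z^2 / (n_total - 1)
  list(eta_sq = eta, size_class = eta_size_class(eta))
}

#' @rdname eta_squared_from_z
#' @param u Mann-Whitney U (either orientation; the magnitude of z is
#'   unaffected).
#' @param n_x,n_y Group sizes.
#' @export
eta_squared_from_u <- function(u, n_x, n_y) {
  mu <- n_x * n_y / 2
  sig <- sqrt(n_x * n_y * (n_x + n_y + 1) / 12)
  eta_squared_from_z((u - mu) / sig, n_x + n_y)
}

eta_size_class <- function(eta) {
  if (eta >= 0.14) "large"
  else if (eta >= 0.06) "medium"
  else if (eta >= 0.01) "small"
  else "negligible"
}

#' Spearman rank correlation
#'
#' Midrank-based Pearson correlation of the ranks; the p-value uses
#' exact enumeration for n <= 9 without ties and the t approximation
#' otherwise (delegated to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return List: `rho`, `p_value`, `n`; `rho` is `NA` with attribute
#'   `reason` for constant input.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    out <- list(rho = NA_real_, p_value = NA_real_, n = n)
    attr(out, "reason") <- "constant input"
    return(out)
  }
  rho <- cor(rank(x), rank(y))
  p <- suppressWarnings(
    cor.test(x, y, method = "spearman",
             exact = n <= 9 && !anyDuplicated(x) && !anyDuplicated(y))$p.value)
  list(rho = rho, p_value = p, n = n)
}

#' Sample size for a two-sample comparison of means
#'
#' Normal-approximation two-sample formula,
#' n = ceiling(2 sd^2 (z_(1-alpha/2) + z_power)^2 / delta^2) per group.
#' An iterative exact-t variant (which typically adds one) is available
#' via `method = "exact_t"`.
#'
#' @param delta Mean difference to detect (same units as `sd`).
#' @param sd Common standard deviation.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @param method `"normal"` (default) or `"exact_t"`.
#' @return Cells per group (integer).
#' @export
sample_size_two_sample_t <- function(delta, sd, alpha = 0.05, power = 0.8,
                                     method = c("normal", "exact_t")) {
  method <- match.arg(method)
  stopifnot(sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (delta == 0) stop("delta must be non-zero", call. = FALSE)
  n0 <- 2 * sd^2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / delta^2
  if (method == "normal") return(max(1L, as.integer(ceiling(n0))))
  n <- max(2, ceiling(n0))
  repeat {
    pw <- stats::power.t.test(n = n, delta = delta, sd = sd,
                              sig.level = alpha)$power
    if (pw >= power) return(as.integer(n))
    n <- n + 1
  }
}

#' Full two-group comparison bundle
#'
#' The standard reporting unit for a two-group contrast: Mann-Whitney
#' U and p, per-group medians with order-statistic CIs, the bootstrap
#' median difference with percentile CI, and (only when p < 0.05, per
#' reporting convention) the eta-squared effect size.
#'
#' @param x,y Numeric samples (x is the reference group).
#' @param n_boot,seed Bootstrap settings.
#' @param label Optional feature name carried in the result.
#' @return Object of class `ep_comparison`.
#' @export
compare_two_groups <- function(x, y, n_boot = 5000, seed = 1,
                               label = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  test <- mann_whitney_u(x, y)
  med_x <- median_with_ci(x)
  med_y <- median_with_ci(y)
  bt <- bootstrap_median_difference(x, y, n_boot = n_boot, seed = seed)
  eta <- if (!is.na(test$p_value) && test$p_value < 0.05 && !is.na(test$z))
    eta_squared_from_z(test$z, test$n_x + test$n_y) else
      list(eta_sq = NA_real_, size_class = NA_character_)
  structure(list(
    label = label, statistic = test$statistic, p_value = test$p_value,
    method = test$method,
    median_a = med_x$median, ci_a = med_x$ci,
    median_b = med_y$median, ci_b = med_y$ci,
    median_diff = bt$diff, ci_diff = bt$ci, boot = bt$boot,
    eta_sq = eta$eta_sq, eta_size = eta$size_class,
    n_a = test$n_x, n_b = test$n_y),
    class = "ep_comparison")
}

#' @export
print.ep_comparison <- function(x, ...) {
  cat(sprintf("<ep_comparison>%s U = %g, p = %.4g\n",
              if (is.na(x$label)) "" else paste0(" ", x$label, ":"),
              x$statistic, x$p_value))
  cat(sprintf("  A: median %.4g, 95%% CI [%.4g, %.4g] (n = %d)\n",
              x$median_a, x$ci_a[1], x$ci_a[2], x$n_a))
  cat(sprintf("  B: median %.4g, 95%% CI [%.4g, %.4g] (n = %d)\n",
              x$median_b, x$ci_b[1], x$ci_b[2], x$n_b))
  cat(sprintf("  median difference (B - A): %.4g, 95%% CI [%.4g, %.4g]\n",
              x$median_diff, x$ci_diff[1], x$ci_diff[2]))
  if (!is.na(x$eta_sq))
    cat(sprintf("  eta^2 = %.3f (%s)\n", x$eta_sq, x$eta_size))
  invisible(x)
}
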