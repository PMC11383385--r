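# Independent oracles used to cross-check the implementation.

# Literal transcription of the burst/tonic/rebound classification rules,
# written as a plain per-spike walk (deliberately structured differently
# from the package implementation).
oracle_classify <- function(spike_t, amp, step_on, step_off,
                            burst_window = 500, burst_isi = 4,
                            ratio_lo = 0.5, ratio_hi = 1.99,
                            tonic_ratio = 2, max_spikes = 15,
                            rebound_window = 1000) {
  n <- length(spike_t)
  lab <- rep("other", n)
  if (n == 0) return(lab)
  if (amp < 0) {
    for (i in seq_len(n))
      if (spike_t[i] > step_off && spike_t[i] <= step_off + rebound_window)
        lab[i] <- "rebound"
    return(lab)
  }
  during <- which(spike_t >= step_on & spike_t < step_off)
  if (length(during) > max_spikes) return(rep("total", n))
  tt <- spike_t[during]
  m <- length(tt)
  if (m == 0) return(lab)
  iv <- function(j) tt[j] - tt[j - 1]          # interval before spike j
  rt <- function(j) iv(j) / iv(j - 1)          # ratio, defined for j >= 3
  ft <- Inf
  if (m >= 3) {
    for (j in 3:m) if (rt(j) >= tonic_ratio) { ft <- j; break }
  }
  out <- rep("other", m)
  if (m >= 2) {
    for (j in 2:m) {
      if (j >= ft) next
      in_window <- (tt[j] - step_on) <= burst_window
      short <- iv(j) < burst_isi
      band <- if (j == 2) TRUE else (rt(j) >= ratio_lo && rt(j) <= ratio_hi)
      if (in_window && short && band) out[j] <- "burst"
    }
    if (out[2] == "burst" && ft > 1) out[1] <- "burst"
  }
  if (is.finite(ft)) out[ft:m] <- "tonic"
  lab[during] <- out
  lab
}

# Random spike trains mixing sparse background with tight clusters.
random_train <- function(seed) {
  set.seed(seed)
  amp <- sample(c(-100, -50, 0, 50, 100), 1)
  n <- sample(0:22, 1)
  t <- if (n > 0) runif(n, 0, 2500) else numeric(0)
  if (runif(1) < 0.6) {
    k <- sample(2:6, 1)
    t0 <- runif(1, 255, 900)
    t <- c(t, t0 + cumsum(c(0, runif(k - 1, 0.8, 6))))
  }
  t <- sort(t)
  if (length(t) > 1) t <- t[c(TRUE, diff(t) > 1e-6)]
  list(t = t, amp = amp)
}

# Full-enumeration Mann-Whitney oracle (tie-free samples).
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_obs <- min(ux, nx * (n - nx) - ux)
  combs <- utils::combn(n, nx)
  ux_all <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  list(u = u_obs, p = min(1, 2 * mean(ux_all <= u_obs)))
}
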