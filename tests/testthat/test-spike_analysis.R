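test_that("spike detection finds template peaks and enforces separation", {
  sub <- flat_sweep(-65, -60, amp = 20, fs = 20000)
  expect_length(detect_spikes(sub), 0)

  times <- c(400, 420, 470, 900, 1200)
  sw <- template_spike_sweep(times)
  got <- detect_spikes(sw)
  expect_length(got, 5)
  expect_true(all(abs(got - times) <= 1000 / sw$fs))

  # two candidate peaks 0.4 ms apart: only the higher survives
  dt <- 1000 / 20000
  t <- seq(0, 500 - dt, by = dt)
  v <- rep(-65, length(t))
  v[which.min(abs(t - 200))] <- 10
  v[which.min(abs(t - 200.4))] <- 25
  sw2 <- sweep(v, fs = 20000, step_on = 100, step_off = 400, amp = 50)
  got2 <- detect_spikes(sw2)
  expect_length(got2, 1)
  expect_equal(sw2$v[which.min(abs(sw2$t - got2))], 25)
})

test_that("third-derivative threshold matches a brute-force oracle", {
  # analytic pre-peak waveform V(t) = V0 + A exp((t - t0)/DT)
  fs <- 20000
  dt <- 1000 / fs
  t <- seq(0, 400 - dt, by = dt)
  v0 <- -65; A <- 1e-4; DT <- 0.3; t0 <- 100
  v <- pmin(v0 + A * exp((t - t0) / DT), 30)
  pk <- t[which.max(v >= 30)]
  sw <- sweep(v, fs = fs, step_on = 10, step_off = 390, amp = 50)

  th <- spike_threshold(sw, pk, cutoff = 0.3, smooth_ms = 0)
  # oracle: exact third derivative A/DT^3 exp((t-t0)/DT) crosses 0.3 at
  t_star <- t0 + DT * log(0.3 * DT^3 / A)
  expect_lt(abs(th$thresh_t - t_star), 0.3)
  v_star <- v0 + A * exp((t_star - t0) / DT)
  expect_lt(abs(th$thresh_v - v_star), 0.5)

  # dense brute-force differentiation agrees
  tt <- seq(t_star - 5, t_star + 5, by = 1e-4)
  d3 <- (A / DT^3) * exp((tt - t0) / DT)
  expect_lt(abs(tt[which(d3 > 0.3)[1]] - t_star), 1e-3)

  # halving the cutoff moves the threshold earlier / more hyperpolarized
  th2 <- spike_threshold(sw, pk, cutoff = 0.15, smooth_ms = 0)
  expect_lt(th2$thresh_t, th$thresh_t)
  expect_lt(th2$thresh_v, th$thresh_v)
})

test_that("threshold estimates are stable under sampling-rate doubling", {
  # identical noise-free dynamics emitted at 40 kHz and at 20 kHz
  p <- md_m_params(seed = 8, noise_pa = 0)
  bias <- holding_bias(p, -65)
  hi <- simulate_sweep(p, 40, bias = bias, fs = 40000, oversample = 1)
  lo <- simulate_sweep(p, 40, bias = bias, fs = 20000, oversample = 2)
  t1 <- spike_threshold(hi, detect_spikes(hi)[1])$thresh_v
  t2 <- spike_threshold(lo, detect_spikes(lo)[1])$thresh_v
  expect_lt(abs(t1 - t2), 0.5)
})

test_that("the classification rules reproduce the worked example", {
  st <- 250 + c(5, 7, 9, 120, 260, 420, 600)
  cls <- classify_step_spikes(st, amp = 50, step_on = 250, step_off = 1250)
  expect_equal(cls$label,
               c("burst", "burst", "burst", "tonic", "tonic", "tonic",
                 "tonic"))
  # ratio at the 4th spike: 111 / 2 >= 2 makes it the first tonic spike
  expect_gte(cls$isi_ratio[4], 2)
})

test_that("the >15-spike gate and the rebound window apply", {
  many <- 250 + sort(runif(22, 10, 900))
  cls <- classify_step_spikes(many, amp = 300, step_on = 250,
                              step_off = 1250)
  expect_true(all(cls$label == "total"))

  reb <- classify_step_spikes(1250 + c(20, 24), amp = -100, step_on = 250,
                              step_off = 1250)
  expect_equal(reb$label, c("rebound", "rebound"))
  late <- classify_step_spikes(c(1250 + 500, 1250 + 1200), amp = -100,
                               step_on = 250, step_off = 1250)
  expect_equal(late$label, c("rebound", "other"))

  expect_error(classify_step_spikes(c(300, 280), 50, 250, 1250),
               "strictly increasing")
})

test_that("classifier agrees spike-for-spike with the literal oracle", {
  rules <- classifier_rules()
  for (s in 1:1000) {
    tr <- random_train(s)
    got <- classify_step_spikes(tr$t, tr$amp, 250, 1250, rules)$label
    want <- oracle_classify(tr$t, tr$amp, 250, 1250)
    expect_identical(got, want)
    # label partition: every spike gets exactly one admissible label
    expect_true(all(got %in% c("burst", "tonic", "rebound", "total",
                               "other")))
  }
})

test_that("rheobase picks the smallest qualifying amplitude per mode", {
  mk <- function(amp, times) template_spike_sweep(times, amp = amp)
  sweeps <- list(
    mk(5, numeric(0)),
    mk(10, 250 + c(10, 12)),             # first burst doublet
    mk(15, 250 + c(10, 12, 14)),
    mk(20, 250 + c(10, 12, 100, 300, 500)))
  rec <- recording(sweeps, holding_mv = -65)
  rb <- rheobase(rec, "burst_depol")
  expect_equal(rb$rheobase_pa, 10)
  rt <- rheobase(rec, "tonic")
  expect_equal(rt$rheobase_pa, 20)      # ratio jump only in the 20 pA sweep

  # no rebound spikes anywhere -> not-measurable flag
  rr <- rheobase(rec, "rebound")
  expect_true(is.na(rr$rheobase_pa))
  expect_match(attr(rr, "reason"), "rebound")

  # rebound needs a burst of >= 2 rebound spikes
  hyp <- list(mk(-10, 1250 + 30), mk(-20, 1250 + c(30, 33)))
  rec2 <- recording(hyp, holding_mv = -65)
  r2 <- rheobase(rec2, "rebound")
  expect_equal(r2$rheobase_pa, -20)
  expect_false(is.na(r2$steady_mv))
})

test_that("accommodation index is the OLS slope of tonic intervals", {
  isis <- seq(10, 32, by = 2)                  # 12 intervals, slope 2
  times <- 250 + c(0, 2, 50, 50 + cumsum(isis))
  sw <- template_spike_sweep(times, amp = 150)
  low <- template_spike_sweep(250 + c(0, 2), amp = 100)
  rec <- recording(list(low, sw), holding_mv = -65)
  acc <- accommodation_index(rec)
  expect_equal(acc$slope_ms_per_interval, 2, tolerance = 0.02)
  expect_equal(acc$amp_used_pa, 150)

  # constant intervals give slope 0; lowest qualifying amplitude wins
  flat_times <- 250 + c(0, 2, 50 + seq(0, 12 * 20, by = 20))
  two <- recording(list(template_spike_sweep(flat_times, amp = 150),
                        template_spike_sweep(times, amp = 200)),
                   holding_mv = -65)
  acc2 <- accommodation_index(two)
  expect_equal(acc2$amp_used_pa, 150)
  expect_equal(acc2$slope_ms_per_interval, 0, tolerance = 0.02)

  none <- recording(list(low), holding_mv = -65)
  expect_true(is.na(accommodation_index(none)$slope_ms_per_interval))
})

test_that("firing-rate curves apply the burst/tonic inclusion rules", {
  sweeps <- list(flat_sweep(-65, -60, amp = 10, fs = 20000),
                 template_spike_sweep(250 + c(5, 7), amp = 20),
                 flat_sweep(-65, -58, amp = 30, fs = 20000))
  fi <- fi_curve(recording(sweeps, holding_mv = -65))
  expect_equal(fi$n_tonic, c(0L, 0L, 0L))    # zero-spike sweeps included
  expect_equal(fi$include_burst, c(FALSE, TRUE, FALSE))
  expect_equal(fi$n_burst[2], 2L)
})

test_that("model bursts carry 2-8 spikes and HCN block weakens rebound", {
  p <- md_m_params(seed = 3)
  bias <- holding_bias(p, -65)
  sw <- simulate_sweep(p, 20, bias = bias)
  cls <- classify_step_spikes(detect_spikes(sw), 20, 250, 1250)
  nb <- sum(cls$label == "burst")
  expect_gte(nb, 2)
  expect_lte(nb, 8)

  pl <- md_l_params(seed = 5)
  pz <- apply_zd7288(pl, 1)
  reb_n <- function(q, a) {
    st <- detect_spikes(simulate_sweep(q, a, bias = holding_bias(q, -65)))
    sum(st > 1250 & st <= 2250)
  }
  pre <- vapply(c(-20, -40, -60), function(a) reb_n(pl, a), 0)
  post <- vapply(c(-20, -40, -60), function(a) reb_n(pz, a), 0)
  expect_true(all(post <= pre))
  expect_lt(mean(post), mean(pre))
})

test_that("tonic firing collapses at strong drive (depolarization block)", {
  p <- apply_zd7288(md_m_params(seed = 5), 1)
  bias <- holding_bias(p, -65)
  counts <- vapply(c(50, 100, 200, 300), function(a) {
    st <- detect_spikes(simulate_sweep(p, a, bias = bias))
    sum(st >= 250 & st < 1250)
  }, 0)
  expect_gt(max(counts), counts[length(counts)])  # non-monotone decline
})
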