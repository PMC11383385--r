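test_that("RMP of a constant baseline is that constant", {
  sw <- flat_sweep(-61, -61, amp = 0, baseline_pa = 0)
  rec <- recording(list(sw), holding_mv = NA, protocol = "rmp")
  expect_equal(estimate_rmp(rec), -61)
  # a biased recording is not-measurable
  swb <- flat_sweep(-65, -70, amp = -10, baseline_pa = -12)
  recb <- recording(list(swb), holding_mv = -65)
  expect_true(is.na(estimate_rmp(recb)))
  expect_match(attr(estimate_rmp(recb), "reason"), "zero-bias")
})

test_that("time constant recovers analytic exponentials in both modes", {
  # the reference fixture: pure exponential with tau = 74.37 ms
  rec <- recording(list(rc_sweep(-65, -8, 74.37)), holding_mv = -65)
  expect_equal(estimate_time_constant(rec, mode = "offset"), 74.37,
               tolerance = 0.01)
  expect_equal(estimate_time_constant(rec, mode = "onset"), 74.37,
               tolerance = 0.01)
  # RC cell with C = 100 pF, g = 2 nS -> 50 ms
  rec50 <- recording(list(rc_sweep(-65, -5, 50)), holding_mv = -65)
  expect_equal(estimate_time_constant(rec50), 50, tolerance = 0.02 * 50)
})

test_that("averaging repetitions improves the tau estimate", {
  # Monte-Carlo: noisy exponentials, averaged estimate closer to truth
  # than a single noisy repetition in at least 80% of seeds
  tau_true <- 60
  wins <- 0L
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    reps <- lapply(1:10, function(i) {
      sw <- rc_sweep(-65, -6, tau_true, fs = 5000)
      sw$v <- sw$v + rnorm(length(sw$v), 0, 0.25)
      sw
    })
    est10 <- estimate_time_constant(recording(reps, holding_mv = -65))
    est1 <- estimate_time_constant(recording(reps[1], holding_mv = -65))
    if (abs(est10 - tau_true) < abs(est1 - tau_true)) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_seeds)
})

test_that("input resistance is the OLS slope of the subthreshold V-I", {
  # exact points (-10, -6), (0, 0), (+10, +6) -> 600 MOhm
  sweeps <- lapply(c(-10, 0, 10), function(a)
    flat_sweep(-65, -65 + a * 0.6, amp = a, fs = 2000))
  fit <- estimate_input_resistance(recording(sweeps, holding_mv = -65))
  expect_equal(fit$rn_mohm, 600, tolerance = 1e-6)
  expect_false(any(fit$vi_curve$has_spikes))

  # sweeps with spikes are excluded; fewer than 3 usable -> flag
  spiky <- lapply(c(-10, 0, 10), function(a)
    template_spike_sweep(c(500, 600), amp = a))
  out <- estimate_input_resistance(recording(spiky, holding_mv = -65))
  expect_true(is.na(out$rn_mohm))
  expect_match(attr(out$rn_mohm, "reason"), "spike-free")
})

test_that("sag is peak minus late-step mean, hyperpolarizing sweeps only", {
  # trace with peak -100 and a late-step mean of -92 -> sag -8
  sw <- rc_sweep(-65, -27, 30, fs = 2000)
  dip <- sw$t >= 300 & sw$t < 500
  sw$v[dip] <- sw$v[dip] - (100 - 92) * exp(-(sw$t[dip] - 300) / 40)
  sw$v[which.min(abs(sw$t - 305))] <- -100
  m <- measure_sag(sw)
  expect_equal(m$peak_mv, -100)
  expect_equal(m$steady_mv, -92, tolerance = 0.05)
  expect_equal(m$sag_mv, -8, tolerance = 0.06)
  expect_error(measure_sag(flat_sweep(-65, -60, amp = 10)), "hyperpolarizing")
})

test_that("sag sweep selection picks the peak nearest the target", {
  sweeps <- lapply(c(-80, -97, -112), function(pk)
    rc_sweep(-65, pk + 65, 40, amp = round((pk + 65) / 0.5)))
  rec <- recording(sweeps, holding_mv = -65)
  out <- sag_at_peak_target(rec, target_mv = -100)
  expect_equal(out$peak_mv, -97, tolerance = 0.2)
  expect_true(out$within_tolerance)
  dep <- recording(list(flat_sweep(-65, -60, amp = 10)), holding_mv = -65)
  expect_error(sag_at_peak_target(dep), "hyperpolarizing")
})

test_that("AHP is the post-offset minimum with its latency", {
  sw <- rc_sweep(-65, 20, 30, amp = 40)
  post <- sw$t > 1250 & sw$t <= 1500
  sw$v[post] <- -65 - 11.1 * exp(-abs(sw$t[post] - 1290) / 25)
  sw$v[which.min(abs(sw$t - 1290))] <- -76.1
  m <- measure_ahp(sw)
  expect_equal(m$ahp_mv, -76.1)
  expect_equal(m$t_min_ms, 40, tolerance = 0.1)
  expect_error(measure_ahp(sw, window_ms = 5000), "window error")
  expect_error(measure_ahp(flat_sweep(-65, -70, amp = -10)), "depolarizing")
})

test_that("drug-matched AHP reads the post trace at the pre minimum time", {
  sw <- rc_sweep(-65, 20, 30, amp = 40)
  post <- sw$t > 1250 & sw$t <= 1500
  sw$v[post] <- -65 - 8 * exp(-abs(sw$t[post] - 1290) / 25)
  same <- measure_ahp_matched(sw, sw)
  expect_equal(same$pre_mv, same$post_mv)
  expect_equal(same$t_match_ms, 40, tolerance = 0.1)
  sw2 <- sw
  sw2$v <- sw2$v + 3
  m <- measure_ahp_matched(sw, sw2)
  expect_equal(m$post_mv - m$pre_mv, 3, tolerance = 1e-9)
  sw3 <- flat_sweep(-65, -60, amp = 40, fs = 20000, pre = 100, dur = 500,
                    post = 400)
  expect_error(measure_ahp_matched(sw, sw3), "alignment error")
})

test_that("HCN block depolarizes the matched AHP in the model", {
  p <- md_l_params(seed = 6)
  spec <- protocol_spec("dep", c(30, 50), post_dur = 600)
  pre <- simulate_protocol(p, spec, -65)
  post <- simulate_protocol(apply_zd7288(p, 1), spec, -65)
  m <- measure_ahp_matched(pre$sweeps[[2]], post$sweeps[[2]])
  expect_gt(m$post_mv, m$pre_mv)
})
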