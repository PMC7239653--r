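# RMS-noise estimation, event detection, window statistics and the
# spontaneous-corrected quantal amplitude.

test_that("estimate_rms_noise: zero, calibrated, and masked cases", {
  # noise-free sweeps -> 0
  tr0 <- ephys_truth(spont_rate = 0, evoked_rate = 0, noise_rms = 0, seed = 1)
  sim0 <- gen_sr_sweeps(tr0, n_sweeps = 3)
  expect_equal(estimate_rms_noise(sim0$sweeps), 0)

  # pure Gaussian noise sd 2.0 -> 2.0 +- 0.1 (>= 1e4 baseline samples)
  tr2 <- ephys_truth(spont_rate = 0, evoked_rate = 0, noise_rms = 2, seed = 2)
  sim2 <- gen_sr_sweeps(tr2, n_sweeps = 20)
  expect_equal(estimate_rms_noise(sim2$sweeps), 2.0, tolerance = 0.05)

  # large events confined to the excluded peri-stimulus segment leave the
  # estimate unchanged exactly (same noise stream, amplitudes zeroed)
  trn <- ephys_truth(noise_rms = 2, seed = 3)
  ev <- data.frame(sweep = rep(1:10, 2), time = rep(c(0.8, 1.0), each = 10),
                   amplitude = 80)
  ev0 <- ev; ev0$amplitude <- 0
  with_ev <- gen_sr_sweeps(trn, n_sweeps = 10, events = ev)
  without <- gen_sr_sweeps(trn, n_sweeps = 10, events = ev0)
  expect_identical(estimate_rms_noise(with_ev$sweeps),
                   estimate_rms_noise(without$sweeps))
})

test_that("detect_events finds injected events with correct labels and amplitudes", {
  tr <- ephys_truth(noise_rms = 2, seed = 5)
  ev <- data.frame(sweep = 1:10, time = 0.9, amplitude = 15)
  sim <- gen_sr_sweeps(tr, n_sweeps = 10, events = ev)
  det <- detect_events(sim$sweeps, rms = 2)
  expect_equal(nrow(det), 10)
  expect_true(all(det$window == "post"))
  expect_true(all(abs(det$amplitude - 15) < 2))
  expect_true(all(det$rise_time <= 3))
  expect_true(all(abs(det$time - 0.9) < 0.002))

  # an event with 5 ms rise time is excluded by the rise-time filter
  tr_slow <- ephys_truth(rise_ms = 5, decay_ms = 30, noise_rms = 2, seed = 5)
  evs <- data.frame(sweep = 1:10, time = 0.5, amplitude = 15)
  sims <- gen_sr_sweeps(tr_slow, n_sweeps = 10, events = evs)
  dets <- detect_events(sims$sweeps, rms = 2)
  expect_equal(nrow(dets), 0)

  # pure noise: false positives below 0.5 events/s
  trn <- ephys_truth(spont_rate = 0, evoked_rate = 0, noise_rms = 2, seed = 6)
  simn <- gen_sr_sweeps(trn, n_sweeps = 20)
  detn <- detect_events(simn$sweeps, rms = 2)
  expect_lt(nrow(detn) / (20 * 1.5), 0.5)

  expect_error(detect_events(sim$sweeps, rms = 0), "> 0")
})

test_that("window_stats computes frequencies and mean amplitudes", {
  ev <- data.frame(sweep_index = 1, time = 0.5, amplitude = 10,
                   rise_time = 1, window = "pre")[0, ]
  s0 <- window_stats(ev, "pre", n_sweeps = 10)
  expect_equal(s0$freq, 0)
  expect_false(s0$amp_defined)
  expect_true(is.na(s0$amp))

  ev8 <- data.frame(sweep_index = rep(1:4, 2), time = 0.5,
                    amplitude = rep(c(10, 20), 4),
                    rise_time = 1, window = "pre")
  s8 <- window_stats(ev8, "pre", n_sweeps = 10)
  expect_equal(s8$freq, 8 / (10 * 0.4))   # 2.0 events/s
  expect_equal(s8$amp, 15)
})

test_that("evoked_quantal_amplitude: limits, identity, and exclusion signal", {
  # no-spontaneous limit
  expect_equal(evoked_quantal_amplitude(NA, 0, 17.3, 5), 17.3)
  # equal-amplitude fixed point
  expect_equal(evoked_quantal_amplitude(14, 2, 14, 6), 14)
  # worked example
  expect_equal(evoked_quantal_amplitude(10, 2, 20, 6), 25)
  # no rate increase is a classed signal
  expect_error(evoked_quantal_amplitude(10, 5, 20, 5),
               class = "odplast_no_rate_increase")
  expect_error(evoked_quantal_amplitude(10, 6, 20, 5),
               class = "odplast_no_rate_increase")
})

test_that("correction removes the spontaneous contribution algebraically", {
  # idealized design: the same spontaneous set S contributes to both windows;
  # the corrected amplitude is then exactly mean(E), and shifting every
  # evoked amplitude by delta shifts the estimate by delta
  set.seed(11)
  for (rep in 1:20) {
    S <- runif(sample(0:8, 1), 5, 30)
    E <- runif(sample(1:10, 1), 5, 30)
    nsw <- 10; w <- 0.4
    pre_f <- length(S) / (nsw * w)
    post_f <- (length(S) + length(E)) / (nsw * w)
    pre_a <- if (length(S)) mean(S) else NA
    post_a <- mean(c(S, E))
    expect_equal(evoked_quantal_amplitude(pre_a, pre_f, post_a, post_f),
                 mean(E), tolerance = 1e-12)
    d <- 3.7
    expect_equal(evoked_quantal_amplitude(pre_a, pre_f, mean(c(S, E + d)), post_f),
                 mean(E) + d, tolerance = 1e-12)
  }
})

test_that("correction is unbiased when spontaneous and evoked amplitudes match", {
  # equal amplitude distributions: the corrected estimate should recover the
  # common mean with < 2% bias (aggregated over > 500 evoked events)
  ests <- numeric(8)
  for (s in seq_along(ests)) {
    tr <- ephys_truth(spont_amp_mean = 15, evoked_amp_mean = 15,
                      noise_rms = 1.5, seed = 40 + s)
    sim <- gen_sr_sweeps(tr, n_sweeps = 40)
    est <- analyze_cell(sim$sweeps)
    ests[s] <- est$evoked_amp
  }
  expect_lt(abs(mean(ests, na.rm = TRUE) / 15 - 1), 0.02)
})

test_that("analyze_cell applies the exclusion rules", {
  # RMS ~ 3 pA -> excluded, reason rms_noise
  tr3 <- ephys_truth(noise_rms = 3, seed = 8)
  est3 <- analyze_cell(gen_sr_sweeps(tr3, n_sweeps = 10)$sweeps)
  expect_false(est3$included)
  expect_equal(est3$exclusion_reason, "rms_noise")
  expect_gt(est3$rms, 2)

  # no events at all -> post rate does not exceed pre rate
  tr0 <- ephys_truth(spont_rate = 0, evoked_rate = 0, noise_rms = 1.5, seed = 9)
  est0 <- analyze_cell(gen_sr_sweeps(tr0, n_sweeps = 10)$sweeps)
  expect_false(est0$included)
  expect_equal(est0$exclusion_reason, "no_rate_increase")
  expect_true(is.na(est0$evoked_amp))
})
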