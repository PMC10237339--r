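test_that("the -70 mV correction is exact at reference and scales linearly", {
  expect_equal(correct_to_minus70(1.0, -70), 1.0)
  expect_equal(correct_to_minus70(1.0, -50), 1.4)
  expect_equal(correct_to_minus70(2.0, -100), 1.4)
  # linear in amplitude
  expect_equal(correct_to_minus70(3.7, -62), 3.7 * correct_to_minus70(1, -62))
  expect_error(correct_to_minus70(1.0, 10), "negative")
  expect_error(correct_to_minus70(-1.0, -70), "positive")
})

test_that("quantal content reproduces hand-computed Martin-corrected values", {
  expect_equal(quantal_content(20, 2, 70, 0), 10)          # f = 0: plain E/M
  expect_equal(quantal_content(20, 1.0, 70, 0.8), 25.92593, tolerance = 1e-6)
  expect_equal(quantal_content(20, 1.0, 70, 0.8),
               20 / (1 - 0.8 * 20 / 70), tolerance = 1e-12)
  expect_error(quantal_content(70, 1, 70, 1.0), "non-linear summation")
  expect_error(quantal_content(-1, 1, 70, 0.8), "positive")
  # Vm accepted as a magnitude regardless of sign convention
  expect_equal(quantal_content(20, 1, -70, 0.8), quantal_content(20, 1, 70, 0.8))
})

test_that("quantal content is increasing in E and decreasing in M", {
  E <- seq(5, 40, by = 5)
  qc_e <- quantal_content(E, 1, 70, 0.8)
  expect_true(all(diff(qc_e) > 0))
  M <- seq(0.5, 2, by = 0.25)
  qc_m <- quantal_content(20, M, 70, 0.8)
  expect_true(all(diff(qc_m) < 0))
})

test_that("miniature frequency is included events over duration", {
  ev <- tibble::tibble(kind = rep("mEPP", 30), included = TRUE)
  expect_equal(mepp_frequency(ev, 30), 1.0)
  expect_equal(mepp_frequency(ev[0, ], 30), 0.0)
  expect_error(mepp_frequency(ev, 0), "duration")
  # Poisson oracle: grand mean over many simulated junctions approaches the rate
  sc <- build_scenario(4, "WT")  # 0.8 /s
  freqs <- vapply(1:25, function(i) {
    sim <- simulate_recording(sc, protocol_spontaneous(), seed = 300 + i)
    mepp_frequency(detect_mepps(sim$trace), 30)
  }, numeric(1))
  se <- sqrt(sc$mepp_rate / 30 / 25)
  expect_lt(abs(mean(freqs) - sc$mepp_rate), 3 * se + 0.05 * sc$mepp_rate)
})

test_that("detection recovers noiseless events exactly and flat traces give none", {
  sc <- build_scenario(12, "WT")
  sc$noise_sd <- 0
  sc$rmp_drift_sd <- 0
  sim <- simulate_recording(sc, protocol_spontaneous(), seed = 21)
  ev <- detect_mepps(sim$trace)
  gt <- sim$ground_truth
  expect_equal(nrow(ev), nrow(gt))
  # amplitudes within 5% of truth (merge-free seed; exact template match)
  matched <- vapply(gt$event_time, function(t) {
    which.min(abs(ev$event_time - t))
  }, integer(1))
  expect_true(all(abs(ev$amplitude_raw[matched] / gt$true_amplitude - 1) < 0.05))

  flat <- sc
  flat$mepp_rate <- 0
  sim0 <- simulate_recording(flat, protocol_spontaneous(5), seed = 1)
  expect_equal(nrow(detect_mepps(sim0$trace)), 0L)
})

test_that("detection rejects degenerate traces", {
  sc <- build_scenario(12, "WT")
  short <- simulate_recording(sc, protocol_spontaneous(0.5), seed = 1)$trace
  expect_error(detect_mepps(short), "shorter than 1 s")
  nan_trace <- simulate_recording(sc, protocol_spontaneous(2), seed = 1)$trace
  nan_trace$samples[] <- NaN
  expect_error(detect_mepps(nan_trace), "NaN")
  slow <- simulate_recording(sc, protocol_spontaneous(2), seed = 1, sampling_rate = 20000)$trace
  slow$sampling_rate <- 5000
  expect_error(detect_mepps(slow), "10 kHz")
})

test_that("events after the fiber depolarizes beyond -50 mV are rejected", {
  dep <- scenario_depolarized(build_scenario(12, "SOD1"))
  sim <- simulate_recording(dep, protocol_spontaneous(), seed = 42)
  ev <- detect_mepps(sim$trace)
  rej <- ev$exclusion_reason == "rmp_above_minus50"
  expect_gt(sum(rej, na.rm = TRUE), 0)
  # rejection applies from the first crossing onwards
  first_bad <- min(ev$event_time[which(rej)])
  expect_true(all(!ev$included[ev$event_time >= first_bad]))
})

test_that("evoked responses with slow rise times are excluded", {
  sc <- build_scenario(12, "WT")
  sc$rise_time <- 2.2  # slower than the 1.5 ms focal-recording criterion
  sim <- simulate_recording(sc, protocol_evoked(), seed = 5)
  ev <- measure_epps(sim$trace)
  expect_true(all(!ev$included))
  expect_true(all(ev$exclusion_reason == "rise_time_above_1p5ms"))

  ok <- simulate_recording(build_scenario(12, "WT"), protocol_evoked(), seed = 5)
  ev_ok <- measure_epps(ok$trace)
  expect_true(all(ev_ok$included))
  expect_true(all(ev_ok$rise_time <= 1.5))
})

test_that("rundown profiles normalize to the first pulse", {
  prof <- rundown_profile(rep(20, 400))
  expect_equal(prof$normalized_amplitude, rep(1, 400))
  expect_equal(prof$late_plateau, 1)
  expect_error(rundown_profile(c(0, 1)), "first amplitude")
  expect_error(rundown_profile(5), "2 pulses")

  # pure depletion: measured normalized profile is non-increasing once the
  # confounds (noise, membrane-potential drift) are switched off
  sc <- build_scenario(12, "WT")
  sc$replenish_rate <- 0
  sc$noise_sd <- 0
  sc$rmp_drift_sd <- 0
  tr <- simulate_train(sc, seed = 2)
  prof0 <- rundown_profile(train_amplitudes(tr$trace))
  expect_true(all(diff(prof0$normalized_amplitude) <= 1e-9))
})

test_that("the quantal rundown plateau matches the depletion steady state", {
  sc <- build_scenario(20, "SOD1")
  tr <- simulate_train(sc, seed = 9)
  amps <- train_amplitudes(tr$trace)
  m <- sc$mepp_mean
  # convert measured amplitudes back to quanta before normalizing: non-linear
  # summation compresses large pulses more than the depressed steady state
  qc_pulse <- quantal_content(pmax(amps, 1e-6), m, 70, 0.8)
  plateau_qc <- mean(tail(qc_pulse, 200)) / qc_pulse[1]
  n_star <- steady_state_pool(sc$release_fraction, sc$replenish_rate, sc$pool_size)
  expect_equal(plateau_qc, n_star / sc$pool_size, tolerance = 0.05)
})

test_that("junction summaries aggregate and flag missing components", {
  sc <- build_scenario(20, "WT")
  spont <- simulate_recording(sc, protocol_spontaneous(), seed = 31)
  evoked <- simulate_recording(sc, protocol_evoked(), seed = 32)
  s <- summarize_nmj(detect_mepps(spont$trace), measure_epps(evoked$trace))
  expect_equal(s$qc_flag, "ok")
  expect_gt(s$qc, 0)
  expect_equal(s$mepp_mean_corrected, sc$mepp_mean, tolerance = 0.15)
  expect_equal(s$epp_mean_corrected, sc$epp_mean, tolerance = 0.1 * sc$epp_mean)

  # all miniatures excluded -> QC undefined, explicitly flagged
  mepps <- detect_mepps(spont$trace)
  mepps$included <- FALSE
  s2 <- summarize_nmj(mepps, measure_epps(evoked$trace))
  expect_true(is.na(s2$qc))
  expect_equal(s2$qc_flag, "undefined_no_included_mepps")
  expect_true(is.na(s2$mepp_mean_corrected))
})
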