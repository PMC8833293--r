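test_that("study generation is deterministic and structurally complete", {
  cfg <- quick_config(rest_duration = 2,
                      burst_protocol = stim_protocol(duration_s = 2))
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  expect_length(s1$hemispheres, 2)
  for (h in s1$hemispheres) {
    expect_s3_class(h$geometry, "contact_geometry")
    expect_s3_class(h$outcome, "outcome_record")
    # truth best contact is the argmax of expected benefit
    avail <- which(!h$params$missing) - 1L
    expect_equal(h$truth$best_contact,
                 avail[which.max(h$truth$expected_benefit[avail + 1])])
  }
  # recordings keyed by hemisphere, burst segment per non-missing contact
  for (side in c("left", "right")) {
    hp <- s1$hemispheres[[paste0("P01_", side)]]$params
    expect_setequal(names(s1$patients$P01$bursts[[side]]),
                    as.character(which(!hp$missing) - 1L))
  }
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(study_config(beta_peak_prob = 1.4),
               "beta_peak_prob", class = "ernarank_config_error")
  expect_error(study_config(fs = 500), "fs",
               class = "ernarank_config_error")
  expect_error(study_config(n_patients = 0), "n_patients",
               class = "ernarank_config_error")
  expect_error(study_config(spatial_lambda = -1), "spatial_lambda",
               class = "ernarank_config_error")
  expect_error(stim_protocol(pulses_per_burst = 1),
               class = "ernarank_config_error")
})

test_that("one forced fault in a 28-hemisphere cohort leaves 111 recorded contacts", {
  cfg <- study_config(n_patients = 14, hemispheres_per_patient = 2,
                      fs = 800, rest_duration = 1,
                      burst_protocol = stim_protocol(duration_s = 2),
                      force_one_missing = TRUE, seed = 77)
  st <- generate_study(cfg)
  expect_length(st$hemispheres, 28)
  n_rec <- sum(vapply(st$hemispheres,
                      function(h) sum(!h$params$missing), numeric(1)))
  expect_equal(n_rec, 111)
  # the faulted contact is ventral (contact 0)
  faulted <- vapply(st$hemispheres, function(h) h$params$missing[1],
                    logical(1))
  expect_equal(sum(faulted), 1L)
})

test_that("rest LFP spectrum obeys Parseval and reflects its components", {
  cfg <- quick_config(fs = 4800, rest_duration = 6, line_amplitude = 0,
                      spike_prob = 0)
  hp <- quick_hp(has_beta = TRUE, has_hfo = TRUE)
  rec <- synth_rest_lfp(hp, cfg, seed = 5)
  x <- rec$signal[3, ]
  # Parseval: total variance equals the periodogram integral
  n <- length(x)
  pgram_int <- sum(Mod(fft(x)[-1])^2) / n^2
  expect_equal(pgram_int, mean((x - mean(x))^2), tolerance = 0.05)
  ps <- psd_stft_blackmanharris(x, cfg$fs)

  # line amplitude 0: no bin in 49-51 Hz stands out from its neighbours
  sel <- ps$frequency >= 49 & ps$frequency <= 51
  near <- ps$frequency >= 40 & ps$frequency <= 60
  expect_lt(max(ps$density[sel]), 3 * median(ps$density[near]))

  # beta component off: 13-30 Hz power matches the background-only signal
  cfg0 <- quick_config(fs = 4800, rest_duration = 6, line_amplitude = 0,
                       spike_prob = 0, beta_amplitude = 0)
  rec0 <- synth_rest_lfp(quick_hp(has_beta = TRUE), cfg0, seed = 5)
  p_with <- band_power(psd_stft_blackmanharris(rec0$signal[3, ], cfg0$fs),
                       13, 30)
  recb <- synth_rest_lfp(quick_hp(has_beta = FALSE), cfg0, seed = 5)
  p_bg <- band_power(psd_stft_blackmanharris(recb$signal[3, ], cfg0$fs),
                     13, 30)
  expect_equal(p_with, p_bg, tolerance = 0.10)
})

test_that("doubling the beta source amplitude quadruples beta band power", {
  ratios <- vapply(1:20, function(s) {
    hp <- quick_hp()
    c1 <- study_config(rest_duration = 4, background_rms = 1,
                       line_amplitude = 0, seed = s)
    c2 <- study_config(rest_duration = 4, background_rms = 1,
                       line_amplitude = 0, beta_amplitude = 12, seed = s)
    p1 <- band_power(psd_stft_blackmanharris(
      synth_rest_lfp(hp, c1, seed = s)$signal[3, ], c1$fs), 13, 30)
    p2 <- band_power(psd_stft_blackmanharris(
      synth_rest_lfp(hp, c2, seed = s)$signal[3, ], c2$fs), 13, 30)
    p2 / p1
  }, numeric(1))
  expect_equal(mean(ratios), 4, tolerance = 0.15)
})

test_that("burst protocol emits 10 bursts of 10 pulses and guards faults", {
  cfg <- quick_config()
  rec <- synth_burst_recording(quick_hp(), cfg, stim_contact = 2,
                               seed = 1)
  # protocol truncated to segment duration: 3 bursts here
  expect_length(rec$pulse_times, 3)
  full <- protocol_pulse_times(stim_protocol())
  expect_length(full, 10)
  expect_equal(lengths(full), rep(10L, 10))
  expect_length(unlist(full), 100)

  hp_miss <- quick_hp(missing = c(TRUE, FALSE, FALSE, FALSE))
  expect_error(synth_burst_recording(hp_miss, cfg, stim_contact = 0),
               class = "ernarank_fault_error")
})

test_that("without ERNA the post-burst window is indistinguishable from baseline", {
  cfg <- quick_config(erna_amplitude = 0, artifact_rail = 0,
                      line_amplitude = 0, fs = 1600)
  post <- numeric(20)
  pre <- numeric(20)
  for (s in 1:20) {
    rec <- synth_burst_recording(quick_hp(), cfg, 0, seed = s)
    fs <- rec$fs
    last <- max(rec$pulse_times[[2]])
    i_post <- round((last + 0.004) * fs):round((last + 0.020) * fs)
    i_pre <- round((rec$pulse_times[[2]][1] - 0.020) * fs):
      round((rec$pulse_times[[2]][1] - 0.004) * fs)
    post[s] <- rms(rec$signal[3, i_post])
    pre[s] <- rms(rec$signal[3, i_pre])
  }
  expect_gt(t.test(post, pre)$p.value, 0.01)
})

test_that("noise-free burst RMS decreases strictly with contact-source distance", {
  cfg <- quick_config(background_rms = 0, line_amplitude = 0,
                      spike_prob = 0, artifact_rail = 0, fs = 4800)
  hp <- quick_hp()
  rec <- synth_burst_recording(hp, cfg, 0, seed = 3)
  fs <- rec$fs
  vals <- vapply(2:4, function(ch) {
    last <- max(rec$pulse_times[[1]])
    idx <- round((last + 0.004) * fs):round((last + 0.020) * fs)
    rms(rec$signal[ch, idx])
  }, numeric(1))
  d <- hp$distances[2:4]
  expect_true(all(diff(vals[order(d)]) < 0))
})

test_that("outcome generator respects its construction rules", {
  cfg <- quick_config(benefit_noise_sd = 0, side_effect_max = 0,
                      patient_sd = 0)
  d <- c(5, 3, 0.8, 2.5)
  o <- synth_outcomes(d, rep(FALSE, 4), cfg, seed = 4)
  expect_true(all(o$stim_fraction == 1))
  ben <- compute_benefit(o$off_updrs, o$on_updrs)
  expect_equal(which.max(ben) - 1L, which.min(d) - 1L)
  expect_true(all(ben <= 100))
  expect_setequal(o$order_index, 1:4)

  # side effects on: fractions restricted to the tolerated set
  cfg2 <- quick_config(side_effect_max = 1, side_effect_lambda = 0.5)
  o2 <- synth_outcomes(d, rep(FALSE, 4), cfg2, seed = 5)
  expect_true(all(o2$stim_fraction %in% c(1, 0.75, 0.5, 0.25)))

  # benefit computed from emitted scores never exceeds 100
  for (s in 1:25) {
    oo <- synth_outcomes(d, rep(FALSE, 4), quick_config(), seed = s)
    expect_true(all(compute_benefit(oo$off_updrs, oo$on_updrs) <= 100))
  }
})

test_that("condition order is counterbalanced across hemispheres", {
  cfg <- quick_config()
  ords <- t(vapply(1:4, function(r)
    synth_outcomes(c(5, 3, 1, 2), rep(FALSE, 4), cfg, order_row = r,
                   seed = r)$order_index, numeric(4)))
  # a balanced Latin square: each contact takes each position once
  for (j in 1:4) expect_setequal(ords[, j], 1:4)
  for (i in 1:4) expect_setequal(ords[i, ], 1:4)
})

test_that("detected beta-peak prevalence tracks the configured probability", {
  # binomial check: 1000 hemispheres at p = 19/28
  p <- 19 / 28
  cfg <- study_config(rest_duration = 15, seed = 1)
  set.seed(2024)
  hits <- vapply(1:1000, function(i) {
    hp <- hemisphere_params(distances = c(6, 3.5, 1, 2.2),
                            has_beta = runif(1) < p,
                            beta_freq = runif(1, 16, 24))
    rec <- synth_rest_lfp(hp, cfg)
    ps <- psd_stft_blackmanharris(rec$signal[3, ], cfg$fs)
    detect_band_peak(ps, c(13, 30))$present
  }, logical(1))
  half <- qnorm(0.995) * sqrt(p * (1 - p) / 1000)
  expect_gt(mean(hits), p - half)
  expect_lt(mean(hits), p + half)
})

test_that("outcome-level simulator exposes only the configured effects", {
  tab <- simulate_rank_table(effects = c(erna = 15, beta = 0),
                             noise_sd = 0, patient_sd = 0,
                             reduction_probs = c(1, 0, 0, 0), seed = 8)
  # benefit strictly decreasing in the informative factor's rank
  for (h in split(tab, tab$hemisphere))
    expect_true(all(diff(h$benefit[order(h$rank_erna)]) < 0))
  expect_equal(nrow(tab), 14 * 2 * 4)
  expect_true(all(tab$stim_fraction == 1))
})
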