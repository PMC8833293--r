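test_that("evoked extraction recovers the injected damped sinusoid", {
  cfg <- quick_config(background_rms = 0, line_amplitude = 0,
                      spike_prob = 0, artifact_rail = 0, fs = 4800)
  hp <- quick_hp()
  rec <- synth_burst_recording(hp, cfg, 0, seed = 1)
  attr(rec, "pulse_width_us") <- cfg$burst_protocol$pulse_width_us
  w <- extract_evoked(rec, 2)
  sel <- w$time >= 4 & w$time < 20
  # template evaluated on the epoch's actual sample grid
  fs <- rec$fs
  last <- max(rec$pulse_times[[1]])
  pw2 <- 2 * cfg$burst_protocol$pulse_width_us * 1e-6
  i_epoch <- round((last + pw2) * fs) + 1
  i_erna <- round((last + pw2 + cfg$erna_onset_ms / 1000) * fs) + 1
  tt <- (i_epoch + which(sel) - 1 - i_erna) / fs
  template <- exp(-tt / (cfg$erna_decay_tau / 1000)) *
    sin(2 * pi * cfg$erna_freq * tt)
  expect_gt(cor(w$amplitude[sel], template), 0.99)
  expect_equal(w$n_bursts_averaged, length(rec$pulse_times))
})

test_that("evoked extraction is invariant to linear ramps and zero input", {
  cfg <- quick_config(background_rms = 0, line_amplitude = 0,
                      spike_prob = 0, artifact_rail = 0, fs = 1600)
  rec <- synth_burst_recording(quick_hp(), cfg, 0, seed = 2)
  w0 <- extract_evoked(rec, 1)
  ramped <- rec
  ramped$signal[2, ] <- rec$signal[2, ] +
    seq(0, 10, length.out = ncol(rec$signal))
  w1 <- extract_evoked(ramped, 1)
  expect_equal(w1$amplitude, w0$amplitude, tolerance = 1e-9)

  zero <- rec
  zero$signal[] <- 0
  expect_equal(max(abs(extract_evoked(zero, 1)$amplitude)), 0)

  expect_error(extract_evoked(rec, rec$stim_contact),
               class = "ernarank_usage_error")
  miss <- rec
  miss$channel_map$missing[2] <- TRUE
  expect_error(extract_evoked(miss, 1), class = "ernarank_fault_error")
})

test_that("window RMS matches closed forms and a direct loop oracle", {
  const <- structure(list(time = seq(0, 49.9, by = 0.5),
                          amplitude = rep(2, 100)),
                     class = "evoked_waveform")
  expect_equal(rms_in_window(const, 4, 20), 2)

  two <- structure(list(time = c(4, 5), amplitude = c(3, 4)),
                   class = "evoked_waveform")
  expect_equal(rms_in_window(two, 4, 20), sqrt((9 + 16) / 2))

  # sinusoid with integer cycles in the window -> A / sqrt(2)
  fs <- 4000
  tms <- seq(0, 50, by = 1000 / fs)
  wv <- structure(list(time = tms, amplitude = 6 * sin(2 * pi * 250 *
                                                         tms / 1000)),
                  class = "evoked_waveform")
  expect_equal(rms_in_window(wv, 4, 20), 6 / sqrt(2), tolerance = 0.01)

  expect_error(rms_in_window(two, 30, 40),
               class = "ernarank_window_error")

  # oracle: loop-computed RMS on a short epoch
  set.seed(9)
  amp <- rnorm(80)
  w <- structure(list(time = seq(0, 39.5, by = 0.5), amplitude = amp),
                 class = "evoked_waveform")
  sel <- which(w$time >= 4 & w$time < 20)
  acc <- 0
  for (i in sel) acc <- acc + amp[i]^2
  expect_equal(rms_in_window(w, 4, 20), sqrt(acc / length(sel)),
               tolerance = 1e-12)
})

test_that("ERNA power aggregates available conditions as a squared mean", {
  expect_equal(erna_power(c(2, 3, 4))$power, 9)
  r <- erna_power(c(5, NA, NA))
  expect_equal(r$power, 25)
  expect_equal(r$n_conditions, 1L)
  expect_equal(erna_power(c(0, 0, 0))$power, 0)
  none <- erna_power(c(NA_real_, NA_real_, NA_real_))
  expect_true(none$missing)
  expect_true(is.na(none$power))
})

test_that("lead features rank contacts by proximity and key by contact, not channel", {
  cfg <- quick_config(background_rms = 0.05, line_amplitude = 0,
                      spike_prob = 0, benefit_noise_sd = 0,
                      missing_channel_prob = 0, fs = 1600, seed = 12)
  st <- generate_study(cfg)
  key <- "P01_left"
  f <- erna_features_for_lead(st, key)
  h <- st$hemispheres[[key]]
  expect_equal(order(-f$erna_power), order(h$params$erna_distances))
  expect_equal(f$n_conditions, rep(3L, 4))

  # permuting channel order in the container leaves features unchanged
  st2 <- st
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  for (sc in names(st2$patients$P01$bursts$left)) {
    seg <- st2$patients$P01$bursts$left[[sc]]
    seg$signal <- seg$signal[perm, ]
    seg$channel_map <- seg$channel_map[perm, ]
    st2$patients$P01$bursts$left[[sc]] <- seg
  }
  f2 <- erna_features_for_lead(st2, key)
  expect_equal(f2$erna_power, f$erna_power, tolerance = 1e-12)
})

test_that("ERNA power scales quadratically and ignores out-of-window content", {
  cfg <- quick_config(background_rms = 0, line_amplitude = 0,
                      spike_prob = 0, artifact_rail = 0, fs = 1600)
  rec <- synth_burst_recording(quick_hp(), cfg, 0, seed = 4)
  attr(rec, "pulse_width_us") <- cfg$burst_protocol$pulse_width_us
  p1 <- rms_in_window(extract_evoked(rec, 2))^2
  scaled <- rec
  scaled$signal <- rec$signal * 3
  p3 <- rms_in_window(extract_evoked(scaled, 2))^2
  expect_equal(p3 / p1, 9, tolerance = 1e-9)

  # modifying the signal outside every epoch window leaves power unchanged
  fs <- rec$fs
  mod <- rec
  protect <- rep(FALSE, ncol(rec$signal))
  for (b in rec$pulse_times) {
    i0 <- round(max(b) * fs)
    protect[max(1, i0 - 5):min(ncol(rec$signal), i0 + 0.060 * fs)] <- TRUE
  }
  mod$signal[3, !protect] <- mod$signal[3, !protect] + 40
  # note: constant offsets inside untouched epochs are irrelevant anyway;
  # this perturbs only samples outside [epoch start - guard, epoch end]
  p_mod <- rms_in_window(extract_evoked(mod, 2))^2
  expect_equal(p_mod, p1, tolerance = 1e-9)
})

test_that("a missing contact yields a flagged feature row, not an error", {
  cfg <- quick_config(fs = 1600, background_rms = 0.1, line_amplitude = 0,
                      spike_prob = 0, seed = 31)
  st <- generate_study(cfg)
  key <- "P01_left"
  st$hemispheres[[key]]$params$missing <- c(TRUE, FALSE, FALSE, FALSE)
  for (sc in names(st$patients$P01$bursts$left)) {
    seg <- st$patients$P01$bursts$left[[sc]]
    seg$channel_map$missing[seg$channel_map$side == "left" &
                              seg$channel_map$contact == 0] <- TRUE
    st$patients$P01$bursts$left[[sc]] <- seg
  }
  st$patients$P01$bursts$left[["0"]] <- NULL
  f <- erna_features_for_lead(st, key)
  expect_true(f$missing[1])
  expect_true(is.na(f$erna_power[1]))
  expect_equal(sum(!is.na(f$erna_power)), 3)
  expect_equal(f$n_conditions[2:4], rep(2L, 3))
})
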