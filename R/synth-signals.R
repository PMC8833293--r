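# Signal-level synthesis: phenomenological LFP/ERNA generators.
# All components are built in closed form or by FFT spectral shaping of
# white noise; no biophysical modelling is attempted.

# 1/f^alpha background noise via FFT shaping, scaled to a target RMS.
# Spectrum is flattened below 1 Hz to keep total power finite.
colored_noise <- function(n, fs, alpha = 1.5, rms = 1) {
  if (rms == 0) return(numeric(n))
  x <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  shape <- 1 / pmax(f, 1)^(alpha / 2)
  shape[1] <- 0                             # no DC
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y * rms / sd(y)
}

# Narrowband Gaussian process: white noise shaped by a Gaussian spectral
# bump centred at f0 with SD bw (Hz), unit or target RMS.
narrowband_noise <- function(n, fs, f0, bw, rms = 1) {
  if (rms == 0) return(numeric(n))
  x <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)
  shape <- exp(-(f - f0)^2 / (2 * bw^2))
  shape[1] <- 0
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y * rms / sd(y)
}

#' Per-hemisphere generation parameters
#'
#' Latent parameters of one synthetic hemisphere: distance of each contact
#' from the dorsal-STN signal source, which spectral components are
#' present, and per-channel interference gains. Normally created inside
#' [generate_study()]; exposed so the signal generators can be driven
#' directly in tests and examples.
#'
#' @param distances contact distances (mm, contacts 0-3) to the latent
#'   benefit source.
#' @param erna_distances,beta_distances,hfo_distances contact distances
#'   to each modality's own source; default to `distances` (perfectly
#'   co-localized signals).
#' @param side hemisphere side.
#' @param missing logical, length 4; faulted contacts.
#' @param has_beta,has_hfo whether a visible beta / HFO bump is present.
#' @param beta_freq,hfo_freq bump centre frequencies, Hz.
#' @param beta_bw,hfo_bw bump spectral SDs, Hz.
#' @param spike_freqs narrowband interference tones in 200-400 Hz
#'   (numeric, possibly empty).
#' @param line_gains,spike_gains per-channel multiplicative gains for the
#'   mains and spike tones (imperfect common-mode coupling).
#' @param background_gains per-channel multiplicative gains of the
#'   aperiodic background.
#' @param artifact_gains per-channel gains of the stimulation-artifact
#'   transient. The artifact couples through the shared recording
#'   reference, so it appears on both leads and is largely removed by
#'   contralateral re-referencing; gain jitter controls the residual.
#' @return A list of class `hemisphere_params`.
#' @export
hemisphere_params <- function(distances,
                              erna_distances = distances,
                              beta_distances = distances,
                              hfo_distances = distances,
                              side = "left",
                              missing = rep(FALSE, 4),
                              has_beta = TRUE, has_hfo = FALSE,
                              beta_freq = 20, hfo_freq = 275,
                              beta_bw = 2.5, hfo_bw = 40,
                              spike_freqs = numeric(),
                              line_gains = rep(1, 4),
                              spike_gains = rep(1, 4),
                              artifact_gains = rep(1, 4),
                              background_gains = rep(1, 4)) {
  stopifnot(length(distances) == 4, length(missing) == 4)
  structure(as.list(environment()), class = "hemisphere_params")
}

# clipped biphasic stimulation-artifact transient: n_phase samples at
# +rail then -rail from each pulse onset (2 samples per phase at 4.8 kHz,
# scaled with fs)
add_pulse_artifact <- function(x, fs, pulse_times, rail, gain = 1) {
  if (rail == 0) return(x)
  n <- length(x)
  n_phase <- max(1L, round(2 * fs / 4800))
  for (p in round(unlist(pulse_times) * fs) + 1L) {
    up <- p:min(n, p + n_phase - 1L)
    dn <- (p + n_phase):min(n, p + 2L * n_phase - 1L)
    x[up] <- gain * rail
    x[dn] <- -gain * rail
  }
  x
}

# shared deterministic components (line + interference tones) for one
# channel; t in seconds, phases fixed per hemisphere via `phases`
interference_wave <- function(t, config, hp, channel, phases) {
  w <- config$line_amplitude * hp$line_gains[channel] *
    (sin(2 * pi * config$line_freq * t + phases$line) +
       0.3 * sin(2 * pi * 3 * config$line_freq * t + phases$line3))
  if (length(hp$spike_freqs)) {
    for (k in seq_along(hp$spike_freqs)) {
      w <- w + config$spike_amplitude * hp$spike_gains[channel] *
        sin(2 * pi * hp$spike_freqs[k] * t + phases$spike[k])
    }
  }
  w
}

#' Synthesize a resting LFP segment for one hemisphere
#'
#' Each contact's signal is the sum of a 1/f^alpha background, an optional
#' narrowband beta (13-30 Hz) component, an optional HFO (200-400 Hz)
#' component, mains interference with a weak third harmonic, and optional
#' sharp interference tones in 200-400 Hz. The neural components
#' (background, beta, HFO) share one waveform per hemisphere and scale
#' with `exp(-d / spatial_lambda)` of the contact-source distance, so with
#' the background turned off their band powers are strictly decreasing in
#' distance.
#'
#' @param hp a [hemisphere_params()].
#' @param config a [study_config()].
#' @param seed optional integer seed.
#' @return A single-lead [lead_recording()] (`kind = "rest"`).
#' @export
synth_rest_lfp <- function(hp, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs
  n <- round(config$rest_duration * fs)
  if (n <= 0) abort("rest_duration must be positive",
                    "ernarank_config_error")
  t <- (seq_len(n) - 1) / fs
  scale_bg <- hp$background_gains *
    exp(-hp$distances / config$background_lambda)
  scale_beta <- exp(-hp$beta_distances / config$spatial_lambda)
  scale_hfo <- exp(-hp$hfo_distances / config$spatial_lambda)
  phases <- list(line = runif(1, 0, 2 * pi), line3 = runif(1, 0, 2 * pi),
                 spike = runif(max(1, length(hp$spike_freqs)), 0, 2 * pi))
  w_beta <- if (hp$has_beta && config$beta_amplitude > 0)
    narrowband_noise(n, fs, hp$beta_freq, hp$beta_bw) else numeric(n)
  w_hfo <- if (hp$has_hfo && config$hfo_amplitude > 0)
    narrowband_noise(n, fs, hp$hfo_freq, hp$hfo_bw) else numeric(n)
  sig <- matrix(NA_real_, nrow = 4, ncol = n)
  for (c in 1:4) {
    if (hp$missing[c]) next
    bg <- colored_noise(n, fs, config$background_alpha,
                        config$background_rms * scale_bg[c])
    sig[c, ] <- bg +
      config$beta_amplitude * scale_beta[c] * w_beta +
      config$hfo_amplitude * scale_hfo[c] * w_hfo +
      interference_wave(t, config, hp, c, phases)
  }
  lead_recording(sig, fs,
                 data.frame(side = hp$side, contact = 0:3,
                            missing = hp$missing),
                 kind = "rest")
}

# damped sinusoid a * exp(-t/tau) * sin(2*pi*f*t) sampled at fs, length n
erna_waveform <- function(n, fs, amplitude, freq, tau_ms) {
  tt <- (seq_len(n) - 1) / fs
  amplitude * exp(-tt / (tau_ms / 1000)) * sin(2 * pi * freq * tt)
}

#' Synthesize a burst-stimulation segment for one hemisphere
#'
#' Produces the four monopolar channels of the stimulated lead during a
#' burst protocol: 1/f background plus interference, a clipped biphasic
#' stimulation-artifact transient at every pulse, and — beginning
#' `erna_onset_ms` after the offset of the last pulse of each burst — a
#' damped sinusoid (the ERNA) whose amplitude at contact `c` is
#' `erna_amplitude * exp(-d_c / spatial_lambda)`.
#'
#' @inheritParams synth_rest_lfp
#' @param stim_contact stimulated contact index, 0-3 (must not be
#'   missing).
#' @return A single-lead [lead_recording()] (`kind = "burst"`) carrying
#'   the grouped pulse timestamps.
#' @export
synth_burst_recording <- function(hp, config, stim_contact, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (hp$missing[stim_contact + 1])
    abort(sprintf("cannot stimulate missing contact %d", stim_contact),
          "ernarank_fault_error")
  proto <- config$burst_protocol
  fs <- config$fs
  n <- round(proto$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  bursts <- protocol_pulse_times(proto)
  pw_s <- proto$pulse_width_us * 1e-6
  scale <- exp(-hp$erna_distances / config$spatial_lambda)
  scale_bg <- hp$background_gains *
    exp(-hp$distances / config$background_lambda)
  phases <- list(line = runif(1, 0, 2 * pi), line3 = runif(1, 0, 2 * pi),
                 spike = runif(max(1, length(hp$spike_freqs)), 0, 2 * pi))

  # ERNA template added after each burst (identical across bursts)
  n_erna <- min(n, round(0.045 * fs))
  erna_t0 <- vapply(bursts, function(b)
    b[length(b)] + 2 * pw_s + config$erna_onset_ms / 1000, numeric(1))
  sig <- matrix(NA_real_, nrow = 4, ncol = n)
  for (c in 1:4) {
    if (hp$missing[c]) next
    bg <- colored_noise(n, fs, config$background_alpha,
                        config$background_rms * scale_bg[c])
    x <- bg + interference_wave(t, config, hp, c, phases)
    amp <- config$erna_amplitude * scale[c]
    if (amp > 0) {
      w <- erna_waveform(n_erna, fs, amp, config$erna_freq,
                         config$erna_decay_tau)
      for (t0 in erna_t0) {
        i0 <- round(t0 * fs) + 1L
        ii <- i0:min(n, i0 + n_erna - 1L)
        x[ii] <- x[ii] + w[seq_along(ii)]
      }
    }
    x <- add_pulse_artifact(x, fs, bursts, config$artifact_rail,
                            hp$artifact_gains[c])
    sig[c, ] <- x
  }
  lead_recording(sig, fs,
                 data.frame(side = hp$side, contact = 0:3,
                            missing = hp$missing),
                 pulse_times = bursts, kind = "burst",
                 stim_contact = stim_contact, stim_side = hp$side)
}
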