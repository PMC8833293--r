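#' Burst stimulation protocol
#'
#' Describes the burst stimulation used to evoke ERNA: short bursts of
#' charge-balanced biphasic pulses, repeated once per second. The defaults
#' are the intraoperative survey settings (3.375 mA, 60 µs per phase,
#' 10 pulses at 130 Hz per burst, 10 s per contact).
#'
#' @param amplitude_mA stimulation current, mA.
#' @param pulse_width_us pulse width per phase, µs.
#' @param intra_burst_rate_hz pulse rate within a burst, Hz.
#' @param pulses_per_burst number of pulses in each burst (>= 2).
#' @param burst_rate_hz burst repetition rate, per second.
#' @param duration_s total duration of the burst segment, s.
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' length(unlist(protocol_pulse_times(p)))  # 100 pulses
#' @export
stim_protocol <- function(amplitude_mA = 3.375, pulse_width_us = 60,
                          intra_burst_rate_hz = 130, pulses_per_burst = 10,
                          burst_rate_hz = 1, duration_s = 10) {
  if (pulses_per_burst < 2)
    abort("pulses_per_burst must be >= 2", "ernarank_config_error")
  if (intra_burst_rate_hz <= burst_rate_hz * pulses_per_burst)
    abort("intra_burst_rate_hz must exceed burst_rate_hz * pulses_per_burst",
          "ernarank_config_error")
  structure(list(amplitude_mA = amplitude_mA, pulse_width_us = pulse_width_us,
                 intra_burst_rate_hz = intra_burst_rate_hz,
                 pulses_per_burst = pulses_per_burst,
                 burst_rate_hz = burst_rate_hz, duration_s = duration_s),
            class = "stim_protocol")
}

#' Pulse timestamps implied by a burst protocol
#'
#' @param protocol a [stim_protocol()].
#' @param t_start time of the first pulse of the first burst, s.
#' @return A list with one numeric vector of pulse times (s) per burst.
#' @export
protocol_pulse_times <- function(protocol, t_start = 0.05) {
  n_bursts <- floor(protocol$duration_s * protocol$burst_rate_hz)
  lapply(seq_len(n_bursts) - 1L, function(k) {
    t_start + k / protocol$burst_rate_hz +
      (seq_len(protocol$pulses_per_burst) - 1L) / protocol$intra_burst_rate_hz
  })
}

#' Configuration of a synthetic study
#'
#' Defines the cohort size, recording parameters, signal amplitudes, their
#' spatial decay away from a latent dorsal-STN source, and the outcome
#' model used by [generate_study()]. Defaults emulate the reference cohort:
#' 14 patients x 2 hemispheres, 15 s rest recordings, 10 s burst
#' stimulation per contact, a visible beta peak in 19/28 hemispheres and a
#' visible HFO peak in 3/28.
#'
#' @param n_patients number of patients (>= 1).
#' @param hemispheres_per_patient hemispheres per patient (1 or 2).
#' @param fs sampling rate, Hz. 4800 keeps runtimes low while leaving the
#'   200-400 Hz HFO band far below Nyquist; 38400 reproduces the original
#'   acquisition rate.
#' @param rest_duration off-stimulation rest segment length, s.
#' @param burst_protocol a [stim_protocol()].
#' @param erna_amplitude ERNA amplitude at the source, µV.
#' @param erna_freq ERNA oscillation frequency, Hz.
#' @param erna_decay_tau ERNA exponential decay constant, ms.
#' @param erna_onset_ms ERNA onset latency after last-pulse offset, ms.
#' @param spatial_lambda exponential decay length (mm) of neural signal
#'   amplitude with contact-source distance.
#' @param erna_source_jitter_sd,beta_source_jitter_sd,hfo_source_jitter_sd
#'   SD (mm per axis) of each modality's own source around the latent
#'   benefit source. The three signals co-localize to the dorsal STN
#'   only imperfectly; small jitter for ERNA and larger jitter for HFO
#'   make ERNA the most faithful proxy of the effective stimulation
#'   site and HFO the least, and keep the three contact rankings
#'   correlated without being collinear.
#' @param background_rms aperiodic (1/f) background RMS at the source, µV.
#' @param background_alpha 1/f^alpha exponent of the background.
#' @param background_lambda decay length (mm) of the aperiodic
#'   background; longer than `spatial_lambda` because broadband activity
#'   is spatially diffuse rather than a localized source.
#' @param background_gain_jitter_sd per-contact log-normal gain jitter
#'   of the background (electrode impedance and local tissue
#'   variability), which limits how informative band power is in
#'   hemispheres without a visible oscillatory peak.
#' @param beta_amplitude RMS of the beta-band component at the source, µV.
#' @param hfo_amplitude RMS of the HFO-band component at the source, µV.
#' @param beta_peak_prob probability a hemisphere has a visible beta bump.
#' @param hfo_peak_prob probability a hemisphere has a visible HFO bump.
#' @param line_freq mains frequency, Hz.
#' @param line_amplitude mains sinusoid amplitude, µV (with a weak third
#'   harmonic; per-channel gain jitter makes common-mode rejection
#'   imperfect, as in real recordings).
#' @param spike_prob probability a hemisphere's recordings carry sharp
#'   narrowband interference tones in 200-400 Hz (mains harmonics).
#' @param spike_amplitude amplitude of each interference tone, µV.
#' @param benefit_max expected motor benefit at the source with full
#'   stimulation amplitude, % UPDRS improvement.
#' @param benefit_lambda exponential decay length (mm) of benefit with
#'   contact-source distance.
#' @param benefit_noise_sd SD of per-contact benefit noise, percentage
#'   points.
#' @param patient_sd SD of the between-patient benefit intercept,
#'   percentage points.
#' @param off_updrs_range range (points) of the hemibody off-stimulation
#'   UPDRS Part III sum (items 20-26).
#' @param missing_channel_prob probability each contact is missing
#'   (technical fault) independently.
#' @param force_one_missing if `TRUE`, exactly one ventral contact in one
#'   hemisphere is missing and `missing_channel_prob` is ignored,
#'   reproducing the single faulted contact of a 28-hemisphere cohort
#'   (111 analysable contacts).
#' @param side_effect_max maximal probability of a side-effect-driven
#'   amplitude reduction (reached far from the source).
#' @param side_effect_lambda distance scale (mm) of the side-effect
#'   probability rise.
#' @param clinician_error_prob probability the clinician-selected contact
#'   differs from the true best contact.
#' @param anatomy_error_sd SD (mm per axis) of the landmark-derived target
#'   around the true source.
#' @param artifact_rail amplitude of the clipped stimulation-artifact
#'   transient, µV.
#' @param seed integer seed making the study reproducible.
#' @return An object of class `study_config`.
#' @seealso [generate_study()]
#' @export
study_config <- function(n_patients = 14,
                         hemispheres_per_patient = 2,
                         fs = 4800,
                         rest_duration = 15,
                         burst_protocol = stim_protocol(),
                         erna_amplitude = 60,
                         erna_freq = 275,
                         erna_decay_tau = 5,
                         erna_onset_ms = 3,
                         spatial_lambda = 3,
                         erna_source_jitter_sd = 0.3,
                         beta_source_jitter_sd = 0.8,
                         hfo_source_jitter_sd = 1.5,
                         background_rms = 8,
                         background_alpha = 1.5,
                         background_lambda = 6,
                         background_gain_jitter_sd = 0.2,
                         beta_amplitude = 6,
                         hfo_amplitude = 1.5,
                         beta_peak_prob = 19 / 28,
                         hfo_peak_prob = 3 / 28,
                         line_freq = 50,
                         line_amplitude = 10,
                         spike_prob = 0.3,
                         spike_amplitude = 2,
                         benefit_max = 70,
                         benefit_lambda = 3,
                         benefit_noise_sd = 12,
                         patient_sd = 10,
                         off_updrs_range = c(15, 35),
                         missing_channel_prob = 0.01,
                         force_one_missing = FALSE,
                         side_effect_max = 0.4,
                         side_effect_lambda = 4,
                         clinician_error_prob = 3 / 28,
                         anatomy_error_sd = 1,
                         artifact_rail = 2000,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      abort(sprintf("'%s' must be a probability in [0, 1]", field),
            "ernarank_config_error")
  }
  for (f in c("beta_peak_prob", "hfo_peak_prob", "spike_prob",
              "missing_channel_prob", "side_effect_max",
              "clinician_error_prob"))
    chk_prob(f)
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      abort(sprintf("'%s' must be a positive number", field),
            "ernarank_config_error")
  }
  for (f in c("fs", "rest_duration", "spatial_lambda", "benefit_lambda",
              "background_lambda", "erna_freq", "erna_decay_tau",
              "side_effect_lambda"))
    chk_pos(f)
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      abort(sprintf("'%s' must be a non-negative number", field),
            "ernarank_config_error")
  }
  for (f in c("erna_amplitude", "background_rms", "beta_amplitude",
              "hfo_amplitude", "line_amplitude", "spike_amplitude",
              "benefit_noise_sd", "patient_sd", "anatomy_error_sd",
              "erna_source_jitter_sd", "beta_source_jitter_sd",
              "hfo_source_jitter_sd"))
    chk_nonneg(f)
  if (cfg$n_patients < 1)
    abort("'n_patients' must be >= 1", "ernarank_config_error")
  if (!cfg$hemispheres_per_patient %in% c(1, 2))
    abort("'hemispheres_per_patient' must be 1 or 2",
          "ernarank_config_error")
  # HFO band extends to 400 Hz: need fs >= 2 * 400
  if (cfg$fs < 2 * 400)
    abort("'fs' must be at least 800 Hz (2x the 400 Hz HFO band edge)",
          "ernarank_config_error")
  if (!inherits(cfg$burst_protocol, "stim_protocol"))
    abort("'burst_protocol' must be a stim_protocol object",
          "ernarank_config_error")
  invisible(cfg)
}
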