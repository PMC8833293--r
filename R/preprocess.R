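# Signal conditioning shared by the ERNA and LFP paths.

# Zero-phase filtering: a forward-reverse pass of an IIR filter has the
# transfer function |H(w)|^2 with zero phase. It is applied here exactly,
# in the frequency domain (multiply the DFT by |H|^2 evaluated from the
# b/a coefficients), rather than by time-domain filtfilt: for the
# narrow high-Q band-stops in this chain, time-domain forward-reverse
# filtering re-acquires the phase of in-notch oscillations at every
# padding boundary, and that startup transient (~1/(pi*BW) seconds)
# dominates the notch attenuation no matter how the signal is padded.
# The frequency-domain form is transient-free, exactly linear and
# exactly zero-phase; its boundary condition is periodic, which only
# matters within a filter time constant of the segment ends — far from
# the analysed epochs.
zero_phase_filter <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  if (n <= 3 * (max(length(a), length(b)) - 1))
    abort("signal too short for zero-phase filtering",
          "ernarank_alignment_error")
  z <- exp(-2i * pi * (seq_len(n) - 1) / n)
  H <- as.vector((outer(z, (length(b) - 1):0, "^") %*% b) /
                   (outer(z, (length(a) - 1):0, "^") %*% a))
  Re(fft(fft(x) * Mod(H)^2, inverse = TRUE)) / n
}

#' Re-reference a lead to the contralateral average
#'
#' Common-mode noise suppression for monopolar recordings: each target
#' channel minus the mean of the contralateral lead's non-missing
#' (unstimulated) channels, sample by sample.
#'
#' @param target single-lead [lead_recording()] to re-reference.
#' @param reference single-lead [lead_recording()] from the opposite
#'   hemisphere, same sampling rate and length.
#' @return The re-referenced `lead_recording`; the contacts used as
#'   reference are recorded in its `reference_contacts` element.
#' @export
rereference_contralateral_average <- function(target, reference) {
  if (target$fs != reference$fs ||
      ncol(target$signal) != ncol(reference$signal))
    abort("target and reference must share sampling rate and length",
          "ernarank_alignment_error")
  if (any(target$channel_map$side %in% reference$channel_map$side))
    abort("reference must come from the opposite hemisphere",
          "ernarank_reference_error")
  ok <- !reference$channel_map$missing
  if (!any(ok))
    abort("all reference channels are missing",
          "ernarank_reference_error")
  ref_mean <- colMeans(reference$signal[ok, , drop = FALSE])
  out <- target
  out$signal <- sweep(target$signal, 2, ref_mean)
  out$reference_contacts <- reference$channel_map$contact[ok]
  out
}

#' ERNA conditioning filter chain
#'
#' Second-order Butterworth high-pass (2 Hz) followed by a second-order
#' Butterworth band-stop (49-51 Hz), each applied forward and reverse
#' for zero net phase.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz (> 102 so the band-stop edge is
#'   representable).
#' @param hp_corner high-pass corner, Hz.
#' @param stop_band band-stop edges, Hz.
#' @return Filtered signal, same length.
#' @export
erna_condition_filter <- function(x, fs, hp_corner = 2,
                                  stop_band = c(49, 51)) {
  if (fs <= 2 * max(stop_band))
    abort("fs too low for the 49-51 Hz band-stop",
          "ernarank_config_error")
  hp <- signal::butter(2, hp_corner / (fs / 2), type = "high")
  bs <- signal::butter(2, stop_band / (fs / 2), type = "stop")
  zero_phase_filter(bs, zero_phase_filter(hp, x))
}

# odd window length nearest to 21 samples at 38.4 kHz (~0.547 ms)
ma_window_length <- function(fs) {
  w <- 21 * fs / 38400
  max(1L, 2L * round((w - 1) / 2) + 1L)
}

#' Centred moving-average smoothing
#'
#' 21-point centred moving average at 38.4 kHz; at other rates the
#' window is the odd sample count nearest to the same duration
#' (~0.547 ms). Edges use shrinking (one-sided) windows.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window odd window length in samples; default derived from
#'   `fs`.
#' @return Smoothed signal, same length.
#' @export
moving_average_smooth <- function(x, fs, window = NULL) {
  w <- window %||% ma_window_length(fs)
  if (w < 1 || w %% 2 == 0)
    abort("moving-average window must be odd and >= 1",
          "ernarank_config_error")
  if (w == 1) return(x)
  k <- (w - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - k - 1L)
  hi <- pmin(n, seq_len(n) + k)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Apply the full ERNA conditioning chain to a recording
#'
#' Zero-phase high-pass + band-stop filtering and moving-average
#' smoothing of every non-missing channel of a (re-referenced)
#' recording.
#'
#' @param recording a [lead_recording()].
#' @return The conditioned `lead_recording`.
#' @export
condition_recording <- function(recording) {
  out <- recording
  for (i in seq_len(nrow(recording$signal))) {
    if (recording$channel_map$missing[i]) next
    y <- erna_condition_filter(recording$signal[i, ], recording$fs)
    out$signal[i, ] <- moving_average_smooth(y, recording$fs)
  }
  out
}
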