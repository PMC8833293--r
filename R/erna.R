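# ERNA: evoked resonant neural activity power per contact.

#' Extract the burst-averaged evoked waveform
#'
#' For each burst, an epoch of `epoch_ms` is cut starting at the offset
#' (end of the second phase) of the burst's last pulse, linearly
#' detrended to remove baseline drift, and averaged across bursts.
#'
#' @param recording a burst-segment [lead_recording()], already
#'   conditioned (see [condition_recording()]).
#' @param record_contact contact index 0-3 to read; must differ from the
#'   stimulated contact and not be missing.
#' @param epoch_ms epoch length after last-pulse offset, ms.
#' @return An object of class `evoked_waveform`: `time` (ms after
#'   last-pulse offset), `amplitude` (µV), `n_bursts_averaged`,
#'   `stim_contact`, `record_contact`, `fs`.
#' @export
extract_evoked <- function(recording, record_contact, epoch_ms = 50) {
  if (recording$kind != "burst")
    abort("evoked extraction requires a burst segment",
          "ernarank_usage_error")
  if (!is.na(recording$stim_contact) &&
      record_contact == recording$stim_contact)
    abort("record contact must differ from the stimulated contact",
          "ernarank_usage_error")
  row <- contact_row(recording, record_contact)
  if (recording$channel_map$missing[row])
    abort(sprintf("contact %d is missing", record_contact),
          "ernarank_fault_error")
  fs <- recording$fs
  pw_s <- 2 * 60e-6   # default biphasic pulse: fall back when no protocol
  if (!is.null(attr(recording, "pulse_width_us")))
    pw_s <- 2 * attr(recording, "pulse_width_us") * 1e-6
  n_ep <- round(epoch_ms / 1000 * fs)
  x <- recording$signal[row, ]
  epochs <- matrix(NA_real_, length(recording$pulse_times), n_ep)
  for (b in seq_along(recording$pulse_times)) {
    last <- max(recording$pulse_times[[b]])
    i0 <- round((last + pw_s) * fs) + 1L
    if (i0 + n_ep - 1L > length(x))
      abort("epoch extends past end of recording",
            "ernarank_alignment_error")
    ep <- x[i0:(i0 + n_ep - 1L)]
    # linear detrend (closed-form least squares)
    tt <- seq_len(n_ep)
    fit <- stats::lm.fit(cbind(1, tt), ep)
    epochs[b, ] <- ep - fit$fitted.values
  }
  structure(list(time = (seq_len(n_ep) - 1) / fs * 1000,
                 amplitude = colMeans(epochs),
                 n_bursts_averaged = nrow(epochs),
                 stim_contact = recording$stim_contact,
                 record_contact = record_contact, fs = fs),
            class = "evoked_waveform")
}

#' RMS amplitude of an evoked waveform in a time window
#'
#' @param w an [extract_evoked()] waveform.
#' @param t0,t1 window, ms after last-pulse offset; samples with
#'   `t0 <= t < t1` are used. Defaults 4-20 ms, the interval containing
#'   the ERNA's decaying oscillation while excluding residual stimulus
#'   artifact.
#' @return RMS amplitude, µV.
#' @export
rms_in_window <- function(w, t0 = 4, t1 = 20) {
  sel <- w$time >= t0 & w$time < t1
  if (!any(sel))
    abort("window contains no samples", "ernarank_window_error")
  sqrt(mean(w$amplitude[sel]^2))
}

#' ERNA power from per-condition RMS amplitudes
#'
#' ERNA power at a contact is the square of the mean RMS amplitude
#' measured there while each of the other contacts was stimulated
#' (up to three conditions; fewer when a stimulation contact was
#' missing).
#'
#' @param rms_values numeric vector of per-condition RMS amplitudes
#'   (µV); `NA`s are dropped.
#' @return List with `power` (µV²; `NA` with a missing flag when no
#'   condition is available) and `n_conditions`.
#' @examples
#' erna_power(c(2, 3, 4))  # power 9, n 3
#' @export
erna_power <- function(rms_values) {
  v <- rms_values[!is.na(rms_values)]
  if (!length(v))
    return(list(power = NA_real_, n_conditions = 0L, missing = TRUE))
  list(power = mean(v)^2, n_conditions = length(v), missing = FALSE)
}

#' ERNA features for one lead of a synthetic study
#'
#' Runs the full ERNA chain for every contact of one hemisphere:
#' contralateral-average re-referencing, zero-phase filtering and
#' smoothing, evoked-waveform extraction after each burst, 4-20 ms RMS,
#' and power aggregation across stimulation conditions.
#'
#' @param study a [generate_study()] result.
#' @param hemisphere hemisphere key (e.g. `"P01_left"`).
#' @param t0,t1 RMS window, ms.
#' @return data.frame with one row per contact: `contact`,
#'   `erna_power`, `n_conditions`, `missing`.
#' @export
erna_features_for_lead <- function(study, hemisphere, t0 = 4, t1 = 20) {
  h <- study$hemispheres[[hemisphere]]
  if (is.null(h))
    abort(sprintf("unknown hemisphere '%s'", hemisphere),
          "ernarank_join_error")
  side <- h$side
  segs <- study$patients[[h$patient]]$bursts[[side]]
  if (length(segs) < 2)
    abort("need burst recordings from at least 2 stimulation contacts",
          "ernarank_usage_error")
  pw <- study$config$burst_protocol$pulse_width_us
  rms <- matrix(NA_real_, nrow = 4, ncol = length(segs),
                dimnames = list(NULL, names(segs)))
  for (sc_name in names(segs)) {
    seg <- segs[[sc_name]]
    sc <- as.integer(sc_name)
    tgt <- lead_subset(seg, side)
    has_contra <- any(seg$channel_map$side != side)
    cond <- if (has_contra) {
      ref <- lead_subset(seg, setdiff(unique(seg$channel_map$side), side))
      rereference_contralateral_average(tgt, ref)
    } else tgt
    cond <- condition_recording(cond)
    attr(cond, "pulse_width_us") <- pw
    for (rc in 0:3) {
      if (rc == sc || cond$channel_map$missing[contact_row(cond, rc)])
        next
      w <- extract_evoked(cond, rc)
      rms[rc + 1, sc_name] <- rms_in_window(w, t0, t1)
    }
  }
  res <- lapply(1:4, function(i) erna_power(rms[i, ]))
  data.frame(contact = 0:3,
             erna_power = vapply(res, `[[`, numeric(1), "power"),
             n_conditions = vapply(res, `[[`, integer(1), "n_conditions"),
             missing = h$params$missing)
}
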