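#' Multichannel lead recording
#'
#' Container for a monopolar recording segment from one or two quadripolar
#' leads. Rows of `signal` are channels; `channel_map` identifies each row
#' by hemisphere side and contact index (0-3, ventral to dorsal) and flags
#' missing channels (technical faults). Missing channels carry `NA`
#' samples and are excluded from every average.
#'
#' @param signal numeric matrix, channels x samples, µV.
#' @param fs sampling rate, Hz.
#' @param channel_map data.frame with columns `side` ("left"/"right"),
#'   `contact` (integer 0-3) and `missing` (logical), one row per channel.
#' @param pulse_times list of numeric vectors (s), one per burst; empty
#'   list for rest segments.
#' @param kind `"rest"` or `"burst"`.
#' @param stim_contact stimulated contact index for burst segments, else
#'   `NA`.
#' @param stim_side stimulated hemisphere side for burst segments.
#' @return An object of class `lead_recording`.
#' @export
lead_recording <- function(signal, fs, channel_map,
                           pulse_times = list(), kind = c("rest", "burst"),
                           stim_contact = NA_integer_,
                           stim_side = NA_character_) {
  kind <- match.arg(kind)
  if (!is.matrix(signal))
    signal <- matrix(signal, nrow = 1)
  if (nrow(channel_map) != nrow(signal))
    abort("channel_map must have one row per signal channel",
          "ernarank_config_error")
  if (fs <= 0) abort("fs must be positive", "ernarank_config_error")
  pt <- unlist(pulse_times, use.names = FALSE)
  if (length(pt) && any(diff(pt) <= 0))
    abort("pulse_times must be strictly increasing",
          "ernarank_alignment_error")
  structure(list(signal = signal, fs = fs, channel_map = channel_map,
                 pulse_times = pulse_times, kind = kind,
                 stim_contact = stim_contact, stim_side = stim_side),
            class = "lead_recording")
}

#' @export
print.lead_recording <- function(x, ...) {
  cat(sprintf(
    "<lead_recording> %s, %d channel(s) x %d samples @ %g Hz\n",
    x$kind, nrow(x$signal), ncol(x$signal), x$fs))
  if (x$kind == "burst")
    cat(sprintf("  stim: %s contact %d, %d bursts (%d pulses)\n",
                x$stim_side, x$stim_contact, length(x$pulse_times),
                length(unlist(x$pulse_times))))
  invisible(x)
}

#' Extract one lead (hemisphere side) from a recording
#'
#' @param recording a [lead_recording()] (possibly spanning both leads).
#' @param side `"left"` or `"right"`.
#' @return A `lead_recording` restricted to the channels of `side`,
#'   ordered by contact index.
#' @export
lead_subset <- function(recording, side) {
  idx <- which(recording$channel_map$side == side)
  if (!length(idx))
    abort(sprintf("no channels for side '%s'", side),
          "ernarank_config_error")
  idx <- idx[order(recording$channel_map$contact[idx])]
  out <- recording
  out$signal <- recording$signal[idx, , drop = FALSE]
  out$channel_map <- recording$channel_map[idx, , drop = FALSE]
  rownames(out$channel_map) <- NULL
  out
}

# row index of a contact within a (single-lead) recording
contact_row <- function(recording, contact) {
  i <- which(recording$channel_map$contact == contact)
  if (!length(i))
    abort(sprintf("contact %d not present in recording", contact),
          "ernarank_config_error")
  i
}

# stack two single-lead recordings of the same segment into one container
bind_leads <- function(a, b) {
  stopifnot(a$fs == b$fs, ncol(a$signal) == ncol(b$signal))
  out <- a
  out$signal <- rbind(a$signal, b$signal)
  out$channel_map <- rbind(a$channel_map, b$channel_map)
  rownames(out$channel_map) <- NULL
  out
}
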