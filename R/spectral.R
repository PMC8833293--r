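# Beta and HFO band power estimation: Blackman-Harris STFT and DPSS
# multitaper PSDs, interference-spike detection/notching, band
# integration, and 1/f-background peak detection.

power_spectrum <- function(frequency, density, method, n_epochs,
                           n_tapers = NA_integer_) {
  structure(list(frequency = frequency, density = pmax(density, 0),
                 method = method, n_epochs = n_epochs,
                 n_tapers = n_tapers),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s, %d bins to %g Hz, %d epoch(s)\n",
              x$method, length(x$frequency), max(x$frequency),
              x$n_epochs))
  invisible(x)
}

# 4-term Blackman-Harris window (periodic form, for spectral averaging)
blackman_harris <- function(n) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- 2 * pi * (seq_len(n) - 1) / n
  a[1] - a[2] * cos(k) + a[3] * cos(2 * k) - a[4] * cos(3 * k)
}

# one-sided PSD of windowed epochs, density-normalized:
# S(f) = |X(f)|^2 / (fs * sum(w^2)), doubled except at DC/Nyquist
psd_epochs <- function(x, fs, epoch_s, window_fun) {
  n_ep_len <- round(epoch_s * fs)
  n_ep <- floor(length(x) / n_ep_len)
  if (n_ep < 1)
    abort("signal shorter than one epoch", "ernarank_length_error")
  nf <- n_ep_len %/% 2 + 1
  acc <- numeric(nf)
  w <- window_fun(n_ep_len)
  wnorm <- sum(w^2)
  n_spectra <- 0L
  for (e in seq_len(n_ep)) {
    seg <- x[((e - 1) * n_ep_len + 1):(e * n_ep_len)]
    if (is.matrix(w)) {            # one column per taper, unit energy
      for (k in seq_len(ncol(w))) {
        X <- fft(seg * w[, k])[seq_len(nf)]
        acc <- acc + Mod(X)^2 / fs
        n_spectra <- n_spectra + 1L
      }
    } else {
      X <- fft(seg * w)[seq_len(nf)]
      acc <- acc + Mod(X)^2 / (fs * wnorm)
      n_spectra <- n_spectra + 1L
    }
  }
  dens <- acc / n_spectra
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (n_ep_len %% 2 == 0) one_sided[nf] <- 1
  list(frequency = seq(0, fs / 2, length.out = nf),
       density = dens * one_sided, n_epochs = n_ep)
}

#' Blackman-Harris STFT power spectral density
#'
#' Averages magnitude-squared FFTs of non-overlapping Blackman-Harris
#' windowed epochs (default 1 s), normalized to a one-sided density in
#' µV²/Hz; used for the beta (13-30 Hz) path.
#'
#' @param x numeric signal, µV.
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch length, s.
#' @return A `power_spectrum` object.
#' @export
psd_stft_blackmanharris <- function(x, fs, epoch_s = 1) {
  p <- psd_epochs(x, fs, epoch_s, blackman_harris)
  power_spectrum(p$frequency, p$density, "stft-blackmanharris",
                 p$n_epochs)
}

# DPSS (Slepian) tapers: eigenvectors of the classic symmetric
# tridiagonal matrix. Computed densely at a base length <= 1024, then
# spline-interpolated to the target length and re-orthonormalized; unit
# energy per taper. Cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  nb <- min(n, 1024L)
  i <- 0:(nb - 1)
  M <- matrix(0, nb, nb)
  diag(M) <- ((nb - 1 - 2 * i) / 2)^2 * cos(2 * pi * nw / nb)
  off <- (1:(nb - 1)) * (nb - (1:(nb - 1))) / 2
  M[cbind(1:(nb - 1), 2:nb)] <- off
  M[cbind(2:nb, 1:(nb - 1))] <- off
  v <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  if (nb < n) {
    g0 <- seq(0, 1, length.out = nb)
    g1 <- seq(0, 1, length.out = n)
    v <- vapply(seq_len(k),
                function(j) spline(g0, v[, j], xout = g1)$y,
                numeric(n))
    v <- qr.Q(qr(v))
  }
  # fix sign convention: first taper positive, unit energy
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

#' Thomson multitaper power spectral density
#'
#' Averages eigenspectra over `n_tapers` DPSS tapers (time-bandwidth
#' product `(n_tapers + 1) / 2`, so 20 tapers use NW = 10.5) and over
#' non-overlapping epochs; used for the HFO (200-400 Hz) path, where the
#' broad band benefits from the reduced estimator variance.
#'
#' @inheritParams psd_stft_blackmanharris
#' @param n_tapers number of DPSS tapers.
#' @return A `power_spectrum` object.
#' @export
psd_multitaper <- function(x, fs, n_tapers = 20, epoch_s = 1) {
  if (n_tapers < 1)
    abort("n_tapers must be >= 1", "ernarank_config_error")
  n_ep_len <- round(epoch_s * fs)
  if (2 * n_tapers >= n_ep_len)
    abort("n_tapers too large for epoch length",
          "ernarank_config_error")
  nw <- (n_tapers + 1) / 2
  p <- psd_epochs(x, fs, epoch_s,
                  function(n) dpss_tapers(n, nw, n_tapers))
  power_spectrum(p$frequency, p$density, "multitaper", p$n_epochs,
                 n_tapers = n_tapers)
}

#' Detect sharp interference spikes in a spectrum
#'
#' Flags frequency bins whose density exceeds `threshold_ratio` times
#' the running median over a `+/- neighbourhood_hz` neighbourhood —
#' automating the visual identification of narrowband interference
#' (mains harmonics) in the HFO band. Adjacent detections within 1 Hz
#' are merged to their peak bin.
#'
#' @param ps a `power_spectrum`.
#' @param band search band, Hz.
#' @param threshold_ratio ratio over the running median.
#' @param neighbourhood_hz half-width of the median neighbourhood, Hz.
#' @return Ascending numeric vector of spike frequencies (possibly
#'   empty).
#' @export
detect_spectral_spikes <- function(ps, band = c(200, 400),
                                   threshold_ratio = 8,
                                   neighbourhood_hz = 10) {
  if (band[1] >= band[2] || band[2] > max(ps$frequency))
    abort("band outside spectrum range", "ernarank_range_error")
  f <- ps$frequency
  d <- ps$density
  in_band <- which(f >= band[1] & f <= band[2])
  med <- vapply(in_band, function(i) {
    nb <- abs(f - f[i]) <= neighbourhood_hz
    median(d[nb])
  }, numeric(1))
  hits <- in_band[d[in_band] > threshold_ratio * med & med > 0]
  if (!length(hits)) return(numeric())
  # merge runs of adjacent detections (within 1 Hz) to the peak bin
  groups <- cumsum(c(1, diff(f[hits]) > 1))
  vapply(split(hits, groups),
         function(g) f[g[which.max(d[g])]], numeric(1),
         USE.NAMES = FALSE)
}

#' Notch out interference spikes
#'
#' Applies a zero-phase second-order Butterworth band-stop of
#' `f +/- 0.5` Hz sequentially for each spike frequency.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param spikes numeric spike frequencies (each < fs/2 - 1).
#' @param half_width_hz half-width of each notch, Hz.
#' @return Filtered signal (unchanged if `spikes` is empty).
#' @export
notch_spikes <- function(x, fs, spikes, half_width_hz = 0.5) {
  for (f0 in spikes) {
    if (f0 >= fs / 2 - 1)
      abort("spike frequency too close to Nyquist",
            "ernarank_range_error")
    bs <- signal::butter(2, c(f0 - half_width_hz, f0 + half_width_hz) /
                           (fs / 2), type = "stop")
    x <- zero_phase_filter(bs, x)
  }
  x
}

#' Band power from a power spectrum
#'
#' Trapezoidal integral of the density over the grid points inside
#' `[f_lo, f_hi]` (µV²). Splitting a band at an interior grid point is
#' exactly additive.
#'
#' @param ps a `power_spectrum`.
#' @param f_lo,f_hi band edges, Hz.
#' @return Band power, µV².
#' @export
band_power <- function(ps, f_lo, f_hi) {
  if (f_lo >= f_hi)
    abort("f_lo must be below f_hi", "ernarank_range_error")
  if (f_hi > max(ps$frequency) + 1e-9)
    abort("band extends past the spectrum grid", "ernarank_range_error")
  sel <- which(ps$frequency >= f_lo & ps$frequency <= f_hi)
  if (length(sel) < 2)
    abort("band contains fewer than 2 grid points",
          "ernarank_range_error")
  f <- ps$frequency[sel]
  d <- ps$density[sel]
  sum(diff(f) * (head(d, -1) + d[-1]) / 2)
}

#' Detect a spectral peak over the 1/f background
#'
#' Fits a log-log linear (1/f) background to the spectrum outside the
#' candidate band (and away from the mains frequency) and declares a
#' peak present when at least `min_bins` consecutive in-band bins exceed
#' `peak_ratio` times the fitted background — an automated stand-in for
#' visual peak identification.
#'
#' @param ps a `power_spectrum`.
#' @param band candidate band, Hz (e.g. `c(13, 30)` for beta).
#' @param peak_ratio required excess over the fitted background.
#' @param min_bins required consecutive qualifying bins.
#' @param line_freq mains frequency excluded (with harmonics, +/- 2 Hz)
#'   from the background fit.
#' @return List with `present` (logical) and `peak_freq` (Hz, `NA` when
#'   absent).
#' @export
detect_band_peak <- function(ps, band, peak_ratio = 2, min_bins = 3,
                             line_freq = 50) {
  if (band[1] >= band[2] || band[2] > max(ps$frequency))
    abort("band outside spectrum grid", "ernarank_range_error")
  f <- ps$frequency
  d <- ps$density
  harm <- line_freq * seq_len(floor(max(f) / line_freq))
  near_line <- Reduce(`|`, lapply(harm, function(h) abs(f - h) <= 2))
  fit_sel <- f >= 2 & f <= min(450, max(f)) & d > 0 &
    !(f >= band[1] & f <= band[2]) & !near_line
  if (sum(fit_sel) < 10)
    abort("too few bins to fit the background",
          "ernarank_range_error")
  fit <- lm(log10(d[fit_sel]) ~ log10(f[fit_sel]))
  in_band <- which(f >= band[1] & f <= band[2] & f > 0)
  bg <- 10^(coef(fit)[1] + coef(fit)[2] * log10(f[in_band]))
  over <- d[in_band] >= peak_ratio * bg
  runs <- rle(over)
  present <- any(runs$values & runs$lengths >= min_bins)
  peak_freq <- NA_real_
  if (present) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    qual <- which(runs$values & runs$lengths >= min_bins)
    idx <- unlist(lapply(qual, function(q) starts[q]:ends[q]))
    ratio <- d[in_band][idx] / bg[idx]
    peak_freq <- f[in_band][idx[which.max(ratio)]]
  }
  list(present = present, peak_freq = peak_freq)
}

#' Beta and HFO features for one lead of a synthetic study
#'
#' Runs the resting-LFP path for every contact of one hemisphere:
#' contralateral-average re-referencing, then beta band power (13-30 Hz)
#' from the Blackman-Harris STFT spectrum of the un-notched signal, and
#' HFO band power (200-400 Hz) from the multitaper spectrum of the
#' spike-notched signal (interference spikes detected in 200-400 Hz are
#' removed before HFO estimation only).
#'
#' @param study a [generate_study()] result.
#' @param hemisphere hemisphere key.
#' @param n_tapers multitaper taper count.
#' @return data.frame per contact: `contact`, `beta_power`, `hfo_power`,
#'   `beta_peak_present`, `hfo_peak_present`, `missing`.
#' @export
lfp_features_for_lead <- function(study, hemisphere, n_tapers = 20) {
  h <- study$hemispheres[[hemisphere]]
  if (is.null(h))
    abort(sprintf("unknown hemisphere '%s'", hemisphere),
          "ernarank_join_error")
  rest <- study$patients[[h$patient]]$rest
  tgt <- lead_subset(rest, h$side)
  sides <- unique(rest$channel_map$side)
  if (length(sides) > 1) {
    ref <- lead_subset(rest, setdiff(sides, h$side))
    tgt <- rereference_contralateral_average(tgt, ref)
  }
  fs <- rest$fs
  out <- data.frame(contact = 0:3, beta_power = NA_real_,
                    hfo_power = NA_real_, beta_peak_present = NA,
                    hfo_peak_present = NA, missing = h$params$missing)
  for (c in 0:3) {
    i <- contact_row(tgt, c)
    if (tgt$channel_map$missing[i]) next
    x <- tgt$signal[i, ]
    ps_beta <- psd_stft_blackmanharris(x, fs)
    out$beta_power[c + 1] <- band_power(ps_beta, 13, 30)
    out$beta_peak_present[c + 1] <-
      detect_band_peak(ps_beta, c(13, 30))$present
    # spike detection needs the sharp STFT spectrum: multitaper smearing
    # (NW ~ 10 Hz) would hide narrowband tones from the running median
    spikes <- detect_spectral_spikes(ps_beta, band = c(200, 400))
    x_n <- notch_spikes(x, fs, spikes)
    ps_hfo <- psd_multitaper(x_n, fs, n_tapers)
    out$hfo_power[c + 1] <- band_power(ps_hfo, 200, 400)
    out$hfo_peak_present[c + 1] <-
      detect_band_peak(ps_hfo, c(200, 400))$present
  }
  out
}
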