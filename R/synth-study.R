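# Study-level synthesis: geometry, outcomes, ground truth, full cohorts.

# lead trajectory + contact positions + latent source for one hemisphere.
# The source sits near contact 2 (dorsal STN), jittered along and across
# the lead axis, so contact 2 is usually — not always — the closest.
synth_geometry <- function(config, side) {
  s <- if (side == "right") 1 else -1
  base <- c(s * 11.5, -1.5, -9) + rnorm(3, 0, 1)
  axis <- c(s * 0.25, 0.35, 0.9) + rnorm(3, 0, 0.05)
  axis <- axis / sqrt(sum(axis^2))
  pos <- t(vapply(0:3, function(k) base + 3 * k * axis, numeric(3)))
  source <- pos[3, ] + runif(1, -1.5, 1.5) * axis + rnorm(3, 0, 0.7)
  target <- source + rnorm(3, 0, config$anatomy_error_sd)
  lm <- red_nucleus_landmarks(
    anterior_border_point = c(target[1] - s * 5, target[2], target[3]),
    superior_border_z = target[3] + 2,
    lateral_border_x = target[1] - s * 3,
    side = side)
  list(positions = pos, landmarks = lm, source = source)
}

# balanced 4x4 Latin square for counterbalancing condition order
latin_square_4 <- function() {
  matrix(c(1, 2, 4, 3,
           2, 3, 1, 4,
           3, 4, 2, 1,
           4, 1, 3, 2), 4, 4, byrow = TRUE)
}

#' Synthesize clinical outcomes for one hemisphere
#'
#' Draws the off-stimulation hemibody UPDRS score, the tolerated
#' stimulation fraction at each contact (reductions to 75/50/25% become
#' more likely with distance from the source), a counterbalanced
#' condition order, and per-contact on-stimulation scores implying a
#' benefit of `benefit_max * exp(-d / benefit_lambda) * fraction` plus a
#' patient offset and Gaussian noise. On-scores are floored at zero, so
#' benefit never exceeds 100%; negative benefit (worsening) is allowed.
#'
#' @param distances contact-source distances, mm.
#' @param missing logical length 4; missing contacts are not tested.
#' @param config a [study_config()].
#' @param patient_effect patient-level benefit offset, percentage points.
#' @param order_row row (1-4) of the balanced Latin square assigning
#'   condition order for this hemisphere.
#' @param seed optional seed.
#' @return A list of class `outcome_record`: `off_updrs`, `on_updrs`
#'   (length 4, `NA` at missing), `stim_fraction`, `order_index`,
#'   `clinician_contact` (0-based), `chronic_settings`, `expected_benefit`
#'   (noise-free, full-amplitude).
#' @export
synth_outcomes <- function(distances, missing, config, patient_effect = 0,
                           order_row = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  off <- round(runif(1, config$off_updrs_range[1],
                     config$off_updrs_range[2]))
  expected <- config$benefit_max * exp(-distances / config$benefit_lambda)
  p_reduce <- config$side_effect_max *
    (1 - exp(-distances / config$side_effect_lambda))
  frac <- rep(1, 4)
  reduce <- runif(4) < p_reduce
  # observed reduction mix: 75% much more often than 50%, rarely 25%
  frac[reduce] <- sample(c(0.75, 0.5, 0.25), sum(reduce), replace = TRUE,
                         prob = c(17, 11, 1) / 29)
  benefit <- expected * frac + patient_effect +
    rnorm(4, 0, config$benefit_noise_sd)
  on <- pmax(0, off * (1 - benefit / 100))
  on[missing] <- NA_real_
  frac[missing] <- NA_real_
  ord <- latin_square_4()[((order_row - 1) %% 4) + 1, ]
  ord[missing] <- NA_integer_
  ord[!missing] <- rank(ord[!missing], ties.method = "first")
  avail <- which(!missing) - 1L
  true_best <- avail[which.max(expected[avail + 1L])]
  clin <- true_best
  if (length(avail) > 1 && runif(1) < config$clinician_error_prob)
    clin <- sample(setdiff(avail, true_best), 1)
  structure(list(
    off_updrs = off, on_updrs = on, stim_fraction = frac,
    order_index = ord, clinician_contact = clin,
    chronic_settings = list(current_mA = round(runif(1, 1.8, 5.1), 1),
                            pulse_width_us = sample(c(60, 90), 1,
                                                    prob = c(0.8, 0.2)),
                            frequency_hz = sample(c(130, 180), 1)),
    expected_benefit = expected), class = "outcome_record")
}

#' Generate a complete synthetic study
#'
#' Produces a full cohort with the structure the downstream analysis
#' assumes: per patient, a 15 s resting recording spanning both leads and
#' one burst-stimulation segment per non-missing contact; per hemisphere,
#' lead geometry with red-nucleus landmarks, clinical outcomes, and
#' ground truth (latent source position, noise-free expected benefit,
#' true best contact). Neural signal amplitudes and expected benefit both
#' decay as `exp(-d / lambda)` with contact-source distance. A visible
#' beta bump is present in a configurable fraction of hemispheres, an
#' HFO bump rarely. Regenerating with the same config (including its
#' seed) reproduces the study exactly.
#'
#' @param config a [study_config()].
#' @return An object of class `synthetic_study` with elements `config`,
#'   `manifest`, `patients` (recordings keyed by patient id) and
#'   `hemispheres` (geometry, generation parameters, outcomes and truth
#'   keyed by `"P<id>_<side>"`).
#' @examples
#' \donttest{
#' study <- generate_study(study_config(n_patients = 1, rest_duration = 2,
#'   burst_protocol = stim_protocol(duration_s = 2), seed = 7))
#' names(study$hemispheres)
#' }
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  set.seed(config$seed)
  sides <- c("left", "right")[seq_len(config$hemispheres_per_patient)]
  n_hemi <- config$n_patients * length(sides)
  pids <- sprintf("P%02d", seq_len(config$n_patients))

  forced <- if (config$force_one_missing) sample.int(n_hemi, 1) else 0L

  patients <- list()
  hemispheres <- list()
  hcount <- 0L
  for (p in seq_len(config$n_patients)) {
    u_p <- rnorm(1, 0, config$patient_sd)
    hps <- list()
    rests <- list()
    bursts <- list()
    for (side in sides) {
      hcount <- hcount + 1L
      geom <- synth_geometry(config, side)
      d_to <- function(src)
        sqrt(colSums((t(geom$positions) - src)^2))
      d <- d_to(geom$source)
      d_erna <- d_to(geom$source + rnorm(3, 0, config$erna_source_jitter_sd))
      d_beta <- d_to(geom$source + rnorm(3, 0, config$beta_source_jitter_sd))
      d_hfo <- d_to(geom$source + rnorm(3, 0, config$hfo_source_jitter_sd))
      missing <- if (config$force_one_missing) {
        c(hcount == forced, FALSE, FALSE, FALSE)
      } else {
        runif(4) < config$missing_channel_prob
      }
      if (all(missing)) missing[4] <- FALSE   # keep hemisphere analysable
      n_spk <- if (runif(1) < config$spike_prob) sample(1:2, 1) else 0L
      hp <- hemisphere_params(
        distances = d, erna_distances = d_erna, beta_distances = d_beta,
        hfo_distances = d_hfo, side = side, missing = missing,
        has_beta = runif(1) < config$beta_peak_prob,
        has_hfo = runif(1) < config$hfo_peak_prob,
        beta_freq = runif(1, 16, 24), hfo_freq = runif(1, 250, 320),
        spike_freqs = if (n_spk) sample(c(200, 250, 300, 350, 400),
                                        n_spk) else numeric(),
        line_gains = rnorm(4, 1, 0.1), spike_gains = rnorm(4, 1, 0.1),
        artifact_gains = rnorm(4, 1, 0.05),
        background_gains = exp(rnorm(4, 0,
                                     config$background_gain_jitter_sd)))
      hps[[side]] <- hp
      rests[[side]] <- synth_rest_lfp(hp, config)
      outc <- synth_outcomes(d, missing, config, patient_effect = u_p,
                             order_row = hcount)
      avail <- which(!missing) - 1L
      truth <- list(source = geom$source,
                    expected_benefit = outc$expected_benefit,
                    best_contact = avail[which.max(
                      outc$expected_benefit[avail + 1L])])
      hemispheres[[sprintf("%s_%s", pids[p], side)]] <- list(
        patient = pids[p], side = side,
        geometry = contact_geometry(geom$positions, geom$landmarks,
                                    missing = missing),
        params = hp, outcome = outc, truth = truth)
    }
    # burst segments: ipsilateral stimulated lead + contralateral
    # background lead bound into one 8-channel container
    for (side in sides) {
      other <- setdiff(sides, side)
      segs <- list()
      for (sc in which(!hps[[side]]$missing) - 1L) {
        ipsi <- synth_burst_recording(hps[[side]], config, sc)
        if (length(other)) {
          cfg_b <- config
          cfg_b$rest_duration <- config$burst_protocol$duration_s
          contra <- synth_rest_lfp(hps[[other]], cfg_b)
          # the stimulation artifact couples through the shared recording
          # reference: it also appears on the contralateral lead
          hpo <- hps[[other]]
          for (ch in which(!hpo$missing))
            contra$signal[ch, ] <- add_pulse_artifact(
              contra$signal[ch, ], config$fs, ipsi$pulse_times,
              config$artifact_rail, hpo$artifact_gains[ch])
          seg <- bind_leads(ipsi, contra)
        } else seg <- ipsi
        segs[[as.character(sc)]] <- seg
      }
      bursts[[side]] <- segs
    }
    rest_all <- if (length(sides) == 2)
      bind_leads(rests[["left"]], rests[["right"]]) else rests[[1]]
    patients[[pids[p]]] <- list(rest = rest_all, bursts = bursts)
  }
  structure(list(
    config = config,
    manifest = list(seed = config$seed,
                    n_patients = config$n_patients,
                    n_hemispheres = n_hemi,
                    generator = "ernarank synthetic study"),
    patients = patients, hemispheres = hemispheres),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  n_missing <- sum(vapply(x$hemispheres, function(h)
    sum(h$params$missing), numeric(1)))
  cat(sprintf(
    "<synthetic_study> %d patients, %d hemispheres, %d/%d contacts with recordings\n",
    x$config$n_patients, length(x$hemispheres),
    4 * length(x$hemispheres) - n_missing, 4 * length(x$hemispheres)))
  invisible(x)
}

#' Long-format outcome table of a synthetic study
#'
#' @param study a [generate_study()] result.
#' @return data.frame, one row per tested contact: `patient`,
#'   `hemisphere`, `contact`, `off_updrs`, `on_updrs`, `stim_fraction`,
#'   `order_index`, `clinician_contact`.
#' @export
outcomes_table <- function(study) {
  do.call(rbind, lapply(names(study$hemispheres), function(key) {
    h <- study$hemispheres[[key]]
    o <- h$outcome
    keep <- !h$params$missing
    data.frame(patient = h$patient, hemisphere = key,
               contact = (0:3)[keep],
               off_updrs = o$off_updrs, on_updrs = o$on_updrs[keep],
               stim_fraction = o$stim_fraction[keep],
               order_index = o$order_index[keep],
               clinician_contact = o$clinician_contact)
  }))
}

#' Simulate an analysis table directly from the rank-benefit model
#'
#' Skips signal synthesis and draws the long-format analysis table from
#' the statistical model the inferential layer assumes: per hemisphere a
#' true contact ordering, factor rankings that either follow it
#' (informative factors) or are uniform random permutations, and benefit
#' `mu + u_patient - sum_f beta_f * (rank_f - 1) + stim_coef *
#' (fraction - 1) + noise`. Used for power, calibration and
#' model-selection simulations where hundreds of replicate cohorts are
#' needed.
#'
#' @param n_patients,hemispheres_per_patient cohort size.
#' @param effects named numeric: benefit decrement (percentage points)
#'   per rank step for each factor; a factor with effect 0 receives an
#'   independent random permutation.
#' @param mu mean benefit at a rank-1 contact with full amplitude, %.
#' @param patient_sd SD of the patient random intercept.
#' @param noise_sd residual SD, percentage points.
#' @param stim_coef benefit change per unit stimulation fraction.
#' @param reduction_probs probabilities of stimulation fractions
#'   1, 0.75, 0.5, 0.25.
#' @param seed optional seed.
#' @return A data.frame of class `analysis_table`.
#' @export
simulate_rank_table <- function(n_patients = 14,
                                hemispheres_per_patient = 2,
                                effects = c(erna = 12, beta = 0, hfo = 0,
                                            anatomy = 0),
                                mu = 60, patient_sd = 10, noise_sd = 12,
                                stim_coef = 40,
                                reduction_probs = c(0.74, 0.15, 0.09,
                                                    0.02),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  factors <- names(effects)
  rows <- list()
  hcount <- 0L
  for (p in seq_len(n_patients)) {
    u_p <- rnorm(1, 0, patient_sd)
    for (s in seq_len(hemispheres_per_patient)) {
      hcount <- hcount + 1L
      true_order <- sample.int(4)      # true benefit ranking of contacts
      ranks <- lapply(factors, function(f)
        if (effects[[f]] != 0) true_order else sample.int(4))
      names(ranks) <- factors
      frac <- sample(c(1, 0.75, 0.5, 0.25), 4, replace = TRUE,
                     prob = reduction_probs)
      lp <- mu + u_p + stim_coef * (frac - 1)
      for (f in factors) lp <- lp - effects[[f]] * (ranks[[f]] - 1)
      benefit <- lp + rnorm(4, 0, noise_sd)
      d <- data.frame(patient = sprintf("P%02d", p),
                      hemisphere = sprintf("P%02d_H%d", p, s),
                      contact = 0:3, benefit = benefit,
                      stim_fraction = frac,
                      order_index = sample.int(4))
      for (f in factors) d[[paste0("rank_", f)]] <- ranks[[f]]
      d$rank_benefit <- rank_by_value(benefit)
      d$is_best_contact <- d$rank_benefit == 1
      rows[[hcount]] <- d
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("analysis_table", "data.frame"))
}
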