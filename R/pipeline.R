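# End-to-end pipeline over a synthetic study, and plain-text I/O.

#' Per-contact features for a whole study
#'
#' Runs the ERNA and resting-LFP feature paths for every hemisphere.
#'
#' @param study a [generate_study()] result.
#' @param n_tapers multitaper taper count for the HFO path.
#' @return data.frame, one row per contact: `patient`, `hemisphere`,
#'   `contact`, `erna_power`, `n_conditions`, `beta_power`,
#'   `hfo_power`, `beta_peak_present`, `hfo_peak_present`, `missing`.
#' @export
study_features <- function(study, n_tapers = 20) {
  do.call(rbind, lapply(names(study$hemispheres), function(key) {
    h <- study$hemispheres[[key]]
    er <- erna_features_for_lead(study, key)
    lf <- lfp_features_for_lead(study, key, n_tapers = n_tapers)
    data.frame(patient = h$patient, hemisphere = key,
               contact = er$contact, erna_power = er$erna_power,
               n_conditions = er$n_conditions,
               beta_power = lf$beta_power, hfo_power = lf$hfo_power,
               beta_peak_present = lf$beta_peak_present,
               hfo_peak_present = lf$hfo_peak_present,
               missing = er$missing)
  }))
}

#' Anatomical ranks for a whole study
#'
#' @param study a [generate_study()] result.
#' @param overrides optional data.frame (`hemisphere`, `contact`,
#'   `new_rank`, `reason`) of expert adjustments.
#' @return data.frame: `hemisphere`, `contact`, `distance_mm`,
#'   `rank_anatomy`.
#' @export
study_anatomy_ranks <- function(study, overrides = NULL) {
  do.call(rbind, lapply(names(study$hemispheres), function(key) {
    h <- study$hemispheres[[key]]
    d <- h$geometry$distances
    d[h$params$missing] <- NA
    ranks <- rank_contacts_by_distance(d)
    if (!is.null(overrides)) {
      ov <- overrides[overrides$hemisphere == key, , drop = FALSE]
      ranks <- apply_expert_overrides(ranks, ov)
    }
    data.frame(hemisphere = key, contact = 0:3,
               distance_mm = h$geometry$distances,
               rank_anatomy = as.integer(ranks))
  }))
}

#' Full analysis of a synthetic study
#'
#' Convenience wrapper: features, anatomical ranks and outcomes are
#' computed and joined into the long-format analysis table (one row per
#' tested contact).
#'
#' @inheritParams study_features
#' @param overrides optional expert rank overrides (see
#'   [study_anatomy_ranks()]).
#' @return An `analysis_table` data.frame.
#' @export
analyze_study <- function(study, overrides = NULL, n_tapers = 20) {
  feats <- study_features(study, n_tapers = n_tapers)
  feats <- feats[!feats$missing,
                 c("patient", "hemisphere", "contact", "erna_power",
                   "beta_power", "hfo_power")]
  anat <- study_anatomy_ranks(study, overrides = overrides)
  outc <- outcomes_table(study)
  assemble_analysis_table(feats, anat, outc)
}

#' Write / read study side files
#'
#' Plain-text interchange for the non-signal parts of a study: lead
#' geometry and landmarks as JSON, outcomes and analysis tables as CSV.
#'
#' @param study a [generate_study()] result.
#' @param path output file path.
#' @name study_io
NULL

#' @rdname study_io
#' @export
write_geometry_json <- function(study, path) {
  geo <- lapply(study$hemispheres, function(h) {
    lm <- h$geometry$landmarks
    list(contacts = unname(apply(h$geometry$contact_positions, 1,
                                 as.numeric, simplify = FALSE)),
         missing = h$params$missing,
         landmarks = list(
           anterior_border_point = lm$anterior_border_point,
           superior_border_z = lm$superior_border_z,
           lateral_border_x = lm$lateral_border_x, side = lm$side))
  })
  jsonlite::write_json(geo, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname study_io
#' @export
read_geometry_json <- function(path) {
  geo <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(geo, function(g) {
    lm <- red_nucleus_landmarks(
      as.numeric(g$landmarks$anterior_border_point),
      g$landmarks$superior_border_z, g$landmarks$lateral_border_x,
      g$landmarks$side)
    pos <- if (is.matrix(g$contacts)) g$contacts else
      do.call(rbind, lapply(g$contacts, as.numeric))
    contact_geometry(pos, lm, missing = as.logical(g$missing))
  })
}

#' @rdname study_io
#' @export
write_outcomes_csv <- function(study, path) {
  write.csv(outcomes_table(study), path, row.names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_outcomes_csv <- function(path) read.csv(path)
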