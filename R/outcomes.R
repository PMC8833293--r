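#' Motor benefit of stimulation
#'
#' Benefit is the percentage improvement of the hemibody UPDRS Part III
#' sum (items 20-26) with stimulation on relative to off:
#' `100 * (off - on) / off`. It can be negative (worsening) and equals
#' 100 exactly when the on-score is zero.
#'
#' @param off off-stimulation score, points (> 0).
#' @param on on-stimulation score(s), points (>= 0); vectorized.
#' @return Benefit in percent, same length as `on`.
#' @examples
#' compute_benefit(40, c(40, 0, 50))  # 0, 100, -25
#' @export
compute_benefit <- function(off, on) {
  if (!is.finite(off) || off <= 0)
    abort("off-stimulation score must be positive for benefit to be defined",
          "ernarank_undefined_benefit_error")
  if (any(on < 0, na.rm = TRUE))
    abort("on-stimulation scores must be non-negative",
          "ernarank_undefined_benefit_error")
  100 * (off - on) / off
}

#' Rank contacts by a per-contact value
#'
#' Rank 1 is the largest value for `"descending"` (signal powers,
#' benefit) and the smallest for `"ascending"` (distances). Ties are
#' broken toward the more dorsal contact (higher index), reflecting the
#' clinically favoured dorsal STN region; `NA` (missing) contacts are
#' ranked last, with the same dorsal-first rule among themselves.
#'
#' @param values numeric vector (position k = contact k-1).
#' @param direction `"descending"` or `"ascending"`.
#' @return Integer ranks `1:length(values)` in contact order.
#' @examples
#' rank_by_value(c(9, 1, 4, 2))                # 1 4 2 3
#' rank_by_value(c(2.1, 0.5, 1, 3), "ascending")  # 3 1 2 4
#' @export
rank_by_value <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (all(is.na(values)))
    abort("no finite values to rank", "ernarank_missing_error")
  key <- if (direction == "descending") -values else values
  key[is.na(key)] <- Inf
  ord <- order(key, -seq_along(key))
  ranks <- integer(length(values))
  ranks[ord] <- seq_along(values)
  ranks
}

#' Contacts yielding the maximal benefit
#'
#' @param benefits numeric length 4 (contacts 0-3), `NA` for untested
#'   contacts.
#' @return Integer vector of 0-based contact indices attaining the
#'   maximum (ties give multi-element sets).
#' @export
identify_best_contacts <- function(benefits) {
  if (all(is.na(benefits)))
    abort("no benefits supplied", "ernarank_missing_error")
  m <- max(benefits, na.rm = TRUE)
  which(!is.na(benefits) & benefits == m) - 1L
}

#' Per-factor concordance with the ideal contact
#'
#' For each ranking factor, the proportion of hemispheres in which a
#' rank-1 contact belongs to the set of contacts yielding maximal
#' benefit, together with the distribution of the ranks attained by the
#' best contacts (and, when available, by the clinician-selected
#' contacts).
#'
#' @param table an analysis table from [assemble_analysis_table()] (or
#'   any data.frame with `hemisphere`, `contact`, `benefit`,
#'   `rank_<factor>` columns and optionally `is_clinician_contact`).
#' @param factors character; ranking factors to summarize.
#' @return A list with `concordance` (named proportions), `n_hemispheres`,
#'   `best_rank_distribution` and (if available)
#'   `clinician_rank_distribution` — one rank-count matrix row per
#'   factor.
#' @export
concordance_summary <- function(table,
                                factors = c("erna", "beta", "hfo",
                                            "anatomy")) {
  hemis <- split(table, table$hemisphere)
  rank_cols <- paste0("rank_", factors)
  missing_cols <- setdiff(rank_cols, names(table))
  if (length(missing_cols))
    abort(paste("missing rank columns:",
                paste(missing_cols, collapse = ", ")),
          "ernarank_join_error")
  hit <- matrix(FALSE, length(hemis), length(factors),
                dimnames = list(names(hemis), factors))
  best_rank <- matrix(0L, length(factors), 4,
                      dimnames = list(factors, paste0("rank", 1:4)))
  clin_rank <- best_rank
  has_clin <- "is_clinician_contact" %in% names(table)
  for (h in seq_along(hemis)) {
    d <- hemis[[h]]
    best <- d$contact[which(d$benefit == max(d$benefit, na.rm = TRUE))]
    for (j in seq_along(factors)) {
      r <- d[[rank_cols[j]]]
      rank1 <- d$contact[which(r == 1)]
      hit[h, j] <- length(intersect(rank1, best)) > 0
      rb <- r[d$contact %in% best]
      for (rr in rb[!is.na(rb)])
        best_rank[j, rr] <- best_rank[j, rr] + 1L
      if (has_clin) {
        rc <- r[d$is_clinician_contact]
        for (rr in rc[!is.na(rc)])
          clin_rank[j, rr] <- clin_rank[j, rr] + 1L
      }
    }
  }
  out <- list(concordance = colMeans(hit), n_hemispheres = length(hemis),
              best_rank_distribution = best_rank)
  if (has_clin) out$clinician_rank_distribution <- clin_rank
  out
}

#' Assemble the long-format analysis table
#'
#' Joins per-contact features, anatomical ranks and clinical outcomes
#' into one row per tested contact, adding within-hemisphere rankings by
#' ERNA, beta and HFO power (descending), the benefit ranking, and
#' indicator columns for the clinician-selected and best contacts.
#'
#' @param features data.frame with `patient`, `hemisphere`, `contact`,
#'   `erna_power`, `beta_power`, `hfo_power` (NA at missing contacts).
#' @param anatomy_ranks data.frame with `hemisphere`, `contact`,
#'   `rank_anatomy`.
#' @param outcomes data.frame with `hemisphere`, `contact`, `off_updrs`,
#'   `on_updrs`, `stim_fraction`, `order_index`, `clinician_contact`.
#' @return A data.frame of class `analysis_table`, one row per tested
#'   contact.
#' @export
assemble_analysis_table <- function(features, anatomy_ranks, outcomes) {
  key <- function(d) paste(d$hemisphere, d$contact)
  for (nm in list(features, anatomy_ranks, outcomes))
    if (anyDuplicated(key(nm)))
      abort("duplicated (hemisphere, contact) rows in input",
            "ernarank_join_error")
  tab <- merge(features, anatomy_ranks, by = c("hemisphere", "contact"),
               all.x = TRUE)
  outcomes <- outcomes[, setdiff(names(outcomes), "patient"),
                       drop = FALSE]
  tab <- merge(tab, outcomes, by = c("hemisphere", "contact"))
  if (nrow(tab) == 0)
    return(structure(tab, class = c("analysis_table", "data.frame")))
  bad <- tab$hemisphere[is.na(tab$rank_anatomy)]
  if (length(bad))
    abort(paste("no anatomy ranks for hemisphere(s):",
                paste(unique(bad), collapse = ", ")),
          "ernarank_join_error")
  tab <- tab[order(tab$hemisphere, tab$contact), ]
  per_h <- split(seq_len(nrow(tab)), tab$hemisphere)
  tab$benefit <- NA_real_
  for (col in c("rank_erna", "rank_beta", "rank_hfo", "rank_benefit"))
    tab[[col]] <- NA_integer_
  tab$is_best_contact <- FALSE
  for (idx in per_h) {
    d <- tab[idx, ]
    ben <- compute_benefit(d$off_updrs[1], d$on_updrs)
    tab$benefit[idx] <- ben
    tab$rank_erna[idx] <- rank_by_value(d$erna_power)[seq_along(idx)]
    tab$rank_beta[idx] <- rank_by_value(d$beta_power)[seq_along(idx)]
    tab$rank_hfo[idx] <- rank_by_value(d$hfo_power)[seq_along(idx)]
    tab$rank_benefit[idx] <- rank_by_value(ben)[seq_along(idx)]
    tab$is_best_contact[idx] <- !is.na(ben) & ben == max(ben, na.rm = TRUE)
  }
  tab$is_clinician_contact <- tab$contact == tab$clinician_contact
  rownames(tab) <- NULL
  structure(tab, class = c("analysis_table", "data.frame"))
}
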