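#' Red-nucleus landmarks for indirect STN targeting
#'
#' The ideal stimulation target is nominated from the red nucleus on the
#' patient's native scan: along its anterior border (the Bejjani line),
#' 2 mm inferior to its superior border and 3 mm lateral to its lateral
#' border. Coordinates are millimetres in a right-handed scanner space
#' with +x toward the patient's right.
#'
#' @param anterior_border_point 3-vector (mm) on the Bejjani line; its y
#'   coordinate fixes the target's y.
#' @param superior_border_z z (mm) of the red nucleus superior border.
#' @param lateral_border_x x (mm) of the red nucleus lateral border.
#' @param side `"left"` or `"right"`; determines the lateral direction.
#' @return An object of class `rn_landmarks`.
#' @export
red_nucleus_landmarks <- function(anterior_border_point, superior_border_z,
                                  lateral_border_x,
                                  side = c("left", "right")) {
  side <- match.arg(side)
  if (length(anterior_border_point) != 3 ||
      !all(is.finite(anterior_border_point)) ||
      !is.finite(superior_border_z) || !is.finite(lateral_border_x))
    abort("landmark coordinates must be finite", "ernarank_config_error")
  structure(list(anterior_border_point = as.numeric(anterior_border_point),
                 superior_border_z = superior_border_z,
                 lateral_border_x = lateral_border_x, side = side),
            class = "rn_landmarks")
}

#' Ideal anatomical target from red-nucleus landmarks
#'
#' Constructs the nominated ideal stimulation site: 3 mm lateral to the
#' red-nucleus lateral border (the STN lies lateral to the red nucleus),
#' at the y of the supplied Bejjani-line point, 2 mm inferior to the
#' superior border.
#'
#' @param lm a [red_nucleus_landmarks()].
#' @param lateral_offset_mm lateral displacement from the lateral border
#'   (default 3 mm); sign is applied according to `lm$side`.
#' @return Numeric 3-vector (mm).
#' @examples
#' lm <- red_nucleus_landmarks(c(10, -8, -4), -4, 10, "right")
#' ideal_target_from_landmarks(lm)  # (13, -8, -6)
#' @export
ideal_target_from_landmarks <- function(lm, lateral_offset_mm = 3) {
  s <- if (lm$side == "right") 1 else -1
  c(lm$lateral_border_x + s * lateral_offset_mm,
    lm$anterior_border_point[2],
    lm$superior_border_z - 2)
}

#' Contact geometry of one quadripolar lead
#'
#' Holds the four contact centres (0-3, ventral to dorsal), the
#' red-nucleus landmarks, the derived ideal target and the Euclidean
#' distance of each contact from it. The lead model is a 1.5 mm contact /
#' 1.5 mm gap array, so adjacent contact centres must be 3 mm apart.
#'
#' @param contact_positions 4 x 3 numeric matrix (mm), rows = contacts
#'   0-3.
#' @param landmarks a [red_nucleus_landmarks()].
#' @param missing logical length 4; faulted contacts.
#' @param spacing_tol tolerance (mm) on the 3 mm centre-to-centre spacing.
#' @return An object of class `contact_geometry` with elements
#'   `contact_positions`, `landmarks`, `ideal_target`, `distances`,
#'   `missing`.
#' @export
contact_geometry <- function(contact_positions, landmarks,
                             missing = rep(FALSE, 4), spacing_tol = 0.2) {
  contact_positions <- as.matrix(contact_positions)
  if (!all(dim(contact_positions) == c(4, 3)))
    abort("contact_positions must be a 4 x 3 matrix",
          "ernarank_config_error")
  spacing <- sqrt(rowSums(diff(contact_positions)^2))
  if (any(abs(spacing - 3) > spacing_tol))
    abort(sprintf(
      "centre-to-centre contact spacing must be 3 mm (got %s)",
      paste(sprintf("%.2f", spacing), collapse = ", ")),
      "ernarank_config_error")
  target <- ideal_target_from_landmarks(landmarks)
  g <- structure(list(contact_positions = contact_positions,
                      landmarks = landmarks, ideal_target = target,
                      missing = missing),
                 class = "contact_geometry")
  g$distances <- distances_to_target(g)
  g
}

#' Euclidean distance of each contact from the ideal target
#'
#' @param geom a [contact_geometry()].
#' @return Numeric length 4 (mm), contacts 0-3.
#' @export
distances_to_target <- function(geom) {
  sqrt(colSums((t(geom$contact_positions) - geom$ideal_target)^2))
}

#' Rank contacts by proximity to the ideal target
#'
#' Rank 1 is the closest contact. Ties are broken toward the more dorsal
#' contact (higher index); missing contacts are ranked last.
#'
#' @param distances numeric length 4 (mm); `NA` for missing contacts.
#' @return Integer ranks 1-4 indexed by contact (position k = contact
#'   k-1).
#' @export
rank_contacts_by_distance <- function(distances) {
  if (all(is.na(distances)))
    abort("all contacts missing: no ranking possible",
          "ernarank_missing_error")
  rank_by_value(distances, direction = "ascending")
}

#' Apply expert rank overrides
#'
#' The landmark-based ranking may be adjusted by an expert who inspects
#' contact position within the STN (centrality, local STN width ideally
#' >= 2 mm). Overrides are declarative — contact, new rank, reason — and
#' the result must remain a permutation of the original ranks.
#'
#' @param ranks integer ranks (contacts 0-3 at positions 1-4).
#' @param overrides data.frame with columns `contact` (0-3), `new_rank`
#'   and `reason`; may have zero rows.
#' @return Re-ranked integer vector with an `audit` attribute recording
#'   each override (contact, original rank, new rank, reason).
#' @export
apply_expert_overrides <- function(ranks, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0) {
    attr(ranks, "audit") <- data.frame(contact = integer(),
                                       original_rank = integer(),
                                       new_rank = integer(),
                                       reason = character())
    return(ranks)
  }
  if (!all(overrides$contact %in% 0:3))
    abort("override contacts must be in 0-3", "ernarank_validation_error")
  out <- ranks
  audit <- data.frame(contact = overrides$contact,
                      original_rank = ranks[overrides$contact + 1],
                      new_rank = overrides$new_rank,
                      reason = as.character(overrides$reason))
  out[overrides$contact + 1] <- overrides$new_rank
  ok <- !is.na(out)
  if (anyDuplicated(out[ok]) || !setequal(out[ok], sort(ranks[ok])))
    abort("expert overrides must yield a permutation of the original ranks",
          "ernarank_validation_error")
  attr(out, "audit") <- audit
  out
}
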