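#' Stimulus geometry of the dichoptic display
#'
#' Describes the rivalry display as an abstract layout: two adjacent
#' grating discs per eye, offset diagonally from a central fixation cross.
#' All lengths are in degrees of visual angle.
#'
#' @param disc_diameter Disc diameter (deg). Default 1.8.
#' @param grating_spatial_frequency Grating spatial frequency (cycles/deg).
#'   Default 4.
#' @param inter_disc_gap Separation gap between the two discs (deg).
#'   Default 0.2.
#' @param fixation_cross_size Fixation cross size (deg). Default 0.5.
#' @param horizontal_offset,vertical_offset Offsets of a disc centre from
#'   fixation (deg, non-negative). Defaults 1 and 1.
#'
#' @return A one-row tibble with the parameters plus the derived
#'   `diagonal_eccentricity` (Euclidean norm of the two offsets).
#' @export
#' @examples
#' stimulus_layout()$diagonal_eccentricity # sqrt(2) ~ 1.41 deg
stimulus_layout <- function(disc_diameter = 1.8,
                            grating_spatial_frequency = 4,
                            inter_disc_gap = 0.2,
                            fixation_cross_size = 0.5,
                            horizontal_offset = 1,
                            vertical_offset = 1) {
  check_number(disc_diameter, "disc_diameter", lower = 1e-12)
  check_number(grating_spatial_frequency, "grating_spatial_frequency", lower = 1e-12)
  check_number(inter_disc_gap, "inter_disc_gap", lower = 1e-12)
  check_number(fixation_cross_size, "fixation_cross_size", lower = 1e-12)
  check_number(horizontal_offset, "horizontal_offset", lower = 0)
  check_number(vertical_offset, "vertical_offset", lower = 0)
  tibble(
    disc_diameter = disc_diameter,
    grating_spatial_frequency = grating_spatial_frequency,
    inter_disc_gap = inter_disc_gap,
    fixation_cross_size = fixation_cross_size,
    horizontal_offset = horizontal_offset,
    vertical_offset = vertical_offset,
    diagonal_eccentricity = stimulus_geometry(horizontal_offset, vertical_offset)
  )
}

#' Diagonal eccentricity from horizontal and vertical offsets
#'
#' @param horizontal_offset,vertical_offset Non-negative offsets in degrees.
#'   Vectorised.
#' @return The Euclidean norm `sqrt(h^2 + v^2)` in degrees.
#' @export
#' @examples
#' stimulus_geometry(1, 1) # 1.414... deg, printed as 1.41
#' stimulus_geometry(3, 4) # 5
stimulus_geometry <- function(horizontal_offset, vertical_offset) {
  if (!is.numeric(horizontal_offset) || !is.numeric(vertical_offset) ||
    any(!is.finite(horizontal_offset)) || any(!is.finite(vertical_offset)) ||
    any(horizontal_offset < 0) || any(vertical_offset < 0)) {
    abort("`horizontal_offset` and `vertical_offset` must be finite and non-negative.")
  }
  sqrt(horizontal_offset^2 + vertical_offset^2)
}

other_orientation <- function(o) ifelse(o == "H", "V", "H")

#' Layout of a single trial condition
#'
#' Returns the per-eye disc layout for one viewing condition and
#' counterbalance variant. At every position the two eyes carry orthogonal
#' grating orientations (a rivalrous pair). In same-eye (SE) conditions each
#' eye's two discs share one orientation; in different-eye (DE) conditions
#' each eye carries one horizontal and one vertical disc. Same-hemifield (SH)
#' conditions place both discs in one lateral hemifield; different-hemifield
#' (DH) conditions place them above and below fixation. `CENTRAL` is the
#' single-position classical rivalry control.
#'
#' Counterbalance convention: variant 1 assigns the horizontal orientation
#' rule to the left eye and (for SH conditions) uses the left hemifield;
#' variant 2 swaps both assignments.
#'
#' @param condition_id One of `"MO_SE_SH"`, `"MO_SE_DH"`, `"MO_DE_SH"`,
#'   `"MO_DE_DH"`, `"CENTRAL"`.
#' @param variant Counterbalance variant, 1 or 2 (`CENTRAL` has only 1).
#' @return A tibble with columns `condition_id`, `variant`, `eye`
#'   (`"left"`/`"right"`), `position`, `orientation` (`"H"`/`"V"`), one row
#'   per disc.
#' @export
condition_layout <- function(condition_id, variant = 1L) {
  condition_id <- match.arg(condition_id, condition_levels)
  if (!variant %in% c(1L, 2L)) {
    abort("`variant` must be 1 or 2.")
  }
  if (condition_id == "CENTRAL") {
    if (variant != 1L) {
      abort("the CENTRAL condition has a single variant.")
    }
    return(tibble(
      condition_id = condition_id, variant = 1L,
      eye = c("left", "right"), position = "center", orientation = c("H", "V")
    ))
  }
  left_eye_ori <- if (variant == 1L) "H" else "V"
  positions <- if (endsWith(condition_id, "SH")) {
    if (variant == 1L) c("left-upper", "left-lower") else c("right-upper", "right-lower")
  } else {
    c("above", "below")
  }
  if (startsWith(condition_id, "MO_SE")) {
    left <- c(left_eye_ori, left_eye_ori)
  } else {
    left <- c(left_eye_ori, other_orientation(left_eye_ori))
  }
  tibble(
    condition_id = condition_id, variant = as.integer(variant),
    eye = rep(c("left", "right"), each = 2L),
    position = rep(positions, 2L),
    orientation = c(left, other_orientation(left))
  )
}

#' Build the full trial-condition catalog
#'
#' The grouping block comprises 4 logical viewing conditions x 2
#' counterbalanced variants = 8 trials; an optional central control trial is
#' appended. The catalog is fully determined (no randomness): serialising it
#' twice yields identical output.
#'
#' @param include_central Include the central single-target control trial?
#'   Default `TRUE`.
#' @return A tibble with one row per disc and columns `trial` (1-based trial
#'   index in catalog order), `condition_id`, `variant`, `eye`, `position`,
#'   `orientation`.
#' @export
#' @examples
#' cond <- build_condition_set()
#' dplyr::n_distinct(cond$trial) # 9
build_condition_set <- function(include_central = TRUE) {
  grid <- tidyr::expand_grid(
    condition_id = condition_levels[condition_levels != "CENTRAL"],
    variant = 1:2
  )
  layouts <- purrr::pmap(grid, condition_layout)
  if (isTRUE(include_central)) {
    layouts <- c(layouts, list(condition_layout("CENTRAL", 1L)))
  }
  out <- purrr::imap(layouts, function(x, i) mutate(x, trial = as.integer(i)))
  dplyr::relocate(bind_rows(out), "trial")
}

#' Reproducibly shuffle the presentation order of a condition catalog
#'
#' Permutes whole trials (blocks of rows sharing one `trial` id) with a fixed
#' seed; the caller's RNG state is untouched.
#'
#' @param conditions A condition catalog as returned by
#'   [build_condition_set()].
#' @param seed Integer seed controlling the permutation.
#' @return The catalog with trial blocks reordered; `trial` ids are kept so
#'   the original catalog position remains identifiable.
#' @export
randomize_order <- function(conditions, seed) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0L) {
    abort("`conditions` must be a non-empty data frame.")
  }
  if (!"trial" %in% names(conditions)) {
    abort("`conditions` must have a `trial` column.")
  }
  trials <- unique(conditions$trial)
  perm <- with_seed(seed, sample(trials))
  conditions[order(match(conditions$trial, perm)), , drop = FALSE]
}
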