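#' Define a factorial visuoauditory stimulus design
#'
#' Enumerates every combination of visual intensity, auditory intensity,
#' visual azimuth, and auditory azimuth, then collapses redundant patterns:
#' when a modality's intensity is at its "off" level (visual contrast 0, or
#' no sound), the location of that modality is irrelevant, so all patterns
#' differing only in that location are a single non-redundant pattern whose
#' azimuth is recorded as `NA`.
#'
#' The default design is 5 visual contrasts (including 0) x 5 auditory
#' levels (including no sound) x 3 visual x 3 auditory locations 30 degrees
#' apart: 225 raw patterns, collapsing to 168 non-redundant stimulus
#' patterns (144 bimodal, 12 visual-only, 12 auditory-only) plus one blank
#' pattern. The blank (no stimulus at all) pattern is enumerated and
#' flagged, but is excluded from the non-redundant count and from the
#' deviance sum; it only serves to measure the baseline rate.
#'
#' Conventions: visual intensity is the absolute fractional contrast of the
#' dark spot (0 to 1, 0 = no stimulus); auditory intensity is the sound
#' level in dB SPL with 0 meaning no sound; azimuths are in degrees,
#' positive toward the contralateral side.
#'
#' @param visual_intensities Numeric vector of visual contrasts, must
#'   include 0 (stimulus absent).
#' @param auditory_intensities Numeric vector of sound levels (dB SPL),
#'   must include 0 (no sound).
#' @param visual_azimuths,auditory_azimuths Numeric vectors of stimulus
#'   locations in degrees.
#'
#' @return An object of class `msi_grid`: a list with the level vectors,
#'   the counts `n_total`, `n_nonredundant`, `n_bimodal`, and `patterns`,
#'   a tibble with one row per non-redundant pattern (columns `pattern_id`,
#'   `phi_V`, `phi_A`, `I_V`, `I_A`, `visual_present`, `auditory_present`,
#'   `type`). Row order is deterministic: patterns are sorted by
#'   (`I_V`, `phi_V`, `I_A`, `phi_A`) with absent-modality azimuths (`NA`)
#'   sorted first.
#' @examples
#' g <- stimulus_grid()
#' g$n_total          # 225
#' g$n_nonredundant   # 168
#' g$n_bimodal        # 144
#' @export
stimulus_grid <- function(visual_intensities = c(0, 0.29, 0.50, 0.65, 0.75),
                          auditory_intensities = c(0, 20, 30, 40, 50),
                          visual_azimuths = c(0, 30, 60),
                          auditory_azimuths = c(0, 30, 60)) {
  check_levels <- function(x, what, allow_negative = FALSE) {
    if (length(x) < 1 || anyNA(x) || !is.numeric(x)) {
      abort(paste0("`", what, "` must be a non-empty numeric vector."),
            class = "scmsi_invalid_design")
    }
    if (anyDuplicated(x)) {
      abort(paste0("duplicate values in `", what, "`."),
            class = "scmsi_invalid_design")
    }
    if (!allow_negative && any(x < 0)) {
      abort(paste0("`", what, "` must be non-negative."),
            class = "scmsi_invalid_design")
    }
    invisible(x)
  }
  check_levels(visual_intensities, "visual_intensities")
  check_levels(auditory_intensities, "auditory_intensities")
  check_levels(visual_azimuths, "visual_azimuths", allow_negative = TRUE)
  check_levels(auditory_azimuths, "auditory_azimuths", allow_negative = TRUE)
  if (!0 %in% visual_intensities || !0 %in% auditory_intensities) {
    abort("each modality needs a zero (stimulus-absent) intensity level.",
          class = "scmsi_invalid_design")
  }

  full <- tidyr::expand_grid(
    I_V = sort(visual_intensities),
    phi_V = sort(visual_azimuths),
    I_A = sort(auditory_intensities),
    phi_A = sort(auditory_azimuths)
  )
  n_total <- nrow(full)

  pats <- full |>
    dplyr::mutate(
      visual_present = .data$I_V > 0,
      auditory_present = .data$I_A > 0,
      phi_V = ifelse(.data$visual_present, .data$phi_V, NA_real_),
      phi_A = ifelse(.data$auditory_present, .data$phi_A, NA_real_)
    ) |>
    dplyr::distinct() |>
    dplyr::mutate(type = dplyr::case_when(
      .data$visual_present & .data$auditory_present ~ "bimodal",
      .data$visual_present ~ "visual",
      .data$auditory_present ~ "auditory",
      TRUE ~ "blank"
    )) |>
    dplyr::arrange(.data$I_V, .data$phi_V, .data$I_A, .data$phi_A) |>
    dplyr::mutate(pattern_id = dplyr::row_number(), .before = 1)

  structure(
    list(
      visual_intensities = sort(visual_intensities),
      auditory_intensities = sort(auditory_intensities),
      visual_azimuths = sort(visual_azimuths),
      auditory_azimuths = sort(auditory_azimuths),
      n_total = n_total,
      n_nonredundant = sum(pats$type != "blank"),
      n_bimodal = sum(pats$type == "bimodal"),
      patterns = pats
    ),
    class = "msi_grid"
  )
}

#' @export
print.msi_grid <- function(x, ...) {
  cat("<msi_grid> factorial visuoauditory design\n")
  cat("  visual intensities:  ", paste(x$visual_intensities, collapse = ", "), "\n")
  cat("  auditory intensities:", paste(x$auditory_intensities, collapse = ", "), "dB\n")
  cat("  visual azimuths:     ", paste(x$visual_azimuths, collapse = ", "), "deg\n")
  cat("  auditory azimuths:   ", paste(x$auditory_azimuths, collapse = ", "), "deg\n")
  cat(sprintf("  patterns: %d total, %d non-redundant (%d bimodal)\n",
              x$n_total, x$n_nonredundant, x$n_bimodal))
  invisible(x)
}

#' Extract the pattern table of a stimulus design
#'
#' @param grid An [stimulus_grid()] object.
#' @param blank Keep the all-blank pattern? Default `FALSE` (the blank
#'   pattern is not part of the likelihood sum).
#' @return A tibble of stimulus patterns.
#' @export
patterns <- function(grid, blank = FALSE) {
  stopifnot(inherits(grid, "msi_grid"))
  p <- grid$patterns
  if (!blank) p <- dplyr::filter(p, .data$type != "blank")
  p
}
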