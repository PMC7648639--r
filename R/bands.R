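#' Define a single absorption band
#'
#' A band is a Gaussian absorbance profile
#' `A(nu) = base_amplitude * exp(-(nu - center)^2 / (2 * width^2))`.
#' `class_effect` is the fractional amplitude difference of the "case"
#' class relative to "control" (0.15 means cases absorb 15% more at this
#' band on average; negative values mean less).
#'
#' @param center band centre, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param base_amplitude control-class peak absorbance (>= 0).
#' @param class_effect fractional case-vs-control amplitude difference.
#' @param assignment free-text biochemical assignment.
#' @return one-row data.frame with the five fields above.
#' @export
band_spec <- function(center, width, base_amplitude, class_effect = 0,
                      assignment = "") {
  if (!is.finite(width) || width <= 0)
    stop("band width must be > 0", call. = FALSE)
  if (!is.finite(base_amplitude) || base_amplitude < 0)
    stop("base_amplitude must be >= 0", call. = FALSE)
  data.frame(center = as.numeric(center), width = as.numeric(width),
             base_amplitude = as.numeric(base_amplitude),
             class_effect = as.numeric(class_effect),
             assignment = as.character(assignment),
             stringsAsFactors = FALSE)
}

#' Default band library for synthetic plasma spectra
#'
#' Ten class-discriminating bands at the wavenumbers a GA-LDA analysis of
#' case/control plasma typically flags (water/glycogen region 901 and
#' 1047 cm^-1; lipid/protein region 1462-1747 cm^-1), each carrying a
#' fractional class effect of magnitude `effect`, plus non-discriminating
#' filler bands reproducing the gross shape of a plasma infrared spectrum.
#' The Amide I anchor at 1650 cm^-1 carries no class effect, so
#' normalisation to that band is well-posed. Amplitudes are relative to
#' the Amide I peak (= 1).
#'
#' @param effect magnitude of the planted fractional class effect on the
#'   discriminating bands (default 0.15). Set 0 for a null cohort.
#' @return data.frame of band specifications (one row per band).
#' @export
default_band_library <- function(effect = 0.15) {
  e <- effect
  rbind(
    # discriminating bands (sign pattern fixed; magnitude = effect)
    band_spec( 901, 12, 0.08,  e, "phosphodiester stretching (collagen/glycogen)"),
    band_spec(1047, 18, 0.15, -e, "glycogen OH stretch/bend"),
    band_spec(1462, 10, 0.12,  e, "CH2 scissoring, lipid acyl chain"),
    band_spec(1539, 15, 0.40, -e, "Amide II, beta-sheet"),
    band_spec(1560, 10, 0.10,  e, "ring base mode"),
    band_spec(1582, 10, 0.08,  e, "ring C-C stretch"),
    band_spec(1645, 16, 0.55, -e, "Amide I"),
    band_spec(1661, 16, 0.50,  e, "Amide I"),
    band_spec(1693, 12, 0.15,  e, "antiparallel beta-sheet Amide I"),
    band_spec(1747,  9, 0.10,  e, "nu(C=O) ester carbonyl"),
    # non-discriminating envelope / filler bands
    band_spec(1650, 25, 1.00,  0, "Amide I envelope (normalisation anchor)"),
    band_spec(1550, 22, 0.55,  0, "Amide II envelope"),
    band_spec(1400, 14, 0.18,  0, "COO- symmetric stretch"),
    band_spec(1240, 16, 0.15,  0, "Amide III / PO2- asymmetric stretch"),
    band_spec(1120, 14, 0.10,  0, "C-O stretch, carbohydrates"),
    band_spec(1080, 12, 0.15,  0, "PO2- symmetric stretch"),
    band_spec( 970, 10, 0.08,  0, "C-N+ stretch"),
    band_spec(2930, 18, 0.30,  0, "CH2 asymmetric stretch"),
    band_spec(2960, 14, 0.20,  0, "CH3 asymmetric stretch"),
    band_spec(3300, 80, 0.80,  0, "Amide A / OH stretch"))
}

#' Evaluate a sum of Gaussian bands on an axis
#'
#' @param bands data.frame of band specs ([band_spec()] rows).
#' @param axis strictly monotone wavenumber vector, cm^-1.
#' @param amplitude_multipliers numeric, one factor per band applied to
#'   `base_amplitude`.
#' @return absorbance vector of `length(axis)`:
#'   `sum_b mult_b * amp_b * exp(-(nu - center_b)^2 / (2 width_b^2))`.
#' @export
band_profile <- function(bands, axis,
                         amplitude_multipliers = rep(1, nrow(bands))) {
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0)))
    stop("axis must be strictly monotone", call. = FALSE)
  if (length(amplitude_multipliers) != nrow(bands))
    stop("need one amplitude multiplier per band (", nrow(bands),
         "), got ", length(amplitude_multipliers), call. = FALSE)
  y <- numeric(length(axis))
  for (b in seq_len(nrow(bands)))
    y <- y + amplitude_multipliers[b] * bands$base_amplitude[b] *
      exp(-(axis - bands$center[b])^2 / (2 * bands$width[b]^2))
  y
}
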