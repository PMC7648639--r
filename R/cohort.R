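#' Configuration for a synthetic case/control cohort
#'
#' Defaults emulate a typical clinical ATR-FTIR plasma study: 50 subjects
#' per class measured in triplicate (300 spectra), axis 600-4000 cm^-1 on
#' a 4 cm^-1 grid (851 points), smooth Gaussian band spectra with planted
#' class effects, multiplicative between-subject and within-subject
#' (replicate) variability, a random low-order polynomial baseline and
#' additive white noise.
#'
#' @param n_per_class subjects per class (>= 1).
#' @param n_replicates spectra per subject (>= 1).
#' @param axis_min,axis_max,axis_step wavenumber grid, cm^-1.
#' @param bands band library data.frame (see [default_band_library()]).
#' @param subject_sd between-subject fractional amplitude sd per band.
#' @param replicate_sd within-subject fractional sd per replicate
#'   (a scalar factor on the whole spectrum, emulating contact-pressure
#'   and aliquot variation).
#' @param noise_sd additive white-noise sd, absorbance units.
#' @param baseline_order polynomial degree of the random baseline drift.
#' @param baseline_scale sd of the baseline polynomial coefficients,
#'   absorbance units (on an axis rescaled to \[-1, 1\]).
#' @param seed integer RNG seed; generation is a pure function of the
#'   configuration including this seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = 50, n_replicates = 3,
                          axis_min = 600, axis_max = 4000, axis_step = 4,
                          bands = default_band_library(),
                          subject_sd = 0.05, replicate_sd = 0.02,
                          noise_sd = 0.002, baseline_order = 3,
                          baseline_scale = 0.02, seed = 1) {
  stopifnot(n_per_class >= 1, n_replicates >= 1,
            axis_min < axis_max, axis_step > 0,
            subject_sd >= 0, replicate_sd >= 0, noise_sd >= 0,
            baseline_order >= 0, baseline_scale >= 0,
            is.data.frame(bands), nrow(bands) >= 1)
  if (any(bands$center < axis_min | bands$center > axis_max))
    stop("every band centre must lie inside [axis_min, axis_max]",
         call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_replicates = as.integer(n_replicates),
                 axis_min = axis_min, axis_max = axis_max,
                 axis_step = axis_step, bands = bands,
                 subject_sd = subject_sd, replicate_sd = replicate_sd,
                 noise_sd = noise_sd,
                 baseline_order = as.integer(baseline_order),
                 baseline_scale = baseline_scale,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Field names mirror [cohort_config()] exactly; `bands`, if present, is
#' a list of records with the [band_spec()] field names. Missing fields
#' take the package defaults.
#'
#' @param path YAML file path.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$bands)) {
    y$bands <- do.call(rbind, lapply(y$bands, function(b)
      band_spec(b$center, b$width, b$base_amplitude,
                if (is.null(b$class_effect)) 0 else b$class_effect,
                if (is.null(b$assignment)) "" else b$assignment)))
  }
  do.call(cohort_config, y)
}

#' Generate a synthetic two-class spectral cohort
#'
#' For each subject, per-band amplitude multipliers are drawn as
#' `(1 + class_effect * [case]) * (1 + N(0, subject_sd))`; each replicate
#' spectrum further scales the whole profile by `1 + N(0, replicate_sd)`
#' and adds a random polynomial baseline and white noise. The output is
#' a pure function of the configuration (including its seed).
#'
#' @param config a [cohort_config()].
#' @return a [spectral_dataset()] with
#'   `2 * n_per_class * n_replicates` spectra; class labels are
#'   `"case"` and `"control"`, sample ids `case_01`, ... , `control_50`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  axis <- seq(cfg$axis_min, cfg$axis_max, by = cfg$axis_step)
  bands <- cfg$bands
  nb <- nrow(bands)
  # band profiles as a matrix so each spectrum is one matrix-vector product
  profiles <- vapply(seq_len(nb), function(b)
    bands$base_amplitude[b] *
      exp(-(axis - bands$center[b])^2 / (2 * bands$width[b]^2)),
    numeric(length(axis)))
  t_axis <- if (length(axis) > 1)
    2 * (axis - mean(axis)) / diff(range(axis)) else axis * 0
  bl_basis <- outer(t_axis, 0:cfg$baseline_order, `^`)

  n_sub <- 2L * cfg$n_per_class
  n_tot <- n_sub * cfg$n_replicates
  X <- matrix(0, n_tot, length(axis))
  sample_id <- character(n_tot)
  class_label <- character(n_tot)
  replicate <- integer(n_tot)
  wid <- max(2L, nchar(as.character(cfg$n_per_class)))
  r <- 1L
  for (cl in c("case", "control")) {
    eff <- if (cl == "case") bands$class_effect else rep(0, nb)
    for (s in seq_len(cfg$n_per_class)) {
      mult_s <- (1 + eff) * (1 + stats::rnorm(nb, 0, cfg$subject_sd))
      sid <- sprintf("%s_%0*d", cl, wid, s)
      for (k in seq_len(cfg$n_replicates)) {
        mult <- mult_s * (1 + stats::rnorm(1, 0, cfg$replicate_sd))
        bl <- drop(bl_basis %*%
                     stats::rnorm(cfg$baseline_order + 1L, 0,
                                  cfg$baseline_scale))
        X[r, ] <- drop(profiles %*% mult) + bl +
          stats::rnorm(length(axis), 0, cfg$noise_sd)
        sample_id[r] <- sid
        class_label[r] <- cl
        replicate[r] <- k
        r <- r + 1L
      }
    }
  }
  spectral_dataset(X, axis, sample_id, class_label, replicate)
}
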