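#' Preprocessing configuration
#'
#' Defaults reproduce the standard plasma-fingerprint chain: cut to the
#' 1800-900 cm^-1 biofingerprint region, Savitzky-Golay smoothing with a
#' 15-point window and 2nd-order polynomial, automatic weighted
#' least-squares (AWLS) baseline correction, and normalisation to the
#' Amide I band at 1650 cm^-1.
#'
#' @param cut_low,cut_high retained wavenumber interval, cm^-1 (closed).
#' @param sg_window Savitzky-Golay window length, odd point count.
#' @param sg_polyorder Savitzky-Golay polynomial order (< sg_window).
#' @param awls_degree baseline polynomial degree.
#' @param awls_max_iter maximum reweighting iterations.
#' @param awls_tol relative L2 change of the fitted baseline below which
#'   iteration stops.
#' @param norm_anchor normalisation anchor wavenumber, cm^-1.
#' @param norm_halfwidth half-width of the anchor window, cm^-1; each
#'   spectrum is divided by its maximum within
#'   `[anchor - halfwidth, anchor + halfwidth]`.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(cut_low = 900, cut_high = 1800,
                              sg_window = 15, sg_polyorder = 2,
                              awls_degree = 4, awls_max_iter = 50,
                              awls_tol = 1e-6,
                              norm_anchor = 1650, norm_halfwidth = 10) {
  stopifnot(cut_low < cut_high, sg_window %% 2 == 1,
            sg_window > sg_polyorder, awls_degree >= 0,
            awls_max_iter >= 1, awls_tol > 0, norm_halfwidth >= 0)
  structure(list(cut_low = cut_low, cut_high = cut_high,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 awls_degree = as.integer(awls_degree),
                 awls_max_iter = as.integer(awls_max_iter),
                 awls_tol = awls_tol, norm_anchor = norm_anchor,
                 norm_halfwidth = norm_halfwidth),
            class = "preprocess_config")
}

#' Cut a wavenumber region
#'
#' Retains exactly the columns with `cut_low <= nu <= cut_high` (closed
#' interval); metadata and column order are unchanged.
#'
#' @param x a [spectral_dataset()].
#' @param cut_low,cut_high interval bounds, cm^-1.
#' @return the cut `spectral_dataset`.
#' @export
cut_region <- function(x, cut_low = 900, cut_high = 1800) {
  stopifnot(inherits(x, "spectral_dataset"), cut_low <= cut_high)
  keep <- x$axis >= cut_low & x$axis <= cut_high
  if (!any(keep))
    stop("no wavenumbers inside [", cut_low, ", ", cut_high, "] cm^-1",
         call. = FALSE)
  replace_absorbance(x, x$absorbance[, keep, drop = FALSE],
                     axis = x$axis[keep])
}

#' Savitzky-Golay smoothing
#'
#' Convolves each spectrum with the least-squares Savitzky-Golay kernel
#' (via [signal::sgolayfilt()]); output length equals input length, with
#' edges handled by the standard off-centre polynomial fits, so every
#' polynomial of degree `<= sg_polyorder` is reproduced exactly.
#'
#' @param x a [spectral_dataset()] on a uniform axis.
#' @param sg_window odd window length in points.
#' @param sg_polyorder polynomial order.
#' @return the smoothed `spectral_dataset`.
#' @export
savgol_smooth <- function(x, sg_window = 15, sg_polyorder = 2) {
  stopifnot(inherits(x, "spectral_dataset"))
  if (sg_window %% 2 != 1)
    stop("sg_window must be odd", call. = FALSE)
  if (sg_window > length(x$axis))
    stop("sg_window (", sg_window, ") exceeds the number of ",
         "wavenumbers (", length(x$axis), ")", call. = FALSE)
  if (sg_polyorder >= sg_window)
    stop("sg_polyorder must be < sg_window", call. = FALSE)
  steps <- diff(x$axis)
  if (max(steps) - min(steps) > 1e-8 * max(abs(steps)))
    stop("Savitzky-Golay smoothing requires a uniform axis",
         call. = FALSE)
  sm <- t(apply(x$absorbance, 1, signal::sgolayfilt,
                p = sg_polyorder, n = sg_window))
  replace_absorbance(x, sm)
}

# one-spectrum AWLS: iterative asymmetric reweighted polynomial fit.
# Returns the fitted baseline.
awls_baseline_one <- function(y, basis, max_iter, tol) {
  w <- rep(1, length(y))
  bl <- rep(0, length(y))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sw <- sqrt(w)
    beta <- qr.coef(qr(basis * sw), y * sw)
    bl_new <- drop(basis %*% beta)
    if (sqrt(sum((bl_new - bl)^2)) <=
        tol * max(sqrt(sum(bl_new^2)), .Machine$double.eps)) {
      bl <- bl_new
      converged <- TRUE
      break
    }
    bl <- bl_new
    r <- y - bl
    s <- stats::sd(r[r > 0])
    if (!is.finite(s) || s == 0) {          # nothing above the baseline
      converged <- TRUE
      break
    }
    w <- ifelse(r > 0, exp(-r / s), 1)
  }
  attr(bl, "converged") <- converged
  bl
}

#' Automatic weighted least-squares baseline correction
#'
#' Per spectrum, iteratively fits a weighted polynomial of degree
#' `awls_degree`: weights start at 1; after each fit, points with
#' positive residual `r` (peaks) are down-weighted to `exp(-r / s)` with
#' `s` the standard deviation of the positive residuals, points at or
#' below the fit keep weight 1. Iteration stops when the fitted baseline
#' changes by less than `awls_tol` in relative L2 norm, or after
#' `awls_max_iter` iterations (with a warning). The final baseline is
#' subtracted.
#'
#' @param x a [spectral_dataset()].
#' @param awls_degree polynomial degree (must be < number of points).
#' @param awls_max_iter maximum iterations.
#' @param awls_tol relative convergence threshold.
#' @return the baseline-corrected `spectral_dataset`.
#' @export
awls_baseline <- function(x, awls_degree = 4, awls_max_iter = 50,
                          awls_tol = 1e-6) {
  stopifnot(inherits(x, "spectral_dataset"), awls_degree >= 0)
  p <- length(x$axis)
  if (awls_degree >= p)
    stop("awls_degree (", awls_degree, ") must be smaller than the ",
         "number of wavenumbers (", p, ")", call. = FALSE)
  t_axis <- if (p > 1) 2 * (x$axis - mean(x$axis)) / diff(range(x$axis))
            else x$axis * 0
  basis <- outer(t_axis, 0:awls_degree, `^`)
  out <- x$absorbance
  n_fail <- 0L
  for (i in seq_len(nrow(out))) {
    bl <- awls_baseline_one(out[i, ], basis, awls_max_iter, awls_tol)
    if (!attr(bl, "converged")) n_fail <- n_fail + 1L
    out[i, ] <- out[i, ] - bl
  }
  if (n_fail > 0L)
    warning("AWLS baseline did not converge within ", awls_max_iter,
            " iterations for ", n_fail, " spectrum/spectra",
            call. = FALSE)
  replace_absorbance(x, out)
}

#' Normalise to a reference band
#'
#' Divides each spectrum by its maximum absorbance within
#' `[norm_anchor - norm_halfwidth, norm_anchor + norm_halfwidth]`
#' (default: the Amide I band, 1650 +/- 10 cm^-1). After normalisation
#' that window maximum equals 1 exactly.
#'
#' @param x a [spectral_dataset()].
#' @param norm_anchor anchor wavenumber, cm^-1.
#' @param norm_halfwidth window half-width, cm^-1.
#' @return the normalised `spectral_dataset`.
#' @export
normalize_to_band <- function(x, norm_anchor = 1650, norm_halfwidth = 10) {
  stopifnot(inherits(x, "spectral_dataset"))
  win <- x$axis >= norm_anchor - norm_halfwidth &
         x$axis <= norm_anchor + norm_halfwidth
  if (!any(win))
    stop("normalisation window [", norm_anchor - norm_halfwidth, ", ",
         norm_anchor + norm_halfwidth, "] contains no wavenumbers",
         call. = FALSE)
  mx <- apply(x$absorbance[, win, drop = FALSE], 1, max)
  bad <- which(mx <= 0)
  if (length(bad))
    stop("non-positive absorbance maximum in the normalisation window ",
         "for spectrum ", x$sample_id[bad[1]], " replicate ",
         x$replicate[bad[1]], call. = FALSE)
  replace_absorbance(x, x$absorbance / mx)
}

#' Training-set mean-centring
#'
#' Computes the columnwise mean of the training spectra only; the
#' returned object can then be applied to any dataset sharing the same
#' axis (validation/test are centred with the training mean, so no
#' information leaks from held-out data).
#'
#' @param train a [spectral_dataset()] (>= 1 spectrum).
#' @return object of class `spectral_centering` with fields `center`
#'   and `axis`.
#' @export
mean_center <- function(train) {
  stopifnot(inherits(train, "spectral_dataset"),
            nrow(train$absorbance) >= 1)
  structure(list(center = colMeans(train$absorbance), axis = train$axis),
            class = "spectral_centering")
}

#' Apply a training-set centring to a dataset or matrix
#'
#' @param centering a [mean_center()] result.
#' @param x a [spectral_dataset()] on the same axis, or a plain matrix
#'   with matching column count.
#' @return `x` with the training column means subtracted (same type as
#'   the input).
#' @export
apply_centering <- function(centering, x) {
  stopifnot(inherits(centering, "spectral_centering"))
  if (inherits(x, "spectral_dataset")) {
    if (length(x$axis) != length(centering$axis) ||
        max(abs(x$axis - centering$axis)) > 1e-9)
      stop("axis mismatch between centering and dataset", call. = FALSE)
    return(replace_absorbance(
      x, sweep(x$absorbance, 2, centering$center)))
  }
  x <- as.matrix(x)
  if (ncol(x) != length(centering$center))
    stop("matrix has ", ncol(x), " columns; centering expects ",
         length(centering$center), call. = FALSE)
  sweep(x, 2, centering$center)
}

#' Run the full preprocessing chain
#'
#' Fixed order: cut -> Savitzky-Golay -> AWLS baseline -> band
#' normalisation. Mean-centring is deliberately not part of this chain:
#' it must be computed on the training subset after splitting (see
#' [mean_center()]).
#'
#' @param x a [spectral_dataset()].
#' @param config a [preprocess_config()].
#' @return the preprocessed `spectral_dataset`.
#' @export
preprocess <- function(x, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  x <- cut_region(x, config$cut_low, config$cut_high)
  x <- savgol_smooth(x, config$sg_window, config$sg_polyorder)
  x <- awls_baseline(x, config$awls_degree, config$awls_max_iter,
                     config$awls_tol)
  normalize_to_band(x, config$norm_anchor, config$norm_halfwidth)
}
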