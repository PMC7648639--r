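#' Principal component analysis of training spectra
#'
#' SVD-based decomposition `X_centered = T P' + E` with scores `T`,
#' orthonormal loadings `P` and residual `E`. Components are ordered by
#' decreasing variance; each loading's largest-magnitude element is made
#' positive, so the decomposition is deterministic. The model stores the
#' explained-variance fraction of every component (they sum to 1 over
#' all `min(n - 1, p)` components) even when only `k` loadings are kept.
#'
#' @param x training data: a [spectral_dataset()] or a numeric matrix
#'   (rows = observations).
#' @param k number of components to keep,
#'   `1 <= k <= min(n - 1, p)`. Default: all.
#' @return object of class `spectra_pca` with fields `mean`, `loadings`
#'   (`p x k`), `scores` (`n x k`), `explained_variance` (all
#'   components), `k`, and `axis` (when fitted on a dataset).
#' @export
fit_pca <- function(x, k = NULL) {
  axis <- NULL
  if (inherits(x, "spectral_dataset")) {
    axis <- x$axis
    x <- x$absorbance
  }
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (is.null(k)) k <- kmax
  if (k < 1 || k > kmax)
    stop("k must be between 1 and min(n - 1, p) = ", kmax, call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  var_all <- var_all[seq_len(kmax)]
  explained <- var_all / sum(var_all)
  P <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| loading element positive
  flip <- vapply(seq_len(k), function(j) {
    v <- P[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  P <- sweep(P, 2, flip, `*`)
  scores <- pc$x[, seq_len(k), drop = FALSE] %*% diag(flip, k, k)
  dimnames(P) <- dimnames(scores) <- NULL
  structure(list(mean = unname(pc$center), loadings = P, scores = scores,
                 explained_variance = explained, k = k, axis = axis),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  ev <- 100 * x$explained_variance[seq_len(min(3, length(x$explained_variance)))]
  cat("<spectra_pca> k =", x$k, "| leading explained variance (%):",
      paste(sprintf("%.2f", ev), collapse = ", "), "\n")
  invisible(x)
}

#' Project new observations onto a fitted PCA model
#'
#' @param model a [fit_pca()] result.
#' @param x a [spectral_dataset()] or matrix with the same number of
#'   wavenumbers the model was fitted on.
#' @return scores matrix `(n x k)`: `(x - mean) %*% loadings`.
#' @export
pca_project <- function(model, x) {
  stopifnot(inherits(model, "spectra_pca"))
  if (inherits(x, "spectral_dataset")) x <- x$absorbance
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop("data has ", ncol(x), " variables; model expects ",
         length(model$mean), call. = FALSE)
  sweep(x, 2, model$mean) %*% model$loadings
}

#' Number of components reaching a cumulative-variance threshold
#'
#' @param model a [fit_pca()] result.
#' @param threshold cumulative explained-variance fraction to exceed
#'   (default 0.90, the usual parsimony rule for smooth band-dominated
#'   spectra).
#' @return the smallest `k` with cumulative explained variance strictly
#'   greater than `threshold` (at least 1).
#' @export
choose_n_components <- function(model, threshold = 0.90) {
  stopifnot(inherits(model, "spectra_pca"))
  cum <- cumsum(model$explained_variance)
  k <- which(cum > threshold)[1]
  if (is.na(k)) k <- length(cum)
  max(1L, as.integer(k))
}

#' Write PCA scores/loadings plots to a PDF
#'
#' Four panels mirroring the usual exploratory figure: PC1 vs PC2,
#' PC1 vs PC3, PC2 vs PC3 score plots coloured by class, and the first
#' three loadings against wavenumber.
#'
#' @param model a [fit_pca()] result fitted on a dataset (so it carries
#'   an axis); must have `k >= 3`.
#' @param class_label character vector of class labels for the training
#'   scores.
#' @param file output PDF path.
#' @return `file`, invisibly.
#' @export
plot_pca_scores <- function(model, class_label, file) {
  stopifnot(inherits(model, "spectra_pca"), model$k >= 3)
  ev <- 100 * model$explained_variance
  cols <- ifelse(class_label == "case", "#C0392B", "#2471A3")
  grDevices::pdf(file, width = 9, height = 8)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  pairs_ <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pr in pairs_) {
    graphics::plot(model$scores[, pr[1]], model$scores[, pr[2]],
                   col = cols, pch = 19, cex = 0.7,
                   xlab = sprintf("PC%d (%.2f%%)", pr[1], ev[pr[1]]),
                   ylab = sprintf("PC%d (%.2f%%)", pr[2], ev[pr[2]]))
    graphics::legend("topright", c("case", "control"), pch = 19,
                     col = c("#C0392B", "#2471A3"), bty = "n", cex = 0.8)
  }
  if (!is.null(model$axis)) {
    graphics::matplot(model$axis, model$loadings[, 1:3], type = "l",
                      lty = 1, col = c("#C0392B", "#2471A3", "#1E8449"),
                      xlab = expression(Wavenumber ~ (cm^-1)),
                      ylab = "Loading")
    graphics::legend("topleft", paste0("PC", 1:3), lty = 1,
                     col = c("#C0392B", "#2471A3", "#1E8449"), bty = "n",
                     cex = 0.8)
  }
  invisible(file)
}
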