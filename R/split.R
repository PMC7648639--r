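#' Kennard-Stone uniform sample selection
#'
#' Deterministic max-min selection: the first two selected rows are the
#' pair at maximal Euclidean distance; each subsequent selection is the
#' row maximising its minimum distance to the already-selected set. Ties
#' are broken towards the lowest row index, so the result is a pure
#' function of the input order.
#'
#' @param X numeric matrix, one observation per row.
#' @param n_select number of rows to select, `2 <= n_select <= nrow(X)`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2) stop("n_select must be at least 2", call. = FALSE)
  if (n_select > n)
    stop("n_select (", n_select, ") exceeds number of rows (", n, ")",
         call. = FALSE)
  D <- as.matrix(stats::dist(X))
  # farthest pair; arrayInd scans column-major so which.max already
  # yields the lexicographically smallest (i, j) among ties
  ij <- arrayInd(which.max(D), dim(D))
  sel <- sort(c(ij[1], ij[2]))
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- which.max(mind)            # first index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  unname(as.integer(sel))
}

#' Kennard-Stone train/validation/test split
#'
#' Runs Kennard-Stone separately within each class on the preprocessed
#' spectra (or on per-subject mean spectra in `"sample"` mode), then
#' assigns the first `ceiling(f_train * n_c)` KS-ranked units of each
#' class to training, the next `ceiling(f_val * n_c)` to validation, and
#' the remainder to test, so class balance is preserved up to rounding.
#'
#' @param x a preprocessed [spectral_dataset()].
#' @param fractions length-3 positive vector `(train, validation, test)`
#'   summing to 1.
#' @param mode `"spectrum"` (each spectrum is a unit; default) or
#'   `"sample"` (each subject is a unit, so replicates never straddle
#'   subsets).
#' @return object of class `split_indices`: list with integer index
#'   vectors `train`, `validation`, `test` (into the spectra of `x`),
#'   plus `fractions` and `mode`.
#' @export
ks_split <- function(x, fractions = c(0.70, 0.15, 0.15),
                     mode = c("spectrum", "sample")) {
  stopifnot(inherits(x, "spectral_dataset"))
  mode <- match.arg(mode)
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("fractions must be 3 positive numbers", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)

  if (mode == "spectrum") {
    units <- seq_len(n_spectra(x))
    M <- x$absorbance
    ucl <- x$class_label
    expand <- function(u) u
  } else {
    sids <- unique(x$sample_id)
    M <- t(vapply(sids, function(s)
      colMeans(x$absorbance[x$sample_id == s, , drop = FALSE]),
      numeric(length(x$axis))))
    ucl <- x$class_label[match(sids, x$sample_id)]
    units <- seq_along(sids)
    expand <- function(u) which(x$sample_id %in% sids[u])
  }

  res <- list(train = integer(), validation = integer(),
              test = integer())
  for (cl in sort(unique(ucl))) {
    idx <- units[ucl == cl]
    n_c <- length(idx)
    if (n_c < 3)
      stop("class '", cl, "' has only ", n_c,
           " unit(s); need at least 3", call. = FALSE)
    ord <- idx[kennard_stone(M[idx, , drop = FALSE], n_c)]
    n_tr <- ceiling(fractions[1] * n_c)
    n_va <- min(ceiling(fractions[2] * n_c), n_c - n_tr)
    res$train <- c(res$train, ord[seq_len(n_tr)])
    res$validation <- c(res$validation,
                        ord[n_tr + seq_len(n_va)])
    res$test <- c(res$test,
                  if (n_tr + n_va < n_c) ord[(n_tr + n_va + 1):n_c]
                  else integer())
  }
  res <- lapply(res, function(u) sort(expand(u)))
  structure(c(res, list(fractions = fractions, mode = mode)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices> mode =", x$mode, "| train/validation/test =",
      length(x$train), "/", length(x$validation), "/", length(x$test),
      "\n")
  invisible(x)
}
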