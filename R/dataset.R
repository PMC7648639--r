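#' Spectral dataset container
#'
#' Bundles an absorbance matrix (one spectrum per row), the shared
#' wavenumber axis, and per-spectrum metadata. All downstream operations
#' (preprocessing, splitting, modelling) consume and return this class.
#'
#' @param absorbance numeric matrix, `n_spectra x n_wavenumbers`.
#' @param axis numeric vector of wavenumbers in cm^-1, strictly monotone.
#'   Stored in ascending order; columns of `absorbance` are reordered to
#'   match if the axis is supplied descending.
#' @param sample_id character vector, one id per spectrum.
#' @param class_label character vector, one of `"case"` or `"control"`
#'   per spectrum. `"case"` is the positive class everywhere downstream.
#' @param replicate positive integer vector, replicate index per spectrum.
#'   `(sample_id, replicate)` pairs must be unique.
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `absorbance`, `axis`, `sample_id`, `class_label`, `replicate`.
#' @export
spectral_dataset <- function(absorbance, axis, sample_id, class_label,
                             replicate) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  axis <- as.numeric(axis)
  if (ncol(absorbance) != length(axis))
    stop("absorbance has ", ncol(absorbance), " columns but axis has ",
         length(axis), " wavenumbers", call. = FALSE)
  if (anyNA(absorbance) || anyNA(axis))
    stop("missing values are not allowed in absorbance or axis",
         call. = FALSE)
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone", call. = FALSE)
  if (length(axis) > 1 && all(d < 0)) {           # store ascending
    axis <- rev(axis)
    absorbance <- absorbance[, rev(seq_along(axis)), drop = FALSE]
  }
  n <- nrow(absorbance)
  sample_id <- as.character(sample_id)
  class_label <- as.character(class_label)
  replicate <- as.integer(replicate)
  if (length(sample_id) != n || length(class_label) != n ||
      length(replicate) != n)
    stop("metadata length must equal the number of spectra (", n, ")",
         call. = FALSE)
  if (anyNA(replicate) || any(replicate < 1L))
    stop("replicate indices must be positive integers", call. = FALSE)
  bad <- setdiff(unique(class_label), c("case", "control"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(sample_id, replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, replicate) pair: ",
         sub("\r", " / replicate ", key[duplicated(key)][1]),
         call. = FALSE)
  dimnames(absorbance) <- NULL
  structure(list(absorbance = absorbance, axis = axis,
                 sample_id = sample_id, class_label = class_label,
                 replicate = replicate),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", nrow(x$absorbance), " spectra x ",
      length(x$axis), " wavenumbers [",
      min(x$axis), "-", max(x$axis), " cm^-1]\n", sep = "")
  tab <- table(x$class_label)
  cat("  classes:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of spectra in a dataset
#' @param x a `spectral_dataset`.
#' @return integer count of spectra (rows).
#' @export
n_spectra <- function(x) {
  stopifnot(inherits(x, "spectral_dataset"))
  nrow(x$absorbance)
}

#' Row-subset a spectral dataset
#'
#' @param x a `spectral_dataset`.
#' @param i integer or logical row index.
#' @return a `spectral_dataset` with the selected spectra.
#' @export
subset_spectra <- function(x, i) {
  stopifnot(inherits(x, "spectral_dataset"))
  spectral_dataset(x$absorbance[i, , drop = FALSE], x$axis,
                   x$sample_id[i], x$class_label[i], x$replicate[i])
}

# replace the absorbance matrix, keeping axis/metadata (internal)
replace_absorbance <- function(x, m, axis = x$axis) {
  spectral_dataset(m, axis, x$sample_id, x$class_label, x$replicate)
}

#' Read a spectral dataset from CSV
#'
#' Canonical dialect: UTF-8, comma separated; header
#' `sample_id,class_label,replicate,<nu1>,<nu2>,...` with wavenumbers as
#' decimal cm^-1; one spectrum per row.
#'
#' @param path path to a CSV file written by [write_spectra()] or
#'   conforming to the dialect above.
#' @return a [spectral_dataset()].
#' @export
read_spectra <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 4)
    stop("spectral CSV needs sample_id, class_label, replicate and at ",
         "least one wavenumber column", call. = FALSE)
  nm <- names(dt)
  if (!identical(nm[1:3], c("sample_id", "class_label", "replicate")))
    stop("first three columns must be sample_id, class_label, replicate",
         call. = FALSE)
  axis <- suppressWarnings(as.numeric(nm[-(1:3)]))
  if (anyNA(axis))
    stop("non-numeric wavenumber in header: ",
         paste(nm[-(1:3)][is.na(axis)][1]), call. = FALSE)
  m <- as.matrix(dt[, -(1:3)])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric or missing absorbance values in ", path,
         call. = FALSE)
  spectral_dataset(m, axis, dt$sample_id, dt$class_label, dt$replicate)
}

#' Write a spectral dataset to CSV
#'
#' Numbers are serialised at full (shortest round-trip) precision so that
#' `read_spectra(write_spectra(x))` reproduces `x` exactly.
#'
#' @param x a [spectral_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectral_dataset"))
  meta <- data.table::data.table(sample_id = x$sample_id,
                                 class_label = x$class_label,
                                 replicate = x$replicate)
  m <- data.table::as.data.table(x$absorbance)
  data.table::setnames(m, format(x$axis, trim = TRUE, digits = 15))
  data.table::fwrite(cbind(meta, m), path)
  invisible(path)
}
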