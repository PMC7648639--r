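# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

# small strong-effect cohort, preprocessed + split + centred
small_strong_fixture <- function() {
  if (is.null(.fixture_cache$small_strong)) {
    ds <- generate_cohort(cohort_config(n_per_class = 15, seed = 42))
    pp <- suppressWarnings(preprocess(ds))
    sp <- ks_split(pp)
    ctr <- mean_center(subset_spectra(pp, sp$train))
    ppc <- apply_centering(ctr, pp)
    .fixture_cache$small_strong <- list(
      raw = ds, pp = pp, ppc = ppc, split = sp,
      Xtr = ppc$absorbance[sp$train, ],
      ytr = ppc$class_label[sp$train],
      Xva = ppc$absorbance[sp$validation, ],
      yva = ppc$class_label[sp$validation],
      Xte = ppc$absorbance[sp$test, ],
      yte = ppc$class_label[sp$test])
  }
  .fixture_cache$small_strong
}

# default 300-spectrum strong-effect cohort, preprocessed (heavier; used
# by the acceptance tests)
default_strong_fixture <- function(seed = 1) {
  key <- paste0("default_strong_", seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- generate_cohort(cohort_config(seed = seed))
    pp <- suppressWarnings(preprocess(ds))
    .fixture_cache[[key]] <- list(raw = ds, pp = pp)
  }
  .fixture_cache[[key]]
}

# tiny hand-sized dataset for I/O and preprocessing unit tests
tiny_dataset <- function(n = 3, p = 5) {
  spectral_dataset(matrix(seq_len(n * p) / 10, n, p, byrow = TRUE),
                   axis = seq(1000, by = 4, length.out = p),
                   sample_id = sprintf("s%d", seq_len(n)),
                   class_label = rep(c("case", "control"),
                                     length.out = n),
                   replicate = rep(1L, n))
}
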