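#' Run the full discrimination pipeline
#'
#' Executes preprocess -> Kennard-Stone split -> training-set
#' mean-centring -> feature derivation (PCA scores with automatic
#' component count; SPA and GA wavenumber subsets chosen by minimum
#' validation cost G) -> classifier fitting (LDA, QDA, validation-tuned
#' RBF-SVM) -> evaluation on the untouched test set. The test subset is
#' used exactly once, at the final evaluation; selection and tuning see
#' only training and validation spectra.
#'
#' @param dataset a raw [spectral_dataset()], or `NULL` to generate a
#'   synthetic cohort from `cohort`.
#' @param cohort a [cohort_config()] used when `dataset` is `NULL`.
#' @param config a [preprocess_config()].
#' @param fractions,mode passed to [ks_split()].
#' @param feature_methods subset of `c("pca", "spa", "ga")`.
#' @param classifiers subset of `c("lda", "qda", "svm")`.
#' @param pca_threshold cumulative-variance threshold for the automatic
#'   PCA component count (default 0.90).
#' @param ga,spa selector configurations ([ga_config()],
#'   [spa_config()]); a `NULL` GA seed is replaced by `seed` so the run
#'   is reproducible end to end.
#' @param seed integer seed governing every stochastic stage.
#' @param unit `"spectrum"` evaluates each spectrum independently;
#'   `"subject"` aggregates test predictions by majority vote within
#'   each sample id (ties broken towards "case").
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `report.md`, `selected_variables.json` and diagnostic plots there.
#' @return object of class `pipeline_report`: list of per-variant model
#'   reports plus the fitted `pca` model, the `split`, and the
#'   preprocessed dataset.
#' @export
run_pipeline <- function(dataset = NULL, cohort = cohort_config(),
                         config = preprocess_config(),
                         fractions = c(0.70, 0.15, 0.15),
                         mode = "spectrum",
                         feature_methods = c("pca", "spa", "ga"),
                         classifiers = c("lda", "qda", "svm"),
                         pca_threshold = 0.90,
                         ga = ga_config(), spa = spa_config(),
                         seed = 1,
                         unit = c("spectrum", "subject"),
                         out_dir = NULL) {
  unit <- match.arg(unit)
  feature_methods <- match.arg(feature_methods,
                               c("pca", "spa", "ga"), several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("lda", "qda", "svm"),
                           several.ok = TRUE)
  if (is.null(dataset)) dataset <- generate_cohort(cohort)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  pp <- stage("preprocess", preprocess(dataset, config))
  split <- stage("split", ks_split(pp, fractions, mode))
  centering <- mean_center(subset_spectra(pp, split$train))
  ppc <- apply_centering(centering, pp)
  Xtr <- ppc$absorbance[split$train, , drop = FALSE]
  Xva <- ppc$absorbance[split$validation, , drop = FALSE]
  Xte <- ppc$absorbance[split$test, , drop = FALSE]
  ytr <- ppc$class_label[split$train]
  yva <- ppc$class_label[split$validation]
  yte <- ppc$class_label[split$test]

  pca_model <- stage("pca", fit_pca(subset_spectra(ppc, split$train)))
  features <- list()
  subsets <- list()
  if ("pca" %in% feature_methods) {
    k <- choose_n_components(pca_model, pca_threshold)
    features$pca <- list(
      train = pca_model$scores[, seq_len(k), drop = FALSE],
      validation = pca_project(pca_model, Xva)[, seq_len(k),
                                               drop = FALSE],
      test = pca_project(pca_model, Xte)[, seq_len(k), drop = FALSE],
      n_features = k, wavenumbers = NULL)
  }
  if ("spa" %in% feature_methods) {
    sub <- stage("spa", spa_select(Xtr, ytr, Xva, yva, spa,
                                   axis = ppc$axis))
    subsets$spa <- sub
    features$spa <- list(train = Xtr[, sub$indices, drop = FALSE],
                         validation = Xva[, sub$indices, drop = FALSE],
                         test = Xte[, sub$indices, drop = FALSE],
                         n_features = length(sub$indices),
                         wavenumbers = sub$wavenumbers)
  }
  if ("ga" %in% feature_methods) {
    if (is.null(ga$seed)) ga$seed <- seed
    sub <- stage("ga", ga_select(Xtr, ytr, Xva, yva, ga,
                                 axis = ppc$axis))
    subsets$ga <- sub
    features$ga <- list(train = Xtr[, sub$indices, drop = FALSE],
                        validation = Xva[, sub$indices, drop = FALSE],
                        test = Xte[, sub$indices, drop = FALSE],
                        n_features = length(sub$indices),
                        wavenumbers = sub$wavenumbers)
  }

  aggregate_votes <- function(labels, ids) {
    u <- unique(ids)
    agg <- vapply(u, function(s) {
      v <- labels[ids == s]
      n_case <- sum(v == "case")
      if (n_case * 2 >= length(v)) "case" else "control"
    }, character(1))
    list(labels = agg, ids = u)
  }

  reports <- list()
  for (fm in feature_methods) {
    ft <- features[[fm]]
    for (clf in classifiers) {
      model <- stage(paste(fm, clf, sep = "-"), switch(clf,
        lda = fit_lda(ft$train, ytr),
        qda = fit_qda(ft$train, ytr),
        svm = fit_svm_rbf(ft$train, ytr, ft$validation, yva,
                          seed = seed)))
      pr_va <- predict(model, ft$validation)
      pr_te <- predict(model, ft$test)
      if (unit == "subject") {
        av <- aggregate_votes(pr_te$labels, ppc$sample_id[split$test])
        truth_te <- ppc$class_label[split$test][
          match(av$ids, ppc$sample_id[split$test])]
        cm_te <- confusion(truth_te, av$labels)
      } else {
        cm_te <- confusion(yte, pr_te$labels)
      }
      cm_va <- confusion(yva, pr_va$labels)
      reports[[paste(fm, clf, sep = "_")]] <- list(
        feature_method = toupper(fm), classifier = toupper(clf),
        n_features = ft$n_features,
        wavenumbers = ft$wavenumbers,
        validation_confusion = cm_va,
        validation_metrics = figures_of_merit(cm_va),
        test_confusion = cm_te,
        test_metrics = figures_of_merit(cm_te),
        test_scores = pr_te$scores,
        model = model)
    }
  }

  out <- structure(list(reports = reports, pca = pca_model,
                        subsets = subsets, split = split,
                        preprocessed = ppc, centering = centering,
                        seed = seed, unit = unit),
                   class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Tabulate a pipeline report
#'
#' @param report a [run_pipeline()] result.
#' @return data.frame with one row per feature-method x classifier
#'   variant: test-set accuracy, sensitivity and specificity (percent)
#'   and the number of features used.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  do.call(rbind, lapply(report$reports, function(r) {
    m <- r$test_metrics
    data.frame(feature_method = r$feature_method,
               classifier = r$classifier, n_features = r$n_features,
               accuracy = m[["accuracy"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               row.names = NULL)
  }))
}

#' @export
print.pipeline_report <- function(x, ...) {
  tab <- report_table(x)
  tab[, 4:6] <- round(tab[, 4:6], 1)
  cat("<pipeline_report> test-set figures of merit (%):\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Full-precision metrics, confusion counts and selected wavenumbers
#' per variant; deterministic for identical runs.
#'
#' @param report a [run_pipeline()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  payload <- list(seed = report$seed, unit = report$unit,
                  variants = lapply(report$reports, function(r) list(
    feature_method = r$feature_method, classifier = r$classifier,
    n_features = r$n_features,
    wavenumbers = r$wavenumbers,
    test_confusion = unclass(r$test_confusion)[c("TP", "TN", "FP", "FN")],
    test_metrics = as.list(r$test_metrics),
    validation_metrics = as.list(r$validation_metrics))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(report, file.path(out_dir, "report.json"))
  tab <- report_table(report)
  tab[, 4:6] <- round(tab[, 4:6], 1)
  md <- c("| Features | Classifier | n | AC (%) | SENS (%) | SPEC (%) |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %s | %d | %.1f | %.1f | %.1f |",
                  tab$feature_method, tab$classifier, tab$n_features,
                  tab$accuracy, tab$sensitivity, tab$specificity))
  writeLines(md, file.path(out_dir, "report.md"))
  sel <- lapply(report$subsets, function(s)
    list(method = s$method, cost_G = s$cost_G,
         wavenumbers = s$wavenumbers))
  jsonlite::write_json(sel, file.path(out_dir, "selected_variables.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (report$pca$k >= 3)
    plot_pca_scores(report$pca,
                    report$preprocessed$class_label[report$split$train],
                    file.path(out_dir, "pca_scores.pdf"))
  ga_lda <- report$reports[["ga_lda"]]
  if (!is.null(ga_lda) && !is.null(ga_lda$test_scores))
    plot_discriminant_scores(
      ga_lda$test_scores,
      report$preprocessed$class_label[report$split$test],
      file.path(out_dir, "ga_lda_test_scores.pdf"))
  invisible(out_dir)
}

#' Plot per-object discriminant scores
#'
#' Strip plot of the scalar two-class discriminant score (positive =
#' case side) for a set of objects, coloured by true class.
#'
#' @param scores numeric discriminant scores.
#' @param class_label true class per object.
#' @param file output PDF path.
#' @return `file`, invisibly.
#' @export
plot_discriminant_scores <- function(scores, class_label, file) {
  cols <- ifelse(class_label == "case", "#C0392B", "#2471A3")
  grDevices::pdf(file, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(seq_along(scores), scores, col = cols, pch = 19,
                 xlab = "Object", ylab = "Discriminant score")
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::legend("topright", c("case", "control"), pch = 19,
                   col = c("#C0392B", "#2471A3"), bty = "n")
  invisible(file)
}
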