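#' Fit a Mahalanobis discriminant model (LDA or QDA)
#'
#' LDA uses class means with a pooled covariance matrix
#' `sum_k (n_k - 1) S_k / (n - K)` (classes share one variance
#' structure); QDA uses each class's own covariance. Near-singular
#' covariances are ridge-regularised (see [regularize_covariance()]).
#'
#' @param X training feature matrix (rows = observations).
#' @param y class labels (>= 2 classes, each with >= 2 rows).
#' @param kind `"lda"` or `"qda"`.
#' @param priors named prior probabilities, or `NULL` for equal priors
#'   (the sensible default for a balanced case/control design).
#' @return object of class `da_model` with fields `classes`, `means`,
#'   `pooled` (LDA) or `covariances` (QDA), `priors`, `kind`.
#' @export
fit_da <- function(X, y, kind = c("lda", "qda"), priors = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("need at least two classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2))
    stop("class '", names(counts)[counts < 2][1],
         "' has fewer than 2 training rows", call. = FALSE)
  if (is.null(priors)) {
    priors <- rep(1 / length(classes), length(classes))
    names(priors) <- classes
  } else {
    if (!all(classes %in% names(priors)) || abs(sum(priors) - 1) > 1e-9)
      stop("priors must be named for every class and sum to 1",
           call. = FALSE)
    priors <- priors[classes]
  }
  means <- matrix(unlist(lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE]))), nrow = length(classes),
    byrow = TRUE)
  out <- list(classes = classes, means = means, priors = priors,
              kind = kind)
  if (kind == "lda") {
    out$pooled <- regularize_covariance(pooled_covariance(X, y))
  } else {
    out$covariances <- lapply(classes, function(cl)
      regularize_covariance(stats::cov(X[y == cl, , drop = FALSE])))
    names(out$covariances) <- classes
  }
  structure(out, class = "da_model")
}

#' Convenience wrappers for the two discriminant kinds
#' @rdname fit_da
#' @export
fit_lda <- function(X, y, priors = NULL) fit_da(X, y, "lda", priors)

#' @rdname fit_da
#' @export
fit_qda <- function(X, y, priors = NULL) fit_da(X, y, "qda", priors)

#' Predict with a discriminant model
#'
#' LDA assigns the class minimising
#' `d^2(x, m_k; pooled) - 2 log(prior_k)`; QDA minimises
#' `d^2(x, m_k; S_k) + log det S_k - 2 log(prior_k)` (the full Gaussian
#' discriminant). Ties go to the lexicographically first class label.
#' For two classes a scalar discriminant score per object is also
#' returned: the second-class criterion minus the first-class criterion,
#' so positive scores favour the first (sorted) class - with
#' case/control labels, positive means "case".
#'
#' @param object a [fit_da()] model.
#' @param newdata feature matrix with matching dimension.
#' @param ... unused.
#' @return list with `labels` (character), `criteria` (matrix, one
#'   column per class) and, for two classes, `scores` (numeric).
#' @export
predict.da_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$means))
    stop("newdata has ", ncol(X), " features; model expects ",
         ncol(object$means), call. = FALSE)
  K <- length(object$classes)
  crit <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    if (object$kind == "lda") {
      d2 <- mahalanobis_sq(X, object$means[k, ], object$pooled)
      crit[, k] <- d2 - 2 * log(object$priors[k])
    } else {
      S <- object$covariances[[k]]
      d2 <- mahalanobis_sq(X, object$means[k, ], S)
      crit[, k] <- d2 + determinant(S, logarithm = TRUE)$modulus -
        2 * log(object$priors[k])
    }
  }
  labels <- object$classes[apply(crit, 1, which.min)]
  out <- list(labels = labels, criteria = crit)
  if (K == 2) out$scores <- crit[, 2] - crit[, 1]
  out
}

#' Fit an RBF-kernel SVM with validation-set tuning
#'
#' Trains a soft-margin radial-basis-function SVM (via [e1071::svm()],
#' without internal rescaling) for every `(C, gamma)` pair on the grid,
#' selects the pair maximising validation accuracy (ties: smaller C,
#' then smaller gamma) and refits it on the training set. Deterministic
#' for fixed inputs.
#'
#' @param X,y training features and labels.
#' @param X_val,y_val validation features and labels used only for
#'   hyperparameter selection.
#' @param C_grid,gamma_grid candidate values; defaults span
#'   `2^-5..2^15` and `2^-15..2^3` in powers of 4.
#' @param seed integer seed applied around fitting (libsvm training is
#'   deterministic; the seed pins any incidental RNG use).
#' @return object of class `svm_rbf_model` wrapping the refitted
#'   [e1071::svm()] fit plus `C`, `gamma` and `validation_accuracy`.
#' @export
fit_svm_rbf <- function(X, y, X_val, y_val,
                        C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        seed = 1) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  y <- factor(as.character(y))
  if (nlevels(y) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (!length(C_grid) || !length(gamma_grid))
    stop("hyperparameter grids must be nonempty", call. = FALSE)
  yv <- as.character(y_val)
  best <- NULL
  withr::with_seed(seed, {
    for (C in sort(C_grid)) {
      for (g in sort(gamma_grid)) {
        fit <- e1071::svm(X, y, kernel = "radial", cost = C, gamma = g,
                          scale = FALSE)
        acc <- mean(as.character(predict(fit, X_val)) == yv)
        if (is.null(best) || acc > best$acc) {
          best <- list(acc = acc, C = C, gamma = g)
        }
      }
    }
    best$fit <- e1071::svm(X, y, kernel = "radial", cost = best$C,
                           gamma = best$gamma, scale = FALSE)
  })
  structure(list(fit = best$fit, C = best$C, gamma = best$gamma,
                 validation_accuracy = best$acc),
            class = "svm_rbf_model")
}

#' Predict with a tuned RBF-SVM
#'
#' @param object a [fit_svm_rbf()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return list with `labels` (character) and `scores` (signed decision
#'   values).
#' @export
predict.svm_rbf_model <- function(object, newdata, ...) {
  pr <- predict(object$fit, as.matrix(newdata), decision.values = TRUE)
  list(labels = as.character(pr),
       scores = as.numeric(attr(pr, "decision.values")))
}
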