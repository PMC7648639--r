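#' Squared Mahalanobis distance
#'
#' `(x - center)' C^-1 (x - center)` for one vector or a matrix of rows.
#'
#' @param x numeric vector, or matrix with one observation per row.
#' @param center numeric vector.
#' @param covariance symmetric positive-definite matrix (regularise
#'   first with [regularize_covariance()] if it may be near-singular).
#' @return nonnegative numeric, one value per row of `x`.
#' @export
mahalanobis_sq <- function(x, center, covariance) {
  covariance <- as.matrix(covariance)
  if (max(abs(covariance - t(covariance))) >
      1e-8 * max(1, max(abs(covariance))))
    stop("covariance must be symmetric", call. = FALSE)
  d <- tryCatch(stats::mahalanobis(x, center, covariance),
                error = function(e)
                  stop("singular covariance in mahalanobis_sq: ",
                       conditionMessage(e), call. = FALSE))
  unname(d)
}

#' Ridge-regularise a near-singular covariance matrix
#'
#' Adds `lambda * trace(S)/p` to the diagonal when the 2-norm condition
#' number of `S` exceeds `max_condition` (or when `S` is not positive
#' definite), leaving well-conditioned matrices untouched.
#'
#' @param S symmetric covariance matrix.
#' @param lambda relative ridge (default 1e-6).
#' @param max_condition condition-number threshold (default 1e10).
#' @return the (possibly regularised) covariance matrix.
#' @export
regularize_covariance <- function(S, lambda = 1e-6,
                                  max_condition = 1e10) {
  S <- as.matrix(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0)
    stop("covariance has no positive eigenvalue; cannot regularise",
         call. = FALSE)
  if (min(ev) <= 0 || ev[1] / min(ev) > max_condition)
    S <- S + diag(lambda * sum(diag(S)) / ncol(S), ncol(S))
  S
}

# Pooled within-class covariance: sum_k (n_k - 1) S_k / (n - K)
pooled_covariance <- function(X, y) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  n <- nrow(X)
  S <- matrix(0, ncol(X), ncol(X))
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    Xc <- sweep(Xc, 2, colMeans(Xc))
    S <- S + crossprod(Xc)
  }
  S / (n - length(classes))
}

# Fast closure evaluating the validation cost G for a column subset.
# Precomputes per-class training blocks; each call does the sub-matrix
# work only. Used by cost_G, spa_select and ga_select.
make_cost_evaluator <- function(X_train, y_train, X_val, y_val,
                                lambda = 1e-6, max_condition = 1e10) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  classes <- sort(unique(as.character(y_train)))
  if (length(classes) < 2)
    stop("cost G needs at least two classes in training", call. = FALSE)
  if (!all(y_val %in% classes))
    stop("validation class absent from training: ",
         paste(setdiff(unique(y_val), classes), collapse = ", "),
         call. = FALSE)
  if (nrow(X_val) < 1) stop("need at least one validation object",
                            call. = FALSE)
  tr_blocks <- lapply(classes, function(cl)
    X_train[y_train == cl, , drop = FALSE])
  n_tr <- nrow(X_train)
  K <- length(classes)
  val_cl <- match(as.character(y_val), classes)

  function(subset) {
    subset <- as.integer(subset)
    p <- length(subset)
    S <- matrix(0, p, p)
    centers <- matrix(0, K, p)
    for (k in seq_len(K)) {
      Xc <- tr_blocks[[k]][, subset, drop = FALSE]
      mk <- colMeans(Xc)
      centers[k, ] <- mk
      Xc <- sweep(Xc, 2, mk)
      S <- S + crossprod(Xc)
    }
    S <- S / (n_tr - K)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] <= 0)
      stop("pooled covariance is not positive semi-definite",
           call. = FALSE)
    if (min(ev) <= 0 || ev[1] / min(ev) > max_condition)
      S <- S + diag(lambda * sum(diag(S)) / p, p)
    R <- tryCatch(chol(S), error = function(e)
      stop("singular pooled covariance after regularisation",
           call. = FALSE))
    V <- X_val[, subset, drop = FALSE]
    # squared Mahalanobis distance of every validation row to every center
    D <- matrix(0, nrow(V), K)
    for (k in seq_len(K)) {
      Z <- sweep(V, 2, centers[k, ])
      W <- backsolve(R, t(Z), transpose = TRUE)
      D[, k] <- colSums(W^2)
    }
    num <- D[cbind(seq_len(nrow(V)), val_cl)]
    D[cbind(seq_len(nrow(V)), val_cl)] <- Inf
    den <- apply(D, 1, min)
    g <- ifelse(den == 0, Inf, num / den)
    mean(g)
  }
}

#' Validation-set cost function G
#'
#' `G = (1/N_V) * sum_n g_n`, where for validation object `x_n` of true
#' class `I(n)`, `g_n` is the ratio of the squared Mahalanobis distance
#' between `x_n` and its own class centre to the squared Mahalanobis
#' distance to the centre of the closest wrong class. Class centres and
#' the pooled covariance are estimated from the training rows restricted
#' to the selected columns; smaller G is better. A validation object
#' lying exactly on a wrong-class centre yields `g_n = Inf`, which
#' propagates.
#'
#' @param X_train,y_train training matrix and class labels.
#' @param X_val,y_val validation matrix and class labels (every
#'   validation class must occur in training).
#' @param subset integer column indices to evaluate (default: all).
#' @param lambda,max_condition covariance regularisation, see
#'   [regularize_covariance()].
#' @return nonnegative scalar G.
#' @export
cost_G <- function(X_train, y_train, X_val, y_val,
                   subset = seq_len(ncol(as.matrix(X_train))),
                   lambda = 1e-6, max_condition = 1e10) {
  if (length(subset) < 1) stop("subset must be nonempty", call. = FALSE)
  ev <- make_cost_evaluator(X_train, y_train, X_val, y_val,
                            lambda, max_condition)
  ev(subset)
}
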