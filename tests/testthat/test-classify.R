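test_that("LDA recovers simulated class structure", {
  withr::local_seed(41)
  n <- 500
  X <- rbind(matrix(rnorm(n * 2, mean = -1), ncol = 2),
             matrix(rnorm(n * 2, mean = 1), ncol = 2))
  y <- rep(c("case", "control"), each = n)
  m <- fit_lda(X, y)
  se <- 1 / sqrt(n)
  expect_lt(max(abs(m$means[1, ] - c(-1, -1))), 3 * se)
  expect_lt(max(abs(m$means[2, ] - c(1, 1))), 3 * se)
  expect_gt(min(eigen(m$pooled, symmetric = TRUE)$values), 0)
  expect_error(fit_lda(X[c(1, n + 1), ], y[c(1, n + 1)]), "fewer than 2")
  expect_error(fit_lda(X, rep("case", 2 * n)), "two classes")
})

test_that("univariate LDA thresholds at the midpoint", {
  withr::local_seed(43)
  X <- matrix(c(rnorm(400, -1), rnorm(400, 1)), ncol = 1)
  y <- rep(c("case", "control"), each = 400)
  m <- fit_lda(X, y)
  # decision boundary for equal priors/variance is ~0
  lab <- predict(m, matrix(c(-0.2, 0.2), ncol = 1))$labels
  expect_equal(lab, c("case", "control"))
})

test_that("discriminant assignment, ties and scores behave as defined", {
  m <- fit_lda(rbind(c(-1, 0), c(-3, 0), c(1, 0), c(3, 0)),
               c("case", "case", "control", "control"))
  pr <- predict(m, rbind(c(-2, 0), c(2, 0), c(0, 0)))
  expect_equal(pr$labels[1:2], c("case", "control"))
  expect_equal(pr$labels[3], "case")       # tie -> first sorted label
  # two-class scalar score: positive favours "case"
  expect_gt(pr$scores[1], 0)
  expect_lt(pr$scores[2], 0)
  expect_equal(pr$scores[3], 0, tolerance = 1e-12)
  expect_error(predict(m, matrix(0, 1, 3)), "features")
})

test_that("LDA error approaches the closed-form Bayes rate", {
  withr::local_seed(47)
  delta <- 2                      # Mahalanobis distance between means
  n <- 1500
  draw <- function(mu, n) cbind(rnorm(n, mu), rnorm(n))
  Xtr <- rbind(draw(0, 400), draw(delta, 400))
  ytr <- rep(c("case", "control"), each = 400)
  Xte <- rbind(draw(0, n), draw(delta, n))
  yte <- rep(c("case", "control"), each = n)
  m <- fit_lda(Xtr, ytr)
  err <- mean(predict(m, Xte)$labels != yte)
  bayes <- pnorm(-delta / 2)
  expect_lt(abs(err - bayes), 0.02)
})

test_that("LDA predictions are invariant under affine feature maps", {
  withr::local_seed(51)
  d <- random_two_class(n_per_class = 30, p = 3, n_val = 20)
  A <- matrix(rnorm(9), 3) + diag(3) * 2
  b <- rnorm(3)
  tf <- function(X) sweep(X %*% A, 2, b, `+`)
  p0 <- predict(fit_lda(d$Xtr, d$ytr), d$Xva)$labels
  p1 <- predict(fit_lda(tf(d$Xtr), d$ytr), tf(d$Xva))$labels
  expect_identical(p0, p1)
})

test_that("QDA with equal class covariances reduces to LDA", {
  withr::local_seed(53)
  base <- matrix(rnorm(40 * 2), 40, 2)
  # class two is a pure translation, so sample covariances are equal
  Xtr <- rbind(base, sweep(base, 2, c(3, -1), `+`))
  ytr <- rep(c("case", "control"), each = 40)
  Xte <- matrix(rnorm(60 * 2, mean = 1), 60, 2)
  p_lda <- predict(fit_lda(Xtr, ytr), Xte)$labels
  p_qda <- predict(fit_qda(Xtr, ytr), Xte)$labels
  expect_identical(p_lda, p_qda)
})

test_that("LDA predictions agree with an independent implementation", {
  withr::local_seed(55)
  d <- random_two_class(n_per_class = 40, p = 4, n_val = 30)
  ours <- predict(fit_lda(d$Xtr, d$ytr), d$Xva)$labels
  ref <- MASS::lda(d$Xtr, grouping = d$ytr, prior = c(0.5, 0.5))
  theirs <- as.character(predict(ref, d$Xva)$class)
  expect_identical(ours, theirs)
})

test_that("RBF-SVM separates what a linear rule cannot", {
  withr::local_seed(57)
  # linearly separable toy
  Xtr <- rbind(matrix(rnorm(60, -2, 0.3), ncol = 2),
               matrix(rnorm(60, 2, 0.3), ncol = 2))
  ytr <- rep(c("case", "control"), each = 30)
  m <- fit_svm_rbf(Xtr, ytr, Xtr, ytr)
  expect_equal(mean(predict(m, Xtr)$labels == ytr), 1)
  expect_equal(m$validation_accuracy, 1)

  # XOR pattern: four clusters, diagonal classes
  xor_data <- function(n) {
    centers <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
    X <- centers[rep(1:4, each = n), ] + matrix(rnorm(8 * n, 0, 0.2),
                                                ncol = 2)
    list(X = X, y = rep(c("case", "case", "control", "control"),
                        each = n))
  }
  tr <- xor_data(25); va <- xor_data(25)
  m_rbf <- fit_svm_rbf(tr$X, tr$y, va$X, va$y)
  expect_gt(mean(predict(m_rbf, va$X)$labels == va$y), 0.9)
  m_lin <- fit_lda(tr$X, tr$y)
  expect_lt(mean(predict(m_lin, va$X)$labels == va$y), 0.75)
})

test_that("SVM tuning is deterministic and validates input", {
  withr::local_seed(59)
  d <- random_two_class(n_per_class = 20, p = 3, n_val = 10)
  a <- fit_svm_rbf(d$Xtr, d$ytr, d$Xva, d$yva, seed = 3)
  b <- fit_svm_rbf(d$Xtr, d$ytr, d$Xva, d$yva, seed = 3)
  expect_identical(c(a$C, a$gamma), c(b$C, b$gamma))
  expect_identical(predict(a, d$Xva)$labels, predict(b, d$Xva)$labels)
  expect_error(fit_svm_rbf(d$Xtr, rep("case", nrow(d$Xtr)),
                           d$Xva, d$yva), "single class")
  expect_error(fit_svm_rbf(d$Xtr, d$ytr, d$Xva, d$yva,
                           C_grid = numeric(0)), "nonempty")
})
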