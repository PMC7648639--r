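# Independent brute-force oracles. These deliberately use the plainest
# possible formulations (explicit inverses, full recomputation, exhaustive
# enumeration) and share no code with the package internals.

oracle_mahalanobis_sq <- function(x, center, S) {
  d <- as.numeric(x) - as.numeric(center)
  drop(t(d) %*% solve(S) %*% d)
}

# literal Eq.-style cost G: training class centres + pooled covariance,
# ratio of own-class to closest-wrong-class squared Mahalanobis distance
oracle_cost_G <- function(Xtr, ytr, Xva, yva, subset) {
  Xtr <- as.matrix(Xtr)[, subset, drop = FALSE]
  Xva <- as.matrix(Xva)[, subset, drop = FALSE]
  classes <- sort(unique(ytr))
  centers <- lapply(classes, function(cl)
    colMeans(Xtr[ytr == cl, , drop = FALSE]))
  names(centers) <- classes
  S <- matrix(0, ncol(Xtr), ncol(Xtr))
  for (cl in classes) {
    n_c <- sum(ytr == cl)
    S <- S + (n_c - 1) * stats::cov(Xtr[ytr == cl, , drop = FALSE])
  }
  S <- S / (nrow(Xtr) - length(classes))
  g <- vapply(seq_len(nrow(Xva)), function(i) {
    own <- oracle_mahalanobis_sq(Xva[i, ], centers[[yva[i]]], S)
    wrong <- min(vapply(setdiff(classes, yva[i]), function(cl)
      oracle_mahalanobis_sq(Xva[i, ], centers[[cl]], S), numeric(1)))
    if (wrong == 0) Inf else own / wrong
  }, numeric(1))
  mean(g)
}

# greedy max-min Kennard-Stone, recomputing every distance from scratch
oracle_kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  ed <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(NA, NA); bd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (ed(i, j) > bd) { bd <- ed(i, j); best <- c(i, j) }
  sel <- best
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    md <- vapply(cand, function(i)
      min(vapply(sel, function(j) ed(i, j), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# exhaustive SPA: every start, chain built by literal orthogonal
# projection (residuals via lm.fit), every prefix scored with the cost
# oracle; global minimum-G prefix returned
oracle_spa <- function(Xtr, ytr, Xva, yva, max_vars) {
  Xtr <- as.matrix(Xtr)
  p <- ncol(Xtr)
  best <- list(G = Inf, chain = integer())
  for (s in seq_len(p)) {
    chain <- s
    repeat {
      G <- oracle_cost_G(Xtr, ytr, Xva, yva, chain)
      if (G < best$G) best <- list(G = G, chain = chain)
      if (length(chain) >= max_vars) break
      B <- Xtr[, chain, drop = FALSE]
      resid_norm <- vapply(seq_len(p), function(j) {
        if (j %in% chain) return(-Inf)
        r <- stats::lm.fit(B, Xtr[, j])$residuals
        nr <- sum(r^2)
        if (nr <= 1e-10 * sum(Xtr[, j]^2)) -Inf else nr
      }, numeric(1))
      if (all(!is.finite(resid_norm))) break
      chain <- c(chain, which.max(resid_norm))
    }
  }
  best
}

# small random two-class instance for oracle comparisons
random_two_class <- function(n_per_class = 8, p = 3, n_val = 4,
                             shift = 1) {
  Xtr <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
               matrix(stats::rnorm(n_per_class * p, mean = shift),
                      ncol = p))
  ytr <- rep(c("case", "control"), each = n_per_class)
  Xva <- rbind(matrix(stats::rnorm(n_val * p), ncol = p),
               matrix(stats::rnorm(n_val * p, mean = shift), ncol = p))
  yva <- rep(c("case", "control"), each = n_val)
  list(Xtr = Xtr, ytr = ytr, Xva = Xva, yva = yva)
}
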