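#' Successive projections algorithm configuration
#'
#' @param max_vars maximum chain length (number of selected variables);
#'   must satisfy `1 <= max_vars <= min(n_train - 2, n_wavenumbers)`.
#' @param candidate_starts integer vector of start columns, or `NULL`
#'   for all columns.
#' @return object of class `spa_config`.
#' @export
spa_config <- function(max_vars = 30, candidate_starts = NULL) {
  stopifnot(max_vars >= 1)
  structure(list(max_vars = as.integer(max_vars),
                 candidate_starts = candidate_starts),
            class = "spa_config")
}

#' Genetic algorithm configuration
#'
#' Defaults follow common chemometric practice for GA wavenumber
#' selection: 100 generations of 200 chromosomes, crossover probability
#' 0.60 and mutation probability 0.10. Under the default
#' `mutation = "per_chromosome"` reading, each bit flips independently
#' with probability `mutation_prob / L` (`L` = chromosome length), so on
#' average about 10% of chromosomes experience a flip;
#' `mutation = "per_bit"` flips each bit with probability
#' `mutation_prob` instead.
#'
#' @param generations number of generations.
#' @param population chromosomes per generation.
#' @param mutation_prob mutation probability (see above).
#' @param crossover_prob one-point crossover probability per pair.
#' @param subset_min,subset_max bounds on the number of selected
#'   variables; offspring are repaired into this range. The default cap
#'   of 30 keeps the pooled covariance invertible with small training
#'   sets.
#' @param elitism number of best-so-far chromosomes reinjected each
#'   generation.
#' @param mutation `"per_chromosome"` or `"per_bit"` (see above).
#' @param seed integer RNG seed, or `NULL` to consume the caller's RNG
#'   stream.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(generations = 100, population = 200,
                      mutation_prob = 0.10, crossover_prob = 0.60,
                      subset_min = 2, subset_max = 30, elitism = 1,
                      mutation = c("per_chromosome", "per_bit"),
                      seed = NULL) {
  stopifnot(generations >= 1, population >= 2,
            mutation_prob >= 0, mutation_prob <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            subset_min >= 1, subset_min <= subset_max, elitism >= 0)
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 mutation_prob = mutation_prob,
                 crossover_prob = crossover_prob,
                 subset_min = as.integer(subset_min),
                 subset_max = as.integer(subset_max),
                 elitism = as.integer(elitism),
                 mutation = match.arg(mutation),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ga_config")
}

new_variable_subset <- function(indices, axis, cost, method,
                                history = NULL) {
  structure(list(indices = as.integer(indices),
                 wavenumbers = if (is.null(axis)) NULL
                               else axis[indices],
                 cost_G = cost, method = method, history = history),
            class = "variable_subset")
}

#' @export
print.variable_subset <- function(x, ...) {
  cat("<variable_subset> ", x$method, ": ", length(x$indices),
      " variables, G = ", format(x$cost_G, digits = 6), "\n", sep = "")
  if (!is.null(x$wavenumbers))
    cat("  wavenumbers (cm^-1):",
        paste(round(x$wavenumbers, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Variable selection by the successive projections algorithm
#'
#' For every candidate start column, builds a chain of up to `max_vars`
#' variables by repeatedly choosing the column with the largest norm
#' after orthogonal projection off the span of the columns already in
#' the chain (computed on the training matrix) - i.e. the variable least
#' collinear with those already selected. Every (start, length) prefix
#' is then scored with the validation cost [cost_G()], and the global
#' minimum-G chain is returned. Fully deterministic.
#'
#' @param X_train,y_train training matrix (rows = spectra) and labels.
#' @param X_val,y_val validation matrix and labels.
#' @param config a [spa_config()].
#' @param axis optional wavenumber axis for reporting.
#' @return a `variable_subset` (fields `indices`, `wavenumbers`,
#'   `cost_G`, `method = "SPA"`).
#' @export
spa_select <- function(X_train, y_train, X_val, y_val,
                       config = spa_config(), axis = NULL) {
  stopifnot(inherits(config, "spa_config"))
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  p <- ncol(X_train)
  max_vars <- config$max_vars
  if (max_vars > min(nrow(X_train) - 2L, p))
    stop("max_vars exceeds min(n_train - 2, n_wavenumbers) = ",
         min(nrow(X_train) - 2L, p), call. = FALSE)
  starts <- config$candidate_starts
  if (is.null(starts)) starts <- seq_len(p)
  evalG_strict <- make_cost_evaluator(X_train, y_train, X_val, y_val)
  # a chain whose pooled covariance is degenerate beyond repair can
  # never be selected; score it Inf instead of aborting the search
  evalG <- function(subset)
    tryCatch(evalG_strict(subset), error = function(e) Inf)

  best <- list(G = Inf, chain = integer())
  for (s in starts) {
    # residuals of all columns after projecting off the growing chain
    R <- X_train
    chain <- integer(max_vars)
    cur <- as.integer(s)
    for (l in seq_len(max_vars)) {
      chain[l] <- cur
      G <- evalG(chain[seq_len(l)])
      if (G < best$G) best <- list(G = G, chain = chain[seq_len(l)])
      if (l == max_vars) break
      v <- R[, cur]
      nv <- sum(v^2)
      if (nv <= 1e-12 * sum(X_train[, cur]^2)) break
      R <- R - tcrossprod(v / nv, crossprod(R, v))  # Gram-Schmidt step
      nrm <- colSums(R^2)
      nrm[chain[seq_len(l)]] <- -Inf
      nrm[nrm <= 1e-10 * max(nrm)] <- -Inf          # collinear: excluded
      if (all(!is.finite(nrm))) break
      cur <- which.max(nrm)
    }
  }
  new_variable_subset(best$chain, axis, best$G, "SPA")
}

# draw a random chromosome with size in [smin, smax]
random_chromosome <- function(L, smin, smax) {
  k <- sample(smin:smax, 1)
  ch <- logical(L)
  ch[sample.int(L, k)] <- TRUE
  ch
}

# force the number of selected bits into [smin, smax] by random flips
repair_chromosome <- function(ch, smin, smax) {
  k <- sum(ch)
  if (k > smax) {
    on <- which(ch)
    ch[sample(on, k - smax)] <- FALSE
  } else if (k < smin) {
    off <- which(!ch)
    ch[sample(off, smin - k)] <- TRUE
  }
  ch
}

#' Variable selection by a genetic algorithm
#'
#' Binary chromosomes of length `n_wavenumbers` encode variable subsets;
#' fitness is `1 / (G + 1e-12)` with [cost_G()] evaluated on the
#' validation set. Each generation applies roulette-wheel selection,
#' one-point crossover, bitwise mutation and repair into
#' `[subset_min, subset_max]`; elitism reinjects the best-so-far
#' chromosome. The best chromosome ever seen and its G are returned.
#' With a non-`NULL` seed the result is a pure function of the inputs.
#'
#' @param X_train,y_train training matrix and labels.
#' @param X_val,y_val validation matrix and labels.
#' @param config a [ga_config()].
#' @param axis optional wavenumber axis for reporting.
#' @param initial_population optional list of logical chromosomes (each
#'   of length `n_wavenumbers`) seeding the first generation; shorter
#'   lists are topped up with random chromosomes.
#' @return a `variable_subset` with `method = "GA"` and `history`, the
#'   best-so-far G after each generation (non-increasing).
#' @export
ga_select <- function(X_train, y_train, X_val, y_val,
                      config = ga_config(), axis = NULL,
                      initial_population = NULL) {
  stopifnot(inherits(config, "ga_config"))
  run <- function() ga_select_impl(X_train, y_train, X_val, y_val,
                                   config, axis, initial_population)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

ga_select_impl <- function(X_train, y_train, X_val, y_val, config,
                           axis, initial_population = NULL) {
  X_train <- as.matrix(X_train)
  L <- ncol(X_train)
  smin <- config$subset_min
  smax <- min(config$subset_max, L)
  if (smin > L)
    stop("subset_min exceeds the number of variables", call. = FALSE)
  evalG_strict <- make_cost_evaluator(X_train, y_train, X_val, y_val)
  memo <- new.env(parent = emptyenv())
  score <- function(ch) {
    key <- paste(which(ch), collapse = ",")
    g <- memo[[key]]
    if (is.null(g)) {
      # degenerate subsets (irreparably singular covariance) are
      # unfit, not fatal
      g <- tryCatch(evalG_strict(which(ch)), error = function(e) Inf)
      memo[[key]] <- g
    }
    g
  }
  bit_rate <- if (config$mutation == "per_chromosome")
    config$mutation_prob / L else config$mutation_prob

  pop <- replicate(config$population, random_chromosome(L, smin, smax),
                   simplify = FALSE)
  if (!is.null(initial_population)) {
    if (any(lengths(initial_population) != L))
      stop("initial_population chromosomes must have length ", L,
           call. = FALSE)
    seed_pop <- lapply(initial_population, function(ch)
      repair_chromosome(as.logical(ch), smin, smax))
    nseed <- min(length(seed_pop), length(pop))
    pop[seq_len(nseed)] <- seed_pop[seq_len(nseed)]
  }
  G <- vapply(pop, score, numeric(1))
  best_idx <- which.min(G)
  best <- list(ch = pop[[best_idx]], G = G[best_idx])
  history <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    fitness <- 1 / (G + 1e-12)
    parents <- sample.int(length(pop), length(pop), replace = TRUE,
                          prob = fitness)
    newpop <- pop[parents]
    # one-point crossover on consecutive pairs
    for (i in seq(1, length(newpop) - 1, by = 2)) {
      if (stats::runif(1) < config$crossover_prob && L > 1) {
        pt <- sample.int(L - 1L, 1)
        a <- newpop[[i]]; b <- newpop[[i + 1]]
        newpop[[i]]     <- c(a[1:pt], b[(pt + 1):L])
        newpop[[i + 1]] <- c(b[1:pt], a[(pt + 1):L])
      }
    }
    newpop <- lapply(newpop, function(ch) {
      if (bit_rate > 0) {
        fl <- stats::runif(L) < bit_rate
        ch <- xor(ch, fl)
      }
      repair_chromosome(ch, smin, smax)
    })
    G <- vapply(newpop, score, numeric(1))
    if (config$elitism > 0) {                 # reinject best-so-far
      worst <- order(G, decreasing = TRUE)[seq_len(config$elitism)]
      for (w in worst) {
        newpop[[w]] <- best$ch
        G[w] <- best$G
      }
    }
    pop <- newpop
    gi <- which.min(G)
    if (G[gi] < best$G) best <- list(ch = pop[[gi]], G = G[gi])
    history[gen] <- best$G
  }
  new_variable_subset(which(best$ch), axis, best$G, "GA",
                      history = history)
}
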