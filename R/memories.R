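as_pattern_matrix <- function(patterns) {
  P <- if (is.matrix(patterns)) patterns else matrix(patterns, nrow = 1)
  if (!all(P %in% c(0, 1))) stop("patterns must be 0/1")
  storage.mode(P) <- "integer"
  P
}

#' Hebbian weight matrix encoding a set of binary memories
#'
#' With the spin mapping `zeta = 2 xi - 1`, the encoded couplings are
#' `w_ij = (1/N) sum_mu zeta_i^mu zeta_j^mu` for `i != j` and 0 on the
#' diagonal (the standard Hopfield convention). Complementing any pattern
#' leaves the matrix unchanged.
#'
#' @param patterns A `p x N` 0/1 matrix (one memory per row) or a single 0/1
#'   vector.
#' @param normalize If `TRUE` (default) the rule carries the usual 1/N factor,
#'   the convention used for the least-squares memory readout. `FALSE` drops
#'   it, giving couplings of order 1 -- the magnitude scale of learned weight
#'   matrices, appropriate when the encoded network is simulated at a fixed
#'   physical temperature.
#' @return Symmetric zero-diagonal `N x N` matrix.
#' @export
#' @examples
#' hebbian_weights(c(1, 1, 1, 1))  # all off-diagonal entries 1/4
hebbian_weights <- function(patterns, normalize = TRUE) {
  P <- as_pattern_matrix(patterns)
  if (nrow(P) < 1) stop("at least one pattern is required")
  Z <- 2 * P - 1
  W <- crossprod(Z)
  storage.mode(W) <- "double"
  if (normalize) W <- W / ncol(P)
  diag(W) <- 0
  W
}

#' Hebbian reconstruction cost of a candidate memory set
#'
#' Sum over unordered off-diagonal pairs of the squared difference between the
#' supplied weights and the Hebbian matrix encoded by the candidate patterns:
#' `sum_{i < j} (w_ij - w^H_ij)^2`. The quantity minimized when reading
#' memories out of learned couplings.
#'
#' @param weights Symmetric zero-diagonal matrix.
#' @param patterns `p x N` 0/1 matrix or 0/1 vector.
#' @return Non-negative cost.
#' @export
memory_cost <- function(weights, patterns) {
  P <- as_pattern_matrix(patterns)
  if (ncol(P) != nrow(weights)) stop("pattern length does not match weights")
  WH <- hebbian_weights(P)
  d <- (weights - WH)[upper.tri(weights)]
  sum(d * d)
}

canonicalize_pattern <- function(xi) {
  if (xi[1] == 1L) 1L - xi else xi
}

canonicalize_patterns <- function(P) {
  P <- t(apply(P, 1, canonicalize_pattern))
  key <- apply(P, 1, paste, collapse = "")
  P[order(key), , drop = FALSE]
}

new_memory_set <- function(patterns, cost, method) {
  structure(list(patterns = as_pattern_matrix(patterns), cost = cost,
                 method = method),
            class = "memory_set")
}

#' @export
print.memory_set <- function(x, ...) {
  cat("Memory set: p = ", nrow(x$patterns), ", N = ", ncol(x$patterns),
      " (", x$method, " search)\n", sep = "")
  cat("  Hebbian reconstruction cost: ", signif(x$cost, 6), "\n", sep = "")
  for (mu in seq_len(nrow(x$patterns)))
    cat("  memory ", mu, ": ", paste(x$patterns[mu, ], collapse = ""), "\n",
        sep = "")
  invisible(x)
}

# Enumerate canonical +-1 candidates (first spin fixed at -1) in lexicographic
# order of the 0/1 pattern, in chunks, and return the score
# g(zeta) = sum_{i<j} w_ij zeta_i zeta_j maximizer.
#' Exhaustive least-squares readout of a single stored memory
#'
#' Scans all `2^(N-1)` pattern classes (patterns up to complement, which leave
#' the Hebbian matrix invariant) and returns the single memory minimizing the
#' reconstruction cost. Minimizing the cost is equivalent to maximizing the
#' quadratic form `sum_{i<j} w_ij zeta_i zeta_j`, which is how the scan is
#' evaluated. Ties are broken deterministically: the lexicographically
#' smallest canonical representative (first bit 0) wins. Guarded at
#' `N <= 22`.
#'
#' @param weights Symmetric zero-diagonal matrix.
#' @return A `memory_set` with `p = 1` (canonical representative) and its
#'   cost.
#' @export
#' @examples
#' xi <- c(0, 1, 1, 0, 1)
#' exhaustive_lse(hebbian_weights(xi))  # recovers xi (cost 0)
exhaustive_lse <- function(weights) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n)
  if (n > 22) stop("exhaustive search is limited to N <= 22")
  if (max(abs(weights - t(weights))) > 1e-9) stop("weights must be symmetric")
  n_free <- n - 1L
  total <- 2^n_free
  chunk <- 2^16
  best_g <- -Inf; best_idx <- NA; best_start <- NA
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    # bits of free positions 2..n, most significant first => lexicographic order
    B <- vapply(seq_len(n_free), function(j)
      (idx %/% 2^(n_free - j)) %% 2, numeric(length(idx)))
    Z <- cbind(-1, 2 * B - 1)
    g <- rowSums((Z %*% weights) * Z) / 2
    k <- which.max(g)
    if (g[k] > best_g) { best_g <- g[k]; best_idx <- k; best_start <- start }
  }
  idx <- best_start + best_idx - 1
  bits <- as.integer((idx %/% 2^(n_free - seq_len(n_free))) %% 2)
  xi <- c(0L, bits)
  new_memory_set(matrix(xi, nrow = 1), memory_cost(weights, xi), "exhaustive")
}

#' Genetic-algorithm configuration for the memory readout
#'
#' @param population_size Number of individuals (default 100).
#' @param generations Number of generations.
#' @param elite_fraction Fraction of best individuals copied unchanged into
#'   the next generation (default 0.10).
#' @param mutations_per_generation Point mutations applied per generation;
#'   default `max(1, population_size / 10)`.
#' @param seed Integer seed.
#' @return A list of class `ga_config`. Tournament size is fixed at 2.
#' @export
ga_config <- function(population_size = 100L, generations = 300L,
                      elite_fraction = 0.10,
                      mutations_per_generation = NULL, seed = 1L) {
  if (is.null(mutations_per_generation))
    mutations_per_generation <- max(1L, as.integer(population_size / 10))
  stopifnot(population_size >= 4, generations >= 0,
            elite_fraction > 0, elite_fraction < 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 tournament_size = 2L,
                 mutations_per_generation = as.integer(mutations_per_generation),
                 seed = as.integer(seed)),
            class = "ga_config")
}

ga_cost <- function(weights, ind, n) {
  # ind: p x N integer matrix
  Z <- 2 * ind - 1
  WH <- crossprod(Z) / n
  diag(WH) <- 0
  d <- (weights - WH)[upper.tri(weights)]
  sum(d * d)
}

#' Genetic-algorithm least-squares readout of p stored memories
#'
#' Evolves a population of candidate memory sets (each individual is `p`
#' binary vectors of length N) to minimize the Hebbian reconstruction cost.
#' The 10 percent best individuals pass unchanged to the next generation
#' (elitism, so the best-so-far cost is non-increasing); the rest are replaced
#' by children built by tournament selection of size 2 (two random pairs, the
#' better of each pair becomes a parent) and single-point crossover applied to
#' each of the `p` vectors, followed by point mutations. Deterministic given
#' the seed.
#'
#' @param weights Symmetric zero-diagonal matrix.
#' @param p Number of memories (>= 2; use [exhaustive_lse()] for p = 1).
#' @param config A [ga_config()].
#' @return A `memory_set` with canonicalized patterns (per-pattern complement
#'   representative, sorted) and the best cost found.
#' @export
ga_lse <- function(weights, p = 2L, config = ga_config()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, p >= 2, inherits(config, "ga_config"))
  set.seed(config$seed)
  ps <- config$population_size
  pop <- lapply(seq_len(ps), function(k)
    matrix(sample(0:1, p * n, replace = TRUE), nrow = p))
  costs <- vapply(pop, ga_cost, numeric(1), weights = weights, n = n)
  n_elite <- max(1L, as.integer(ceiling(config$elite_fraction * ps)))

  for (gen in seq_len(config$generations)) {
    ord <- order(costs)
    pop <- pop[ord]; costs <- costs[ord]
    newpop <- pop[seq_len(n_elite)]
    while (length(newpop) < ps) {
      # tournament of size 2, twice: best of each random pair is a parent
      pick <- function() {
        pair <- sample.int(ps, 2L)
        if (costs[pair[1]] <= costs[pair[2]]) pop[[pair[1]]] else pop[[pair[2]]]
      }
      dad <- pick(); mum <- pick()
      child <- dad
      for (mu in seq_len(p)) {
        cut <- sample.int(n - 1L, 1L)
        child[mu, (cut + 1L):n] <- mum[mu, (cut + 1L):n]
      }
      newpop[[length(newpop) + 1L]] <- child
    }
    # point mutations on non-elite individuals
    for (k in seq_len(config$mutations_per_generation)) {
      tgt <- sample((n_elite + 1L):ps, 1L)
      mu <- sample.int(p, 1L); pos <- sample.int(n, 1L)
      newpop[[tgt]][mu, pos] <- 1L - newpop[[tgt]][mu, pos]
    }
    pop <- newpop
    costs <- vapply(pop, ga_cost, numeric(1), weights = weights, n = n)
  }
  best <- which.min(costs)
  new_memory_set(canonicalize_patterns(pop[[best]]), costs[best], "genetic")
}

#' Read candidate stored memories out of learned couplings
#'
#' Convenience front end: exhaustive search for a single memory, genetic
#' algorithm for two or more.
#'
#' @param fit A `boltzmann_fit`, `coupling_model`, or a weight matrix.
#' @param p Number of memories to read out.
#' @param config GA configuration, used when `p >= 2`.
#' @return A `memory_set`.
#' @export
read_memories <- function(fit, p = 1L, config = ga_config()) {
  W <- if (inherits(fit, "boltzmann_fit")) fit$model$weights
       else if (inherits(fit, "coupling_model")) fit$weights
       else as.matrix(fit)
  if (p == 1L) exhaustive_lse(W) else ga_lse(W, p = p, config = config)
}
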