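# Independent oracles used across tests; deliberately brute-force and
# independent of the package's search/learning code paths.

# all 0/1 patterns of length n as rows, lexicographic (leftmost bit most
# significant)
all_patterns <- function(n) {
  G <- expand.grid(rep(list(0:1), n))[, n:1, drop = FALSE]
  m <- as.matrix(G)
  dimnames(m) <- NULL
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# brute-force single-memory least-squares cost minimum (loops, no algebraic
# shortcut)
brute_lse_p1 <- function(W) {
  n <- nrow(W)
  best <- Inf; best_xi <- NULL
  P <- all_patterns(n)
  for (r in seq_len(nrow(P))) {
    xi <- P[r, ]
    z <- 2 * xi - 1
    cost <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      cost <- cost + (W[i, j] - z[i] * z[j] / n)^2
    if (cost < best - 1e-12) { best <- cost; best_xi <- xi }
  }
  list(cost = best, pattern = best_xi)
}

# brute-force two-memory minimum over all canonical (first-bit-0) pairs
brute_lse_p2 <- function(W) {
  n <- nrow(W)
  P <- all_patterns(n - 1)
  cand <- cbind(0L, P)  # canonical representatives
  best <- Inf
  for (a in seq_len(nrow(cand))) for (b in seq_len(nrow(cand))) {
    best <- min(best, memory_cost(W, rbind(cand[a, ], cand[b, ])))
  }
  best
}

binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -(p * log2(p) + (1 - p) * log2(1 - p)))
}

# tiny hand-built DMN: n subsystems in a ring of fluxes, one signal of each
# class per target (balanced), optional overrides
toy_network <- function(n = 4, seed = 11, stimuli = NULL) {
  if (is.null(stimuli)) stimuli <- stats::setNames(0.5, "1")
  generate_network(seed = seed, n = n, stimuli = stimuli)
}
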