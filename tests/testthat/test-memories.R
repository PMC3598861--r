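test_that("Hebbian encoding follows the 1/N spin-product rule", {
  W <- hebbian_weights(c(1, 1, 1, 1))
  expect_equal(W, matrix(1 / 4, 4, 4) - diag(1 / 4, 4))
  # complement invariance
  set.seed(3)
  xi <- rbinom(10, 1, 0.5)
  expect_equal(hebbian_weights(xi), hebbian_weights(1 - xi))
  P <- rbind(xi, 1 - xi)
  expect_equal(hebbian_weights(P), 2 * hebbian_weights(xi))
  # independence of random pattern bits: off-diagonal mean near zero
  set.seed(8)
  n <- 50
  acc <- replicate(400, {
    W <- hebbian_weights(matrix(rbinom(2 * n, 1, 0.5), 2))
    mean(W[upper.tri(W)])
  })
  expect_lt(abs(mean(acc)), 3 / (n * sqrt(400)) * 5)
  expect_error(hebbian_weights(matrix(0.5, 1, 4)), "0/1")
})

test_that("the reconstruction cost is a pairwise MSE with the stated degeneracies", {
  set.seed(5)
  P <- matrix(rbinom(2 * 8, 1, 0.5), 2)
  W <- hebbian_weights(P)
  expect_equal(memory_cost(W, P), 0)
  # complementing any single pattern leaves the cost unchanged
  P2 <- P; P2[1, ] <- 1 - P2[1, ]
  Wx <- matrix(rnorm(64), 8); Wx <- Wx + t(Wx); diag(Wx) <- 0
  expect_equal(memory_cost(Wx, P), memory_cost(Wx, P2))
  # permuting patterns leaves the cost unchanged
  expect_equal(memory_cost(Wx, P), memory_cost(Wx, P[2:1, ]))
  # hand-computed: zero weights, single all-ones pattern at N = 3
  expect_equal(memory_cost(matrix(0, 3, 3), c(1, 1, 1)), 3 * (1 / 3)^2)
  expect_error(memory_cost(Wx, c(1, 0)), "does not match")
})

test_that("exhaustive single-memory search matches a brute-force oracle", {
  set.seed(12)
  xi <- rbinom(9, 1, 0.5)
  mem <- exhaustive_lse(hebbian_weights(xi))
  expect_equal(mem$cost, 0)
  expect_true(all(mem$patterns[1, ] == xi) || all(mem$patterns[1, ] == 1 - xi))
  expect_equal(mem$patterns[1, 1], 0L)  # canonical representative

  # adversarial matrix: negated Hebbian, compare with independent brute force
  W4 <- -hebbian_weights(c(1, 0, 1, 0))
  oracle <- brute_lse_p1(W4)
  got <- exhaustive_lse(W4)
  expect_equal(got$cost, oracle$cost, tolerance = 1e-12)

  # random matrices agree with the oracle too
  for (s in 1:3) {
    set.seed(s)
    Wr <- matrix(rnorm(36), 6); Wr <- Wr + t(Wr); diag(Wr) <- 0
    expect_equal(exhaustive_lse(Wr)$cost, brute_lse_p1(Wr)$cost,
                 tolerance = 1e-12)
  }

  # full degeneracy: deterministic canonical tie-break
  z <- exhaustive_lse(matrix(0, 3, 3))
  expect_equal(unname(z$patterns[1, ]), c(0L, 0L, 0L))
  expect_error(exhaustive_lse(matrix(0, 23, 23)), "N <= 22")
})

test_that("the genetic algorithm is elitist, seeded and oracle-bounded", {
  set.seed(42)
  n <- 8
  Wr <- matrix(rnorm(n^2), n); Wr <- Wr + t(Wr); diag(Wr) <- 0

  # determinism given the seed
  g1 <- ga_lse(Wr, config = ga_config(generations = 50, seed = 9))
  g2 <- ga_lse(Wr, config = ga_config(generations = 50, seed = 9))
  expect_identical(g1$patterns, g2$patterns)
  expect_identical(g1$cost, g2$cost)

  # more generations never hurt (elitism) and the exhaustive pair minimum is
  # a hard lower bound
  g0 <- ga_lse(Wr, config = ga_config(generations = 0, seed = 9))
  expect_lte(g1$cost, g0$cost)
  lb <- brute_lse_p2(Wr)
  expect_gte(g1$cost + 1e-12, lb)

  # reported cost is consistent with the returned patterns
  expect_equal(g1$cost, memory_cost(Wr, g1$patterns))
})

test_that("planted orthogonal pairs are recovered by the genetic algorithm", {
  xi1 <- rep(c(0L, 1L), 6)
  xi2 <- rep(c(0L, 0L, 1L, 1L), 3)   # orthogonal in the +-1 inner product
  W <- hebbian_weights(rbind(xi1, xi2))
  hit <- 0L
  for (s in 1:5) {
    g <- ga_lse(W, config = ga_config(generations = 300, seed = s))
    if (g$cost < 1e-12) hit <- hit + 1L
  }
  expect_gte(hit, 4L)
  g <- ga_lse(W, config = ga_config(generations = 300, seed = 1))
  want <- canonical_sorted <- {
    cp <- function(x) if (x[1] == 1) 1 - x else x
    m <- rbind(cp(xi1), cp(xi2))
    m[order(apply(m, 1, paste, collapse = "")), ]
  }
  expect_equal(unname(g$patterns), unname(want))
})

test_that("read_memories dispatches by pattern count", {
  xi <- c(0, 1, 1, 0, 1, 0)
  W <- hebbian_weights(xi)
  m1 <- read_memories(W, p = 1)
  expect_equal(m1$method, "exhaustive")
  m2 <- read_memories(W, p = 2, config = ga_config(generations = 30, seed = 2))
  expect_equal(m2$method, "genetic")
  expect_gte(m2$cost, 0)
})
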