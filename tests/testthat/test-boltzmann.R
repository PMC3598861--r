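test_that("Glauber probability is the logistic of field over temperature", {
  expect_equal(glauber_probability(0, 1), 0.5)
  expect_equal(glauber_probability(0, 0.01), 0.5)
  expect_equal(glauber_probability(1, 0.5), plogis(2), tolerance = 1e-12)
  expect_equal(glauber_probability(1, 0.5), 0.8808, tolerance = 1e-4)
  expect_gt(glauber_probability(0.5, 1e-4), 1 - 1e-10)
  expect_error(glauber_probability(1, 0), "temperature")
})

test_that("exact Boltzmann-Gibbs distribution matches closed forms", {
  n <- 4
  m0 <- coupling_model(matrix(0, n, n), rep(0, n))
  d0 <- exact_distribution(m0)
  expect_equal(d0$prob, rep(2^-n, 2^n))
  expect_equal(sum(d0$prob), 1)

  m1 <- coupling_model(matrix(0, 1, 1), -1)
  d1 <- exact_distribution(m1)
  expect_equal(d1$prob[d1$states[, 1] == 1], plogis(1), tolerance = 1e-12)
  expect_equal(d1$prob[2], 0.7311, tolerance = 1e-4)

  W <- matrix(c(0, 50, 50, 0), 2)
  d2 <- exact_distribution(coupling_model(W, c(0, 0)))
  agree <- rowSums(d2$states) != 1
  expect_gt(sum(d2$prob[agree]), 1 - 1e-10)

  expect_error(exact_distribution(coupling_model(matrix(0, 21, 21),
                                                 rep(0, 21))), "N <= 20")
})

test_that("mean-field linear-response learning has the right closed-form limits", {
  # independent data: diagonal covariance -> zero couplings, logit thresholds
  m <- c(0.3, 0.6, 0.8)
  X <- rbind(rep(c(1, 0), c(3, 7)), rep(c(1, 0), c(6, 4)), rep(c(1, 0), c(8, 2)))
  st <- compute_moments(X)
  st$covariance <- diag(m * (1 - m))
  st$means <- m
  fit <- learn_mf_lr(st, temperature = 2)
  expect_equal(unname(coef(fit, "weights")), matrix(0, 3, 3))
  expect_equal(unname(coef(fit, "thresholds")), -2 * log(m / (1 - m)))

  # symmetry and zero diagonal on real data
  set.seed(21)
  X2 <- matrix(rbinom(5 * 4000, 1, 0.5), 5)
  f2 <- boltzmann_fit(X2, method = "mflr")
  W2 <- coef(f2, "weights")
  expect_equal(W2, t(W2))
  expect_equal(diag(W2), rep(0, 5), ignore_attr = TRUE)
})

test_that("degenerate units are excluded with undefined thresholds", {
  set.seed(2)
  X <- rbind(matrix(rbinom(3 * 500, 1, 0.5), 3), rep(1L, 500))
  fit <- boltzmann_fit(X, method = "mflr")
  expect_equal(fit$excluded, 4L)
  expect_true(is.na(coef(fit, "thresholds")[4]))
  expect_true(all(coef(fit, "weights")[4, ] == 0))
})

test_that("singular covariance signals collinearity unless ridged", {
  X <- rbind(c(1, 0, 1, 0, 1, 0), c(1, 0, 1, 0, 1, 0), c(1, 1, 0, 0, 1, 0))
  st <- compute_moments(X)
  expect_error(learn_mf_lr(st), "ridge")
  fit <- learn_mf_lr(st, ridge = 1e-6)
  expect_true(all(is.finite(coef(fit, "weights"))))
})

test_that("exact learning reaches the moment-matching fixed point", {
  # independent biased coins: couplings shrink to zero
  set.seed(31)
  X <- matrix(rbinom(5 * 1e5, 1, rep(c(0.25, 0.4, 0.5, 0.6, 0.75), 1e5)), 5)
  fit <- learn_exact(X, learning_rate = 0.5, max_iter = 3000, tol = 1e-3,
                     seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit, "weights"))), 0.05)
  res <- residuals(fit)
  expect_lt(max(abs(res$means)), 1e-2)

  # zero-iteration call returns the (seeded) initialization with residuals
  f0 <- learn_exact(X, max_iter = 0, seed = 7)
  f0b <- learn_exact(X, max_iter = 0, seed = 7)
  expect_identical(coef(f0, "weights"), coef(f0b, "weights"))
  expect_false(isTRUE(f0$converged))
  expect_true(is.finite(f0$moment_residuals))

  # learner output is symmetric with zero diagonal
  W <- coef(fit, "weights")
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 5), ignore_attr = TRUE)
})

test_that("mean-field entropy matches the closed form and its bounds", {
  expect_identical(entropy_mf(rep(0.5, 17)), 17)
  expect_identical(entropy_mf(c(0, 1, 0.5)), 1)
  expect_equal(entropy_mf(rep(0.85, 17)), 17 * binary_entropy(0.85))
  expect_equal(entropy_mf(rep(0.85, 17)), 10.37, tolerance = 1e-3)
  # moving any mean toward 0.5 increases the entropy
  m <- c(0.1, 0.3, 0.9)
  for (i in seq_along(m)) {
    m2 <- m; m2[i] <- m[i] + 0.05 * sign(0.5 - m[i])
    expect_gt(entropy_mf(m2), entropy_mf(m))
  }
  # exclusion removes a unit's contribution
  expect_equal(entropy_mf(rep(0.5, 18), excluded = 15), 17)
})

test_that("mean-field energy matches hand evaluation and guards exclusions", {
  n <- 2
  expect_equal(energy_mf(coupling_model(matrix(0, n, n), c(0, 0)), c(0.3, 0.9)), 0)
  W <- matrix(c(0, 4, 4, 0), 2)
  mod <- coupling_model(W, c(1, 1))
  expect_equal(energy_mf(mod, c(0.5, 0.5)), 0)
  expect_equal(energy_mf(mod, c(0, 0)), 0)
  mod_na <- coupling_model(W, c(1, NA))
  expect_error(energy_mf(mod_na, c(0.5, 0.5)), "undefined threshold")
  expect_equal(energy_mf(mod_na, c(0.5, 0.5), excluded = 2), 0.5)
})

test_that("weight-distribution summary reproduces the published table statistics", {
  fx <- paper_fixture("T3")
  s <- weight_distribution_summary(fx$payload)
  expect_equal(round(s$mean, 2), 0.37)
  expect_equal(round(s$sd, 2), 2.83)
  expect_equal(s$min, -6.66)
  expect_equal(s$max, 18.31)
  # strongly non-Gaussian couplings flagged by the diagnostics
  expect_gt(s$excess_kurtosis, 2)

  z <- weight_distribution_summary(matrix(0, 4, 4))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)

  set.seed(77)
  G <- matrix(rnorm(1e4), 100)
  g <- weight_distribution_summary(G)
  expect_lt(abs(g$excess_kurtosis), 0.3)
  expect_lt(g$qq_deviation, 0.05)
})

test_that("the two learners agree for weak couplings", {
  set.seed(55)
  n <- 8
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, -0.2, 0.2)
  W <- W + t(W)
  true_model <- coupling_model(W, rnorm(n, 0, 0.1))
  raster <- simulate(true_model, nsim = 1e5, seed = 8, burn_in_mcs = 200)
  f_mf <- boltzmann_fit(raster, method = "mflr")
  f_ex <- boltzmann_fit(raster, method = "exact", learning_rate = 0.5,
                        max_iter = 20000, tol = 3e-4, seed = 3)
  wm <- coef(f_mf, "weights")[upper.tri(W)]
  we <- coef(f_ex, "weights")[upper.tri(W)]
  rel_frob <- sqrt(sum((wm - we)^2) / sum(we^2))
  expect_lt(rel_frob, 0.15)
})

test_that("Glauber sampling obeys detailed balance against the exact distribution", {
  set.seed(14)
  n <- 5
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, -0.8, 0.8)
  W <- W + t(W)
  model <- coupling_model(W, runif(n, -0.5, 0.5))
  ed <- exact_distribution(model)
  # 10^6 elementary steps = 2 * 10^5 MCS at N = 5
  tr <- glauber_run(model, initial = rep(0L, n), n_mcs = 2e5, seed = 5)
  code <- drop(2^(seq_len(n) - 1) %*% tr$states) + 1
  emp <- tabulate(code, 2^n) / length(code)
  tv <- 0.5 * sum(abs(emp - ed$prob))
  expect_lt(tv, 0.01)
})

test_that("fit methods expose coherent summaries and predictions", {
  set.seed(61)
  X <- matrix(rbinom(4 * 5000, 1, 0.5), 4)
  fit <- boltzmann_fit(X, method = "mflr")
  s <- summary(fit)
  expect_s3_class(s, "summary.boltzmann_fit")
  expect_equal(s$entropy_bits, entropy_mf(fit$stats))
  p <- predict(fit, rep(1, 4))
  expect_true(all(p > 0 & p < 1))
  expect_output(print(fit), "Boltzmann fit")
  expect_output(print(s), "mean-field entropy")
})
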