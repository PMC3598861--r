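#' Glauber activation probability
#'
#' Probability that a binary unit is set to 1 when resampled: the logistic
#' function of its local field over the temperature,
#' `sigma(h / T) = 1 / (1 + exp(-h / T))`, where the local field of unit `i`
#' is `h_i = sum_j w_ij s_j - theta_i`.
#'
#' @param local_field Numeric local field(s).
#' @param temperature Positive temperature (Boltzmann constant taken as 1).
#' @return Probabilities in (0,1).
#' @export
#' @examples
#' glauber_probability(0, 1)    # 0.5
#' glauber_probability(1, 0.5)  # sigma(2)
glauber_probability <- function(local_field, temperature = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  stats::plogis(local_field / temperature)
}

new_coupling_model <- function(weights, thresholds, temperature = 1) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, length(thresholds) == n, temperature > 0)
  if (max(abs(weights - t(weights)), na.rm = TRUE) > 1e-9)
    stop("weights must be symmetric")
  diag(weights) <- 0
  structure(list(weights = weights, thresholds = as.numeric(thresholds),
                 temperature = temperature),
            class = "coupling_model")
}

#' Construct a coupling model (weights, thresholds, temperature)
#'
#' A pairwise binary-unit model with symmetric zero-diagonal weights `w_ij`,
#' thresholds `theta_i` (entries may be `NA` for degenerate, permanently
#' clamped units, the finite-data rendering of an infinite threshold) and a
#' positive temperature. Its energy is
#' `E(s) = -1/2 sum_{i != j} w_ij s_i s_j + sum_i theta_i s_i` and its
#' stationary law under Glauber dynamics is `p(s) propto exp(-E(s)/T)`.
#'
#' @param weights Symmetric numeric matrix; the diagonal is forced to zero.
#' @param thresholds Numeric vector, `NA` allowed for degenerate units.
#' @param temperature Positive temperature.
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(weights, thresholds, temperature = 1) {
  new_coupling_model(weights, thresholds, temperature)
}

#' @export
print.coupling_model <- function(x, ...) {
  n <- nrow(x$weights)
  cat("Coupling model: ", n, " units, T = ", x$temperature, "\n", sep = "")
  offd <- x$weights[upper.tri(x$weights)]
  cat("  weights  (off-diag): mean ", signif(mean(offd), 3), ", range [",
      signif(min(offd), 3), ", ", signif(max(offd), 3), "]\n", sep = "")
  cat("  thresholds: ", sum(is.na(x$thresholds)), " undefined (degenerate)\n",
      sep = "")
  invisible(x)
}

enumerate_states <- function(n) {
  # 2^n x n matrix of 0/1 rows, row r is the binary expansion of r-1
  # (unit 1 = least significant bit)
  stopifnot(n >= 1)
  idx <- 0:(2^n - 1)
  vapply(seq_len(n), function(j) (idx %/% 2^(j - 1)) %% 2, numeric(2^n))
}

state_energies <- function(model, S) {
  -0.5 * rowSums((S %*% model$weights) * S) + drop(S %*% model$thresholds)
}

#' Exact Boltzmann-Gibbs distribution over all states
#'
#' Enumerates the `2^N` binary configurations and returns
#' `p(s) propto exp(-E(s)/T)`. Guarded at `N <= 20`.
#'
#' @param model A `coupling_model` with all thresholds defined.
#' @return List with `states` (2^N x N 0/1 matrix), `prob` (normalized
#'   probabilities) and `energy`.
#' @export
exact_distribution <- function(model) {
  stopifnot(inherits(model, "coupling_model"))
  n <- nrow(model$weights)
  if (n > 20) stop("exact enumeration is limited to N <= 20")
  if (anyNA(model$thresholds))
    stop("exact_distribution requires all thresholds to be defined")
  S <- enumerate_states(n)
  E <- state_energies(model, S)
  lw <- -E / model$temperature
  p <- exp(lw - max(lw))
  list(states = S, prob = p / sum(p), energy = E)
}

#' Mean-field + linear-response inverse Ising learning
#'
#' Closed-form fixed point of Boltzmann-machine learning without hidden units:
#' over the non-degenerate units,
#' `w_ij = T * (delta_ij / (m_i (1 - m_i)) - (C^-1)_ij)` with the diagonal then
#' forced to zero, and `theta_i = sum_j w_ij m_j - T * log(m_i / (1 - m_i))`.
#' Degenerate units (constant rows in the data) get zero weight rows/columns
#' and an undefined (`NA`) threshold, the finite rendering of an infinite one.
#'
#' @param stats A `moment_stats` object (see [compute_moments()]).
#' @param temperature Positive temperature carried into the weights and the
#'   logit term of the thresholds.
#' @param ridge Optional non-negative ridge `lambda` added to the covariance
#'   diagonal before inversion (default 0; use e.g. `1e-6` for near-singular
#'   covariances from near-duplicate units).
#' @return An object of class `boltzmann_fit`.
#' @export
learn_mf_lr <- function(stats, temperature = 1, ridge = 0) {
  stopifnot(inherits(stats, "moment_stats"), temperature > 0, ridge >= 0)
  m <- stats$means
  n <- length(m)
  excluded <- which(stats$flags != "ok")
  incl <- setdiff(seq_len(n), excluded)
  if (length(incl) < 2) stop("need at least two non-degenerate units")
  C <- stats$covariance[incl, incl, drop = FALSE]
  if (ridge > 0) C <- C + diag(ridge, nrow(C))
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular covariance among non-degenerate units; near-duplicate ",
         "subsystems are a common cause - consider the ridge option ",
         "(e.g. ridge = 1e-6)"))
  mi <- m[incl]
  Wsub <- temperature * (diag(1 / (mi * (1 - mi)), length(incl)) - Cinv)
  diag(Wsub) <- 0
  Wsub <- (Wsub + t(Wsub)) / 2
  W <- matrix(0, n, n)
  W[incl, incl] <- Wsub
  th <- rep(NA_real_, n)
  th[incl] <- drop(Wsub %*% mi) - temperature * log(mi / (1 - mi))
  un <- names(m)
  dimnames(W) <- list(un, un)
  model <- new_coupling_model(W, stats::setNames(th, un), temperature)
  new_boltzmann_fit(model, method = "mflr", excluded = excluded,
                    stats = stats, residuals = NULL, converged = NA)
}

model_moments_exact <- function(model, S = NULL) {
  if (is.null(S)) S <- enumerate_states(nrow(model$weights))
  p <- exact_distribution(model)$prob
  m <- drop(crossprod(S, p))
  S2 <- crossprod(S, S * p)
  list(means = m, second_moments = (S2 + t(S2)) / 2)
}

#' Exact-enumeration Boltzmann machine learning (small-N oracle)
#'
#' Gradient learning of weights and thresholds by moment matching, with the
#' model-side expectations computed exactly over all `2^N` states (guarded at
#' `N <= 15`). Updates are
#' `dw_ij = eta * (<s_i s_j>_data - <s_i s_j>_model)` and
#' `dtheta_i = -eta * (<s_i>_data - <s_i>_model)`, iterated until the largest
#' absolute moment residual drops below `tol` or `max_iter` is reached. At
#' convergence model and data share the same means and pairwise correlations,
#' which is the defining fixed point of the learning rule.
#'
#' @param raster A `binary_raster` or 0/1 matrix (units x time).
#' @param temperature Positive temperature.
#' @param learning_rate Positive step size `eta`.
#' @param max_iter Iteration cap; `0` returns the random initialization with
#'   its residuals.
#' @param tol Convergence tolerance on the maximum absolute moment residual.
#' @param init_sd Standard deviation of the random initialization.
#' @param seed Optional seed for the random initialization.
#' @return An object of class `boltzmann_fit`; `converged` is `FALSE` (with a
#'   warning) if `max_iter` was exhausted.
#' @export
learn_exact <- function(raster, temperature = 1, learning_rate = 0.5,
                        max_iter = 5000L, tol = 1e-3, init_sd = 0.1,
                        seed = NULL) {
  raster <- as_raster(raster)
  stats <- compute_moments(raster)
  n <- length(stats$means)
  if (n > 15) stop("exact learning is limited to N <= 15")
  stopifnot(learning_rate > 0)
  excluded <- which(stats$flags != "ok")
  incl <- setdiff(seq_len(n), excluded)
  ni <- length(incl)
  if (ni < 2) stop("need at least two non-degenerate units")
  if (!is.null(seed)) set.seed(seed)
  Wi <- matrix(stats::rnorm(ni * ni, sd = init_sd), ni)
  Wi <- (Wi + t(Wi)) / 2; diag(Wi) <- 0
  thi <- stats::rnorm(ni, sd = init_sd)
  md <- stats$means[incl]
  S2d <- stats$second_moments[incl, incl, drop = FALSE]
  Senum <- enumerate_states(ni)

  sub <- new_coupling_model(Wi, thi, temperature)
  mm <- model_moments_exact(sub, Senum)
  resid <- function(mm) {
    d2 <- S2d - mm$second_moments; diag(d2) <- 0
    max(max(abs(md - mm$means)), max(abs(d2)))
  }
  r <- resid(mm)
  iter <- 0L
  while (r > tol && iter < max_iter) {
    dW <- S2d - mm$second_moments; diag(dW) <- 0
    Wi <- Wi + learning_rate * dW
    thi <- thi - learning_rate * (md - mm$means)
    sub <- new_coupling_model(Wi, thi, temperature)
    mm <- model_moments_exact(sub, Senum)
    r <- resid(mm)
    iter <- iter + 1L
  }
  converged <- r <= tol
  if (!converged && max_iter > 0)
    warning("exact Boltzmann learning did not converge in ", max_iter,
            " iterations (residual ", signif(r, 3), ")")
  W <- matrix(0, n, n); W[incl, incl] <- Wi
  th <- rep(NA_real_, n); th[incl] <- thi
  un <- names(stats$means)
  dimnames(W) <- list(un, un)
  model <- new_coupling_model(W, stats::setNames(th, un), temperature)
  new_boltzmann_fit(model, method = "exact", excluded = excluded,
                    stats = stats, residuals = r, converged = converged,
                    iterations = iter)
}

#' Mean-field Shannon entropy of the network activity (bits)
#'
#' Under the factorized mean-field distribution the entropy decomposes into a
#' sum of binary entropies of the unit means:
#' `S = sum_i -(m_i log2 m_i + (1 - m_i) log2(1 - m_i))`, with `0 log 0 = 0`.
#' Degenerate (excluded) units contribute nothing. The result does not depend
#' on weights, thresholds or temperature.
#'
#' @param stats A `moment_stats` object or a numeric vector of means in \[0,1\].
#' @param excluded Indices of units to exclude from the sum.
#' @return Entropy in bits, between 0 and the number of included units.
#' @export
#' @examples
#' entropy_mf(rep(0.5, 17))   # 17 bits
#' entropy_mf(rep(0.85, 17))  # about 10.37 bits
entropy_mf <- function(stats, excluded = integer(0)) {
  m <- if (inherits(stats, "moment_stats")) stats$means else as.numeric(stats)
  stopifnot(all(m >= 0 & m <= 1))
  if (length(excluded)) m <- m[-excluded]
  h2 <- function(p) {
    out <- numeric(length(p))
    ok <- p > 0 & p < 1
    out[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
    out
  }
  sum(h2(m))
}

#' Mean-field energy of the network
#'
#' `E = -1/2 sum_{i != j} w_ij m_i m_j + sum_i theta_i m_i` over the included
#' units; the smaller the mean energy, the more stable the network
#' configuration.
#'
#' @param model A `coupling_model`.
#' @param stats A `moment_stats` object or numeric vector of means.
#' @param excluded Indices of units excluded from both sums (degenerate units).
#' @return The mean-field energy (a real number).
#' @export
energy_mf <- function(model, stats, excluded = integer(0)) {
  stopifnot(inherits(model, "coupling_model"))
  m <- if (inherits(stats, "moment_stats")) stats$means else as.numeric(stats)
  n <- nrow(model$weights)
  stopifnot(length(m) == n)
  incl <- setdiff(seq_len(n), excluded)
  if (anyNA(model$thresholds[incl]))
    stop("undefined threshold on an included unit; exclude degenerate units")
  W <- model$weights[incl, incl, drop = FALSE]
  mi <- m[incl]
  -0.5 * drop(mi %*% W %*% mi) + sum(model$thresholds[incl] * mi)
}

#' Summary statistics and normality diagnostics of a weight matrix
#'
#' Statistics over all `N^2` matrix entries (diagonal included, the convention
#' of the printed coupling tables): mean, standard deviation (sample, n-1),
#' minimum, maximum, plus two non-Gaussianity diagnostics -- the excess
#' kurtosis and a normal quantile--quantile deviation score (mean absolute
#' difference between the standardized sorted entries and the corresponding
#' normal quantiles; near 0 for Gaussian data).
#'
#' @param model A `coupling_model` or a numeric matrix.
#' @return A list with `mean`, `sd`, `min`, `max`, `excess_kurtosis` and
#'   `qq_deviation`.
#' @export
weight_distribution_summary <- function(model) {
  W <- if (inherits(model, "coupling_model")) model$weights else as.matrix(model)
  v <- as.numeric(W)
  mu <- mean(v); s <- stats::sd(v)
  if (s > 0) {
    z <- sort((v - mu) / s)
    qq <- mean(abs(z - stats::qnorm(stats::ppoints(length(z)))))
    kur <- mean(((v - mu) / s)^4) - 3
  } else {
    qq <- 0; kur <- NA_real_
  }
  list(mean = mu, sd = s, min = min(v), max = max(v),
       excess_kurtosis = kur, qq_deviation = qq)
}

new_boltzmann_fit <- function(model, method, excluded, stats, residuals,
                              converged, iterations = NA_integer_) {
  structure(list(model = model, method = method,
                 excluded = as.integer(excluded), stats = stats,
                 moment_residuals = residuals, converged = converged,
                 iterations = iterations),
            class = "boltzmann_fit")
}

#' Fit the equivalent Boltzmann model of a binary activity raster
#'
#' The central estimator: from a two-state activity raster it learns the
#' pairwise model (symmetric zero-diagonal weights, thresholds, temperature)
#' whose Boltzmann-Gibbs distribution reproduces the raster's means and
#' pairwise correlations. Two routes are available: the closed-form mean-field
#' + linear-response fixed point (`method = "mflr"`, any N), and exact
#' moment-matching gradient learning with full state enumeration
#' (`method = "exact"`, an oracle for N <= 15). Degenerate (constant) units
#' are excluded from inference and reported with `NA` thresholds.
#'
#' @param x A `binary_raster`, a 0/1 matrix (units x time), or a
#'   `dmn_trajectory` (binarized amplitude series via [binarize()]).
#' @param method `"mflr"` or `"exact"`.
#' @param temperature Positive temperature.
#' @param burn_in Initial columns to discard before computing moments.
#' @param ... Passed on to [learn_mf_lr()] or [learn_exact()].
#' @return An object of class `boltzmann_fit` with components `model` (a
#'   [coupling_model()]), `method`, `excluded`, `stats`, `moment_residuals`,
#'   `converged`.
#' @seealso [summary.boltzmann_fit()], [simulate.boltzmann_fit()],
#'   [read_memories()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(5 * 400, 1, 0.5), 5)
#' fit <- boltzmann_fit(x)
#' summary(fit)
boltzmann_fit <- function(x, method = c("mflr", "exact"), temperature = 1,
                          burn_in = 0L, ...) {
  method <- match.arg(method)
  if (inherits(x, "dmn_trajectory")) x <- binarize(x)
  raster <- as_raster(if (inherits(x, "binary_raster")) x$values else x)
  if (burn_in > 0) raster <- as_raster(
    raster$values[, (burn_in + 1L):ncol(raster$values), drop = FALSE])
  if (method == "mflr") {
    learn_mf_lr(compute_moments(raster), temperature = temperature, ...)
  } else {
    learn_exact(raster, temperature = temperature, ...)
  }
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann fit (", x$method, "), ", nrow(x$model$weights), " units, T = ",
      x$model$temperature, "\n", sep = "")
  if (length(x$excluded))
    cat("  excluded degenerate units: ", paste(x$excluded, collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$moment_residuals))
    cat("  max moment residual: ", signif(x$moment_residuals, 3),
        if (isTRUE(x$converged)) " (converged)" else " (not converged)",
        "\n", sep = "")
  invisible(x)
}

#' Extract weights or thresholds from a Boltzmann fit
#'
#' @param object A `boltzmann_fit`.
#' @param what `"weights"` (matrix) or `"thresholds"` (vector).
#' @param ... Unused.
#' @export
coef.boltzmann_fit <- function(object, what = c("weights", "thresholds"), ...) {
  what <- match.arg(what)
  if (what == "weights") object$model$weights else object$model$thresholds
}

#' Summarize a Boltzmann fit
#'
#' Reports the weight-distribution statistics, the mean-field Shannon entropy
#' of the data means and the mean-field energy of the fitted model (both over
#' the non-degenerate units).
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @export
summary.boltzmann_fit <- function(object, ...) {
  ws <- weight_distribution_summary(object$model)
  out <- list(
    method = object$method,
    n = nrow(object$model$weights),
    excluded = object$excluded,
    weights = ws,
    entropy_bits = entropy_mf(object$stats, excluded = object$excluded),
    energy = energy_mf(object$model, object$stats, excluded = object$excluded),
    temperature = object$model$temperature,
    moment_residuals = object$moment_residuals
  )
  class(out) <- "summary.boltzmann_fit"
  out
}

#' @export
print.summary.boltzmann_fit <- function(x, ...) {
  cat("Equivalent Boltzmann model (", x$method, "), ", x$n, " units, T = ",
      x$temperature, "\n", sep = "")
  if (length(x$excluded))
    cat("  degenerate units excluded: ", paste(x$excluded, collapse = ", "),
        "\n", sep = "")
  w <- x$weights
  cat(sprintf("  weights (all %d entries): mean %.2f, sd %.2f, min %.2f, max %.2f\n",
              x$n^2, w$mean, w$sd, w$min, w$max))
  cat(sprintf("  non-Gaussianity: excess kurtosis %.2f, qq deviation %.3f\n",
              w$excess_kurtosis, w$qq_deviation))
  cat(sprintf("  mean-field entropy: %.2f bits (%.3f bits/unit)\n",
              x$entropy_bits, x$entropy_bits / max(1, x$n - length(x$excluded))))
  cat(sprintf("  mean-field energy:  %.2f\n", x$energy))
  invisible(x)
}

#' Sample activity rasters from a fitted Boltzmann model
#'
#' Draws states from the model's Boltzmann-Gibbs distribution by running
#' Glauber dynamics and recording one state per Monte Carlo step (after a
#' burn-in). Degenerate units are frozen at their constant value.
#'
#' @param object A `boltzmann_fit` or `coupling_model`.
#' @param nsim Number of recorded states (columns).
#' @param seed Optional seed.
#' @param burn_in_mcs Monte Carlo steps discarded before recording.
#' @param ... Unused.
#' @return A `binary_raster` of `nsim` sampled states.
#' @export
simulate.boltzmann_fit <- function(object, nsim = 1000L, seed = NULL,
                                   burn_in_mcs = 100L, ...) {
  frozen_at_1 <- object$stats$flags == "constant-1"
  sample_glauber(object$model, nsim, seed, burn_in_mcs, frozen_at_1)
}

#' @rdname simulate.boltzmann_fit
#' @export
simulate.coupling_model <- function(object, nsim = 1000L, seed = NULL,
                                    burn_in_mcs = 100L, ...) {
  sample_glauber(object, nsim, seed, burn_in_mcs,
                 rep(FALSE, nrow(object$weights)))
}

sample_glauber <- function(model, nsim, seed, burn_in_mcs, frozen_at_1) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(model$weights)
  frozen <- is.na(model$thresholds)
  th <- model$thresholds
  th[frozen] <- 0
  init <- stats::rbinom(n, 1, 0.5)
  init[frozen] <- as.integer(frozen_at_1[frozen])
  W <- model$weights
  chain <- glauber_chain_cpp(W, th, model$temperature, as.integer(init),
                             as.integer(burn_in_mcs + nsim), frozen)
  out <- chain[, (burn_in_mcs + 1L):(burn_in_mcs + nsim), drop = FALSE]
  rownames(out) <- rownames(W)
  as_raster(out)
}

#' Moment residuals of a Boltzmann fit
#'
#' Differences between the data moments and the fitted model's exact moments
#' (enumeration over the non-degenerate units; guarded at 15 included units).
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return List with `means` and `second_moments` residual arrays
#'   (data minus model) over the included units.
#' @export
residuals.boltzmann_fit <- function(object, ...) {
  incl <- setdiff(seq_len(nrow(object$model$weights)), object$excluded)
  if (length(incl) > 15)
    stop("exact moment residuals are limited to 15 included units")
  sub <- new_coupling_model(object$model$weights[incl, incl, drop = FALSE],
                            object$model$thresholds[incl],
                            object$model$temperature)
  mm <- model_moments_exact(sub)
  d2 <- object$stats$second_moments[incl, incl, drop = FALSE] - mm$second_moments
  diag(d2) <- 0
  list(means = object$stats$means[incl] - mm$means, second_moments = d2)
}

#' Conditional activation probabilities given a network state
#'
#' For each unit, the Glauber probability of being active given the rest of
#' the supplied state: `sigma((sum_j w_ij s_j - theta_i) / T)`. Degenerate
#' units get `NA`.
#'
#' @param object A `boltzmann_fit`.
#' @param newdata A 0/1 state vector (or matrix with states in rows).
#' @param ... Unused.
#' @export
predict.boltzmann_fit <- function(object, newdata, ...) {
  model <- object$model
  S <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  stopifnot(ncol(S) == nrow(model$weights))
  H <- S %*% model$weights - matrix(model$thresholds, nrow(S),
                                    ncol(S), byrow = TRUE)
  p <- glauber_probability(H, model$temperature)
  if (nrow(p) == 1) drop(p) else p
}
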