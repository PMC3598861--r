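#' Overlap and distance between a network state and a memory
#'
#' The usual normalized spin overlap,
#' `m = (1/|I|) sum_{i in I} (2 s_i - 1)(2 xi_i - 1)` over the included units
#' `I`; the associated distance is `d = 1 - m`, so `d = 0` at the memory and
#' `d = 2` at its complement.
#'
#' @param state 0/1 vector.
#' @param memory 0/1 vector of the same length.
#' @param included Indices entering the average (default: all units).
#' @return The overlap in \[-1, 1\].
#' @export
#' @examples
#' overlap(c(1, 0, 1, 1), c(1, 0, 1, 0))  # 0.5
overlap <- function(state, memory, included = NULL) {
  stopifnot(length(state) == length(memory))
  if (is.null(included)) included <- seq_along(state)
  if (length(included) == 0) stop("included unit set must be non-empty")
  mean((2 * state[included] - 1) * (2 * memory[included] - 1))
}

frozen_mask <- function(model) is.na(model$thresholds)

#' Run Glauber dynamics on a coupling model
#'
#' Sequential stochastic dynamics: at each elementary step one non-frozen unit
#' is chosen uniformly at random (with replacement) and resampled with the
#' Glauber probability of its local field; one Monte Carlo step (MCS) is N
#' elementary steps. Degenerate units (undefined thresholds) are frozen at
#' their initial value and excluded from the overlap average. One state per
#' MCS is recorded, together with the distance `1 - overlap` to each probe
#' memory.
#'
#' @param model A `coupling_model` (or `boltzmann_fit`).
#' @param initial 0/1 initial state.
#' @param n_mcs Number of Monte Carlo steps (>= 1).
#' @param seed Integer seed (runs are deterministic given it).
#' @param probes Optional memories to track: a `memory_set` or 0/1 matrix
#'   (one memory per row).
#' @param temperature Temperature override (default: the model's).
#' @return A list of class `spin_trajectory`: `states` (N x n_mcs), and
#'   `distances` (n_mcs x p matrix) when probes are given.
#' @export
glauber_run <- function(model, initial, n_mcs, seed = 1L, probes = NULL,
                        temperature = NULL) {
  if (inherits(model, "boltzmann_fit")) model <- model$model
  stopifnot(inherits(model, "coupling_model"), n_mcs >= 1)
  n <- nrow(model$weights)
  stopifnot(length(initial) == n, all(initial %in% c(0, 1)))
  if (is.null(temperature)) temperature <- model$temperature
  frozen <- frozen_mask(model)
  th <- model$thresholds
  th[frozen] <- 0
  set.seed(as.integer(seed))
  states <- glauber_chain_cpp(model$weights, th, temperature,
                              as.integer(initial), as.integer(n_mcs), frozen)
  out <- list(states = states, n_mcs = as.integer(n_mcs),
              temperature = temperature)
  if (!is.null(probes)) {
    P <- if (inherits(probes, "memory_set")) probes$patterns
         else as_pattern_matrix(probes)
    incl <- which(!frozen)
    out$distances <- vapply(seq_len(nrow(P)), function(mu)
      1 - colSums((2 * states[incl, , drop = FALSE] - 1) *
                    (2 * P[mu, incl] - 1)) / length(incl),
      numeric(n_mcs))
  }
  structure(out, class = "spin_trajectory")
}

#' @export
print.spin_trajectory <- function(x, ...) {
  cat("Glauber trajectory: ", nrow(x$states), " units x ", x$n_mcs,
      " MCS, T = ", x$temperature, "\n", sep = "")
  if (!is.null(x$distances))
    cat("  final distance to probes: ",
        paste(round(x$distances[x$n_mcs, ], 3), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Test whether a memory is a local attractor of the dynamics
#'
#' Initializes the network at the candidate memory and lets temperature
#' fluctuations perturb it under Glauber dynamics. Around a local minimum the
#' activity fluctuates but converges back; away from one it escapes
#' permanently. The verdict is `stable` iff the mean distance to the memory
#' after the transient stays below the tolerance.
#'
#' @param model A `coupling_model` or `boltzmann_fit`.
#' @param memory 0/1 vector.
#' @param temperature Fluctuation temperature (default 0.7).
#' @param n_mcs Run length in MCS.
#' @param transient MCS discarded before averaging (default 10 percent).
#' @param tolerance Stability tolerance on the mean distance (default 0.1).
#' @param seed Integer seed.
#' @return A list of class `stability_report` with `mean_distance`, `verdict`,
#'   `transient`, `temperature` and the distance trace.
#' @export
stability_test <- function(model, memory, temperature = 0.7, n_mcs = 500L,
                           transient = NULL, tolerance = 0.1, seed = 1L) {
  if (is.null(transient)) transient <- max(1L, as.integer(0.1 * n_mcs))
  stopifnot(transient < n_mcs)
  tr <- glauber_run(model, initial = memory, n_mcs = n_mcs, seed = seed,
                    probes = matrix(memory, nrow = 1),
                    temperature = temperature)
  d <- tr$distances[, 1]
  md <- mean(d[(transient + 1L):n_mcs])
  structure(list(mean_distance = md,
                 verdict = if (md < tolerance) "stable" else "unstable",
                 transient = transient, temperature = temperature,
                 tolerance = tolerance, distance = d),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability test (T = ", x$temperature, "): ", x$verdict,
      " (mean post-transient distance ", round(x$mean_distance, 4),
      ", tolerance ", x$tolerance, ")\n", sep = "")
  invisible(x)
}

#' Monte-Carlo estimate of the Hopfield storage capacity
#'
#' For each load `alpha`, builds `ceil(alpha * N)` independent equiprobable
#' random binary patterns, encodes them with the 1/N Hebbian rule, and runs
#' zero-temperature asynchronous dynamics from a stored pattern (thresholds
#' `theta_i = (1/2) sum_j w_ij`, the 0/1-spin equivalent of the zero-threshold
#' +-1 network). A run retrieves iff the final overlap with the cued pattern
#' reaches `retrieval_threshold`. The critical load `alpha_c` is the largest
#' load whose retrieval frequency across replicates is at least 0.5.
#'
#' @param n Network size (>= 100 recommended for meaningful estimates).
#' @param loads Increasing numeric vector of loads `alpha = p / N`.
#' @param replicates Independent replicates per load (default 20).
#' @param retrieval_threshold Final-overlap threshold scoring retrieval
#'   (default 0.97).
#' @param n_mcs Monte Carlo step budget per run (default 50; runs stop early
#'   at a fixed point).
#' @param seed Integer seed.
#' @return A list of class `capacity_estimate` with `alpha_c`, and `table`
#'   (load, retrieval frequency).
#' @export
#' @examples
#' \donttest{
#' capacity_estimate(200, c(0.08, 0.14, 0.25), replicates = 5, seed = 1)
#' }
capacity_estimate <- function(n, loads, replicates = 20L,
                              retrieval_threshold = 0.97, n_mcs = 50L,
                              seed = 1L) {
  if (length(loads) == 0) stop("load list must be non-empty")
  stopifnot(all(diff(loads) > 0), n >= 2)
  set.seed(as.integer(seed))
  freq <- numeric(length(loads))
  for (li in seq_along(loads)) {
    p <- as.integer(ceiling(loads[li] * n))
    hits <- 0L
    for (r in seq_len(replicates)) {
      P <- matrix(sample(0:1, p * n, replace = TRUE), nrow = p)
      W <- hebbian_weights(P)
      th <- 0.5 * rowSums(W)
      res <- zero_t_relax_cpp(W, th, P[1L, ], as.integer(n_mcs))
      if (overlap(res$state, P[1L, ]) >= retrieval_threshold) hits <- hits + 1L
    }
    freq[li] <- hits / replicates
  }
  retrieved <- which(freq >= 0.5)
  alpha_c <- if (length(retrieved)) loads[max(retrieved)] else NA_real_
  structure(list(alpha_c = alpha_c, n = n,
                 table = data.frame(load = loads, retrieval_frequency = freq),
                 retrieval_threshold = retrieval_threshold,
                 replicates = replicates),
            class = "capacity_estimate")
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat("Storage-capacity estimate at N = ", x$n, ": alpha_c = ", x$alpha_c,
      "\n", sep = "")
  cat("  (largest load with retrieval frequency >= 0.5 over ", x$replicates,
      " replicates,\n   retrieval = final overlap >= ", x$retrieval_threshold,
      ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
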