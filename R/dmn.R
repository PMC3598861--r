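#' Default piecewise-linear flux-response curves
#'
#' The three response curves map an integrated substrate flux in \[0,1\] to the
#' normalized amplitude, baseline and frequency of a subsystem's oscillatory
#' activity. They are piecewise-linear stand-ins for the glycolytic response
#' shapes of the Goldbeter--Lefever dissipative regime: a bell-shaped amplitude
#' curve (oscillations exist only in an intermediate flux window), a monotone
#' baseline curve (mean activity grows with substrate supply) and a monotone
#' saturating frequency curve. Knots are data, not code: any recovered or
#' alternative curve on \[0,1\] -> \[0,1\] can be substituted.
#'
#' @return A named list with elements `amplitude`, `baseline` and `frequency`,
#'   each a list with numeric vectors `x` and `y` (the knots).
#' @export
#' @examples
#' k <- default_knots()
#' eval_knots(k$amplitude, c(0, 0.5, 1))
default_knots <- function() {
  list(
    amplitude = list(x = c(0, 0.15, 0.5, 0.85, 1), y = c(0, 0.9, 1, 0.9, 0)),
    baseline  = list(x = c(0, 0.5, 1),             y = c(0, 0.6, 1)),
    frequency = list(x = c(0, 0.2, 0.5, 1),        y = c(0, 0.5, 0.85, 1))
  )
}

#' Evaluate a piecewise-linear knot table
#'
#' @param knots A list with numeric vectors `x` (increasing, in \[0,1\]) and `y`.
#' @param x Points at which to evaluate, each in \[0,1\].
#' @return Numeric vector of interpolated values.
#' @export
eval_knots <- function(knots, x) {
  stopifnot(is.list(knots), length(knots$x) == length(knots$y))
  stats::approx(knots$x, knots$y, xout = x, rule = 2)$y
}

clamp01 <- function(x) pmin(1, pmax(0, x))

signal_classes <- c("AC", "IN", "TI")

#' Generate a random dissipative metabolic network
#'
#' Draws a random network of `n` multienzymatic subsystems under the structural
#' constraints of the dissipative-metabolic-network (DMN) model: every
#' subsystem receives between one and three incoming substrate-flux edges
#' (self-loops permitted), exactly three incoming regulatory signals, and the
#' three signal classes -- allosteric activation (`AC`), allosteric inhibition
#' (`IN`) and all-or-nothing covalent modulation (`TI`) -- are balanced across
#' the network. Flux-integration parameters and allosteric regulatory
#' coefficients are drawn uniformly in (0,1); the three flux-integration
#' constants default to 2 and the covalent-modulation threshold to
#' `delta = 0.54`. External stimuli enter as additional constant incoming
#' fluxes and count against the three-flux budget of their target.
#'
#' @param seed Integer seed; identical seeds give identical networks.
#' @param n Number of subsystems (default 18).
#' @param stimuli Named numeric vector of constant external substrate inputs,
#'   names are 1-based subsystem indices (default `c("3" = 0.54, "10" = 0.16)`).
#' @param delta Covalent-modulation threshold in (0,1).
#' @param flux_constants Three positive constants of the flux-integration
#'   functions.
#' @param knots Response curves, see [default_knots()].
#' @return An object of class `dmn_network`.
#' @export
#' @examples
#' net <- generate_network(seed = 7)
#' net
generate_network <- function(seed, n = 18L, stimuli = c("3" = 0.54, "10" = 0.16),
                             delta = 0.54, flux_constants = c(2, 2, 2),
                             knots = default_knots()) {
  n <- as.integer(n)
  if (n < 2L) stop("a DMN needs at least 2 subsystems to place balanced signal classes")
  if (length(stimuli)) {
    targets <- as.integer(names(stimuli))
    if (anyNA(targets) || any(targets < 1L | targets > n))
      stop("stimulus target index out of range 1..", n)
  } else targets <- integer(0)
  stopifnot(delta > 0, delta < 1, length(flux_constants) == 3)

  rs <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))

    # flux topology: each subsystem draws 1..3 incoming fluxes (sources uniform,
    # self-loops allowed); stimulus targets keep room in the 3-flux budget
    budget <- rep(3L, n)
    budget[targets] <- budget[targets] - tabulate(targets, n)[targets]
    if (any(budget < 1L)) stop("stimuli exhaust the three-flux budget of a subsystem")
    indeg <- pmin(sample(1:3, n, replace = TRUE), budget)
    flux_edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(from = sample.int(n, indeg[i], replace = TRUE), to = i)
    }))

    # signal topology: 3 incoming signals per subsystem, classes balanced
    # network-wide; within each target TI is listed (and applied) last so that
    # covalent total inhibition is absolute
    cls <- sample(rep(signal_classes, n))
    signal_edges <- data.frame(
      from  = sample.int(n, 3L * n, replace = TRUE),
      to    = rep(seq_len(n), each = 3L),
      class = cls,
      stringsAsFactors = FALSE
    )
    ord <- order(signal_edges$to, signal_edges$class == "TI")
    signal_edges <- signal_edges[ord, ]
    rownames(signal_edges) <- NULL
    rc <- matrix(stats::runif(3L * n * 3L), ncol = 3,
                 dimnames = list(NULL, c("r1", "r2", "r3")))
    rc[signal_edges$class == "TI", ] <- NA_real_
    signal_edges <- cbind(signal_edges, as.data.frame(rc))

    list(
      flux_edges   = as.data.frame(flux_edges),
      signal_edges = signal_edges,
      flux_params  = matrix(stats::runif(3L * n), ncol = 3,
                            dimnames = list(NULL, c("amplitude", "baseline", "frequency"))),
      init_state   = matrix(stats::runif(3L * n), ncol = 3,
                            dimnames = list(NULL, c("amplitude", "baseline", "frequency")))
    )
  })

  structure(
    c(rs, list(
      n = n, stimuli = stimuli, delta = delta,
      flux_constants = flux_constants, knots = knots, seed = as.integer(seed)
    )),
    class = "dmn_network"
  )
}

#' @export
print.dmn_network <- function(x, ...) {
  cat("Dissipative metabolic network (", x$n, " subsystems, seed ", x$seed, ")\n",
      sep = "")
  cat("  flux edges:   ", nrow(x$flux_edges),
      " (max in-degree ", max(tabulate(x$flux_edges$to, x$n)), ")\n", sep = "")
  cat("  signals:      ", nrow(x$signal_edges), " (",
      paste(names(table(x$signal_edges$class)), table(x$signal_edges$class),
            sep = "=", collapse = ", "), ")\n", sep = "")
  if (length(x$stimuli))
    cat("  stimuli:      ", paste0("MSb", names(x$stimuli), "=", x$stimuli,
                                   collapse = ", "), "\n", sep = "")
  cat("  delta (TI threshold): ", x$delta, "\n", sep = "")
  invisible(x)
}

validate_network <- function(net) {
  stopifnot(inherits(net, "dmn_network"))
  n <- net$n
  indeg_flux <- tabulate(net$flux_edges$to, n)
  stim_load <- tabulate(as.integer(names(net$stimuli)), n)
  if (any(indeg_flux + stim_load > 3L)) stop("flux in-degree exceeds 3")
  if (any(indeg_flux < 1L)) stop("every subsystem must receive at least one flux")
  if (!all(tabulate(net$signal_edges$to, n) == 3L)) stop("each subsystem needs exactly 3 signals")
  cc <- table(net$signal_edges$class)
  if (length(unique(cc)) != 1L) stop("signal classes must be balanced")
  invisible(net)
}

#' Flux integration of incoming substrate fluxes
#'
#' First stage of a subsystem's input-output conversion: the incoming substrate
#' fluxes are converted into an internal activity triple (amplitude, baseline,
#' frequency), each in \[0,1\]. For a single flux `f` each component is the
#' corresponding response curve evaluated at `min(1, c_k * p_k * f)` where
#' `c_k` is the flux-integration constant and `p_k` the subsystem's parameter.
#' When several fluxes arrive, the component-wise arithmetic mean of the
#' per-flux results is taken.
#'
#' @param fluxes Numeric vector of incoming fluxes, each in \[0,1\], non-empty.
#' @param params Numeric length-3 vector of subsystem parameters in (0,1).
#' @param knots Response curves, see [default_knots()].
#' @param constants Three flux-integration constants (default 2).
#' @return Named numeric triple (amplitude, baseline, frequency) in \[0,1\].
#' @export
flux_integrate <- function(fluxes, params, knots = default_knots(),
                           constants = c(2, 2, 2)) {
  if (length(fluxes) == 0) stop("isolated subsystem: no incoming fluxes")
  if (any(fluxes < 0 | fluxes > 1)) stop("fluxes must lie in [0,1]")
  stopifnot(length(params) == 3, length(constants) == 3)
  comp <- vapply(1:3, function(k) {
    mean(eval_knots(knots[[k]], clamp01(constants[k] * params[k] * fluxes)))
  }, numeric(1))
  names(comp) <- c("amplitude", "baseline", "frequency")
  clamp01(comp)
}

#' Sequential regulatory-signal integration
#'
#' Second stage of the input-output conversion: the internal activity triple is
#' modified by the incoming regulatory signals, applied sequentially in list
#' order. An activatory signal (`AC`) moves each component toward 1,
#' `x <- x + r * a * (1 - x)`; an inhibitory signal (`IN`) moves it toward 0,
#' `x <- x * (1 - r * a)`; a covalent-modulation signal (`TI`) fully inhibits
#' the subsystem (returns the zero triple) when the source activity reaches the
#' threshold `delta`, and is transparent otherwise. Here `a` is the source
#' subsystem's activity (its amplitude component) and `r` the per-component
#' regulatory coefficient in (0,1).
#'
#' @param internal Numeric triple in \[0,1\]^3.
#' @param signals A list; each element a list with `class` (one of `"AC"`,
#'   `"IN"`, `"TI"`), `source_activity` in \[0,1\] and `coeff` (length-3 numeric
#'   for AC/IN; ignored for TI).
#' @param delta Covalent-modulation threshold.
#' @return The regulated activity triple in \[0,1\]^3.
#' @export
apply_signals <- function(internal, signals, delta = 0.54) {
  x <- as.numeric(internal)
  stopifnot(length(x) == 3)
  for (sg in signals) {
    if (sg$class == "AC") {
      r <- rep_len(sg$coeff, 3)
      x <- x + r * sg$source_activity * (1 - x)
    } else if (sg$class == "IN") {
      r <- rep_len(sg$coeff, 3)
      x <- x * (1 - r * sg$source_activity)
    } else if (sg$class == "TI") {
      if (sg$source_activity >= delta) x <- c(0, 0, 0)
    } else stop("unknown signal class: ", sg$class)
  }
  names(x) <- c("amplitude", "baseline", "frequency")
  clamp01(x)
}

#' Simulate the deterministic catalytic dynamics of a DMN
#'
#' Iterates the two-stage update (flux integration, then sequential signal
#' integration) for `n_transitions` transition intervals. The substrate flux a
#' source subsystem emits is its baseline component (its mean catalytic level);
#' the strength of an allosteric signal is the source's amplitude component.
#' External stimuli enter every interval as constant additional fluxes. The
#' dynamics is purely deterministic: all randomness lives in network
#' generation.
#'
#' @param net A `dmn_network`.
#' @param n_transitions Number of transition intervals M (>= 1).
#' @return An object of class `dmn_trajectory`: a list with `states` (array
#'   `n x 3 x M`), `n`, and the generating network's seed.
#' @export
#' @examples
#' net <- generate_network(seed = 7, n = 6)
#' traj <- dmn_simulate(net, 50)
#' dim(traj$states)
dmn_simulate <- function(net, n_transitions) {
  validate_network(net)
  M <- as.integer(n_transitions)
  stopifnot(M >= 1L)
  n <- net$n
  state <- net$init_state
  states <- array(NA_real_, dim = c(n, 3L, M),
                  dimnames = list(paste0("MSb", seq_len(n)),
                                  c("amplitude", "baseline", "frequency"), NULL))
  stim_target <- as.integer(names(net$stimuli))
  # per-target structures hoisted out of the time loop
  flux_src <- lapply(seq_len(n), function(i)
    net$flux_edges$from[net$flux_edges$to == i])
  stim_val <- lapply(seq_len(n), function(i)
    unname(net$stimuli[stim_target == i]))
  sig_tmpl <- lapply(seq_len(n), function(i) {
    sgdf <- net$signal_edges[net$signal_edges$to == i, , drop = FALSE]
    list(class = sgdf$class, from = sgdf$from,
         coeff = as.matrix(sgdf[, c("r1", "r2", "r3")]))
  })

  for (m in seq_len(M)) {
    nxt <- state
    for (i in seq_len(n)) {
      fl <- c(state[flux_src[[i]], "baseline"], stim_val[[i]])
      internal <- flux_integrate(fl, net$flux_params[i, ], net$knots,
                                 net$flux_constants)
      sg <- sig_tmpl[[i]]
      signals <- lapply(seq_along(sg$class), function(k)
        list(class = sg$class[k],
             source_activity = state[sg$from[k], "amplitude"],
             coeff = sg$coeff[k, ]))
      nxt[i, ] <- apply_signals(internal, signals, net$delta)
    }
    state <- nxt
    states[, , m] <- state
  }
  structure(list(states = states, n = n, seed = net$seed),
            class = "dmn_trajectory")
}

#' @export
print.dmn_trajectory <- function(x, ...) {
  M <- dim(x$states)[3]
  cat("DMN trajectory: ", x$n, " subsystems x ", M, " transitions\n", sep = "")
  on_frac <- mean(apply(x$states, c(1, 3), function(tr) any(tr > 0)))
  cat("  fraction of active (subsystem, interval) cells: ",
      round(on_frac, 3), "\n", sep = "")
  invisible(x)
}

#' Per-subsystem amplitude series of a trajectory
#'
#' @param traj A `dmn_trajectory`.
#' @return Matrix `n x M` of amplitude components, the series the equivalent
#'   Ising analysis binarizes.
#' @export
amplitude_series <- function(traj) {
  stopifnot(inherits(traj, "dmn_trajectory"))
  traj$states[, "amplitude", ]
}

#' Classify subsystem activity states
#'
#' A subsystem is "on" in an interval iff its triple is not the inactive state
#' (all three components zero). Post burn-in, subsystems on in every interval
#' are `always-on` (metabolic-core candidates), never on are `always-off`, the
#' rest are `on-off`.
#'
#' @param traj A `dmn_trajectory`.
#' @param burn_in Number of initial intervals to discard (must be < M).
#' @return Character vector of labels, one per subsystem.
#' @export
classify_states <- function(traj, burn_in = 1000L) {
  stopifnot(inherits(traj, "dmn_trajectory"))
  M <- dim(traj$states)[3]
  if (burn_in >= M) stop("burn_in must be smaller than the number of intervals")
  keep <- (burn_in + 1L):M
  on <- apply(traj$states[, , keep, drop = FALSE], c(1, 3),
              function(tr) any(tr > 0))
  lab <- ifelse(rowSums(on) == length(keep), "always-on",
                ifelse(rowSums(on) == 0L, "always-off", "on-off"))
  stats::setNames(lab, rownames(traj$states))
}

# harmonics are referenced to the global time origin, so the prolongation of
# one stage and the back-propagation of the next coincide whenever the two
# triples are equal
harmonic_value <- function(triple, t_global, freq_max = 1) {
  clamp01(triple[2] + triple[1] *
            sin(2 * pi * triple[3] * freq_max * t_global))
}

#' Reconstruct continuous activity from a trajectory
#'
#' Within each transition interval the activity is harmonic:
#' `baseline + amplitude * sin(2*pi*frequency*freq_max*t)`, clamped to \[0,1\].
#' Between consecutive intervals a mixed transition regime blends the
#' prolongation of the previous harmonic with the back-propagation of the next
#' one through a linear crossfade `s1(t) * prev + s2(t) * next` with
#' `s1 + s2 = 1`, `s1` falling 1 to 0 across the window.
#'
#' @param traj A `dmn_trajectory`.
#' @param harmonic_duration Duration of each harmonic window (> 0).
#' @param transition_duration Duration of each transition window (> 0).
#' @param sample_rate Samples per unit time (> 0).
#' @param freq_max Frequency scale: cycles per unit time at normalized
#'   frequency 1.
#' @return A list of class `dmn_activity` with `time` (vector) and `values`
#'   (matrix `n x length(time)`).
#' @export
reconstruct_activity <- function(traj, harmonic_duration = 1,
                                 transition_duration = 0.5,
                                 sample_rate = 20, freq_max = 1) {
  stopifnot(inherits(traj, "dmn_trajectory"))
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (harmonic_duration <= 0 || transition_duration <= 0)
    stop("durations must be positive")
  M <- dim(traj$states)[3]
  n <- traj$n
  dt <- 1 / sample_rate
  block <- harmonic_duration + transition_duration
  total <- M * harmonic_duration + (M - 1) * transition_duration
  time <- seq(0, total, by = dt)
  values <- matrix(NA_real_, n, length(time),
                   dimnames = list(rownames(traj$states), NULL))
  m_idx <- pmin(floor(time / block) + 1, M)
  t_in <- time - (m_idx - 1) * block
  for (i in seq_len(n)) {
    v <- numeric(length(time))
    for (s in seq_along(time)) {
      m <- m_idx[s]; tl <- t_in[s]
      cur <- traj$states[i, , m]
      if (tl <= harmonic_duration || m == M) {
        v[s] <- harmonic_value(cur, time[s], freq_max)
      } else {
        u <- (tl - harmonic_duration) / transition_duration
        nxt <- traj$states[i, , m + 1]
        prev_v <- harmonic_value(cur, time[s], freq_max)  # prolonged previous
        next_v <- harmonic_value(nxt, time[s], freq_max)  # back-propagated next
        v[s] <- (1 - u) * prev_v + u * next_v
      }
    }
    values[i, ] <- v
  }
  structure(list(time = time, values = values), class = "dmn_activity")
}
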