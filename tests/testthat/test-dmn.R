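test_that("network generation is deterministic in the seed and respects structure", {
  a <- generate_network(seed = 7)
  b <- generate_network(seed = 7)
  expect_identical(a, b)
  c8 <- generate_network(seed = 8)
  expect_false(identical(a$flux_edges, c8$flux_edges) &&
                 identical(a$flux_params, c8$flux_params))

  for (s in c(1, 5, 9)) {
    net <- generate_network(seed = s, n = 18)
    indeg <- tabulate(net$flux_edges$to, net$n) +
      tabulate(as.integer(names(net$stimuli)), net$n)
    expect_true(all(indeg <= 3))
    expect_true(all(tabulate(net$flux_edges$to, net$n) >= 1))
    expect_true(all(tabulate(net$signal_edges$to, net$n) == 3))
    expect_equal(unname(table(net$signal_edges$class)), rep(18L, 3),
                 ignore_attr = TRUE)
    acin <- net$signal_edges$class != "TI"
    expect_true(all(net$signal_edges[acin, c("r1", "r2", "r3")] > 0 &
                      net$signal_edges[acin, c("r1", "r2", "r3")] < 1))
  }
})

test_that("invalid generation inputs are rejected", {
  expect_error(generate_network(seed = 1, n = 18, stimuli = c("19" = 0.5)),
               "out of range")
  expect_error(generate_network(seed = 1, n = 1), "at least 2")
})

test_that("flux integration averages per-flux responses and stays in [0,1]", {
  p <- c(0.4, 0.6, 0.3)
  one <- flux_integrate(0.5, p)
  expect_equal(flux_integrate(c(0.5, 0.5), p), one)
  expect_equal(flux_integrate(c(0.2, 0.8), p),
               (flux_integrate(0.2, p) + flux_integrate(0.8, p)) / 2)
  # permutation invariance
  expect_equal(flux_integrate(c(0.1, 0.7, 0.4), p),
               flux_integrate(c(0.4, 0.1, 0.7), p))
  # default curves map zero flux to full inactivity
  expect_equal(unname(flux_integrate(0, p)), c(0, 0, 0))
  expect_true(all(flux_integrate(c(0.33, 0.99), p) >= 0 &
                    flux_integrate(c(0.33, 0.99), p) <= 1))
  expect_error(flux_integrate(numeric(0), p), "isolated")
  expect_error(flux_integrate(1.2, p), "\\[0,1\\]")
})

test_that("signal integration is sequential, order-sensitive, and TI dominates", {
  x <- c(0.5, 0.4, 0.6)
  expect_equal(unname(apply_signals(x, list())), x)

  ti_hot <- list(class = "TI", source_activity = 0.60, coeff = NA)
  expect_equal(unname(apply_signals(x, list(ti_hot), delta = 0.54)), c(0, 0, 0))
  ti_cold <- list(class = "TI", source_activity = 0.50, coeff = NA)
  expect_equal(unname(apply_signals(x, list(ti_cold), delta = 0.54)), x)

  ac <- list(class = "AC", source_activity = 0.8, coeff = rep(0.5, 3))
  inh <- list(class = "IN", source_activity = 0.8, coeff = rep(0.5, 3))
  ac_in <- apply_signals(x, list(ac, inh))
  in_ac <- apply_signals(x, list(inh, ac))
  # composed updates evaluated by hand
  manual <- (x + 0.5 * 0.8 * (1 - x)) * (1 - 0.5 * 0.8)
  expect_equal(unname(ac_in), unname(manual))
  expect_false(isTRUE(all.equal(ac_in, in_ac)))

  # TI applied last wins over anything before it
  expect_equal(unname(apply_signals(x, list(ac, inh, ti_hot))), c(0, 0, 0))
  expect_error(apply_signals(x, list(list(class = "XX", source_activity = 0,
                                          coeff = 1))), "unknown signal class")
})

test_that("simulation is deterministic and closed in [0,1]", {
  net <- toy_network(n = 6, seed = 3)
  t1 <- dmn_simulate(net, 80)
  t2 <- dmn_simulate(net, 80)
  expect_identical(t1, t2)
  expect_true(all(t1$states >= 0 & t1$states <= 1))
  expect_equal(dim(t1$states), c(6, 3, 80))
})

test_that("uniform covalent suppression is absorbing", {
  # every subsystem starts at amplitude 1 and receives a TI signal; with
  # delta < 1 the whole network collapses to the inactive state in one
  # transition and stays there (no stimuli feed it back)
  net <- generate_network(seed = 2, n = 3, stimuli = c("1" = 0))
  net$signal_edges$class <- rep(c("AC", "IN", "TI"), 3)
  net$signal_edges$r1 <- net$signal_edges$r2 <- net$signal_edges$r3 <- 0.5
  net$init_state[] <- 1
  traj <- dmn_simulate(net, 5)
  expect_true(all(traj$states == 0))
})

test_that("state classification distinguishes core, intermittent and silent units", {
  states <- array(0, dim = c(3, 3, 6))
  states[1, , ] <- 0.5                       # always active
  states[2, 1, c(4, 6)] <- 0.3               # intermittent after burn-in
  traj <- structure(list(states = states, n = 3, seed = 0),
                    class = "dmn_trajectory")
  expect_equal(unname(classify_states(traj, burn_in = 2)),
               c("always-on", "on-off", "always-off"))
  # forcing the intermittent unit off changes only its label
  states2 <- states; states2[2, , ] <- 0
  traj2 <- structure(list(states = states2, n = 3, seed = 0),
                     class = "dmn_trajectory")
  expect_equal(unname(classify_states(traj2, burn_in = 2)),
               c("always-on", "always-off", "always-off"))
  expect_error(classify_states(traj, burn_in = 6), "burn_in")
})

test_that("continuous reconstruction blends harmonics as specified", {
  # identical consecutive states: transition equals the common harmonic
  st <- array(rep(c(0.2, 0.5, 0.4), each = 1), dim = c(1, 3, 2))
  st[1, , 2] <- st[1, , 1]
  traj <- structure(list(states = st, n = 1, seed = 0),
                    class = "dmn_trajectory")
  act <- reconstruct_activity(traj, harmonic_duration = 1,
                              transition_duration = 1, sample_rate = 8)
  ref <- 0.5 + 0.2 * sin(2 * pi * 0.4 * act$time)
  expect_equal(act$values[1, ], pmin(1, pmax(0, ref)), tolerance = 1e-12)

  # zero amplitude and frequency: constant baseline
  st2 <- array(c(0, 0.7, 0), dim = c(1, 3, 1))
  traj2 <- structure(list(states = st2, n = 1, seed = 0),
                     class = "dmn_trajectory")
  act2 <- reconstruct_activity(traj2, sample_rate = 10)
  expect_true(all(abs(act2$values - 0.7) < 1e-12))

  # linear crossfade between constant levels 0 and 1 passes through 0.5
  st3 <- array(c(0, 0, 0, 0, 1, 0), dim = c(1, 3, 2))
  traj3 <- structure(list(states = st3, n = 1, seed = 0),
                     class = "dmn_trajectory")
  act3 <- reconstruct_activity(traj3, harmonic_duration = 1,
                               transition_duration = 1, sample_rate = 2)
  mid <- which.min(abs(act3$time - 1.5))
  expect_equal(act3$values[1, mid], 0.5)
  # blend conservation: samples stay between the two harmonic envelopes
  expect_true(all(act3$values >= 0 & act3$values <= 1))
  expect_error(reconstruct_activity(traj3, sample_rate = 0), "sample_rate")
})
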