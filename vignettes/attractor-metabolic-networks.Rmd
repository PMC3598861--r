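---
title: "Attractor metabolic networks: models, learning and readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor metabolic networks: models, learning and readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attractornet)
```

This vignette is the package's account of the science it implements: the
dissipative-metabolic-network (DMN) simulator, the equivalent Boltzmann model
and how it is learned, the Hebbian memory readout, and the attractor
validation. It also records the numerical choices and the decisions taken
where the underlying model description left the design genuinely open.

## The dissipative metabolic network

A DMN is an open dynamical system of `n` metabolic subsystems — self-organized
multienzymatic complexes — exchanging two kinds of biochemical messages:
substrate fluxes and regulatory signals. Each subsystem's catalytic activity
is summarized by a normalized triple in $[0,1]^3$: oscillation *amplitude*
$A$, *baseline* $B$ (the mean catalytic level) and *frequency* $F$. A
subsystem is inactive when all three are zero, and in a steady state when the
amplitude or frequency vanishes with positive baseline.

Each transition interval the network is updated deterministically in two
stages per subsystem:

1. **Flux integration.** Incoming substrate fluxes $f \in [0,1]$ are mapped
   through three response curves $\Phi_A, \Phi_B, \Phi_F : [0,1] \to [0,1]$,
   each evaluated at $\min(1,\, c_k\, p_k\, f)$ where $c_k$ (default 2) is a
   network-wide flux-integration constant and $p_k \in (0,1)$ a per-subsystem
   parameter. Several incoming fluxes contribute through the component-wise
   arithmetic mean of their per-flux results, which makes the stage invariant
   under permutation of the flux list.
2. **Signal integration.** The internal triple is then modified by the three
   incoming regulatory signals, applied *sequentially*: activation moves each
   component toward 1 ($x \leftarrow x + r\,a\,(1-x)$), inhibition toward 0
   ($x \leftarrow x\,(1 - r\,a)$), and covalent modulation (`TI`) zeroes the
   whole triple when the source activity reaches the threshold
   $\delta = 0.54$. Here $a$ is the source subsystem's amplitude and
   $r \in (0,1)$ a per-component regulatory coefficient.

The default response curves are piecewise-linear knot tables mimicking the
glycolytic response shapes of the Goldbeter–Lefever dissipative regime: a
bell-shaped amplitude curve (oscillations only in an intermediate flux
window), and monotone baseline and saturating frequency curves. They are data
(`default_knots()`), not code, so alternative curves can be substituted
without touching the simulator. All three map 0 to 0, so a subsystem starved
of substrate falls silent.

**Open choices and how they were fixed.** The algebraic forms of the
flux-integration and allosteric-update maps are not uniquely pinned down by
the model description; the forms above were chosen because they (i) keep
$[0,1]$ closed without clamping, (ii) reduce to the identity when the source
is silent, and (iii) are monotone in the coefficient and the source activity.
The quantity a source *emits* as substrate flux is taken to be its baseline
(its mean catalytic level), while the quantity *sensed* by allosteric signals
is its amplitude — the same functional of activity that the downstream Ising
analysis binarizes. `TI` signals are stored, and applied, last within each
target's signal list, so covalent total inhibition is absolute regardless of
what the allosteric signals did first.

**Random networks.** `generate_network()` draws the topology and parameters
from a seed: one to three incoming flux edges per subsystem (self-loops
allowed), exactly three incoming signals per subsystem with the three classes
balanced network-wide, flux parameters and regulatory coefficients uniform in
$(0,1)$, and random initial activities. External stimuli (defaults: constant
inputs 0.54 to subsystem 3 and 0.16 to subsystem 10) enter as extra incoming
fluxes and count against the three-flux budget. The simulated dynamics after
a 1000-interval burn-in typically shows the systemic metabolic structure of
interest — a few always-active subsystems (the metabolic core), most units
intermittent — but this is configuration-dependent: some seeds settle into a
fixed point where most units are constant, and downstream learning then
(correctly) refuses to fit with fewer than two non-degenerate units.

**What the generator does not emulate.** Real metabolic time series carry
measurement noise, non-stationarity, and far richer within-interval waveform
structure than the harmonic-with-crossfade reconstruction offered by
`reconstruct_activity()`. Passing tests therefore demonstrate correctness of
the machinery on the idealized generative model, not fidelity to any
particular experimental system. Period structure of specific published runs
(which depends on unpublished network parameters) is deliberately not
asserted anywhere.

## Binarization and moments

The equivalent Ising analysis works on the amplitude series. Each unit is
thresholded at one half of its maximum over the whole series (`half-max`,
the default; a `mean` mode is provided because published figures draw the
series mean as the threshold line). An entry is 1 only when the value
*strictly* exceeds the threshold, so ties map to 0. Units whose binarized row
is constant are *degenerate*: they are flagged (`constant-0`/`constant-1`)
but kept, and every downstream consumer decides explicitly — learners exclude
them from inference and report an undefined (`NA`) threshold, the finite-data
rendering of an infinitely large one; entropy and energy sums skip them;
Glauber dynamics freezes them at their constant value and drops them from
overlap averages.

Moments use the $1/T$ normalization, so the second-moment diagonal equals the
means and the covariance diagonal equals $m_i(1-m_i)$ exactly — identities
the tests assert rather than approximate.

## The equivalent Boltzmann model

With binary states, symmetric zero-diagonal couplings, a logistic
input–output rule and sequential updating, the stationary distribution of
Glauber dynamics is the Boltzmann–Gibbs law $p(s) \propto e^{-E(s)/T}$ with

$$E(s) = -\tfrac12 \sum_{i \ne j} w_{ij} s_i s_j + \sum_i \theta_i s_i.$$

The sign convention makes a more positive threshold mean a less excitable
unit. The Boltzmann constant is 1 throughout, so the temperature is
dimensionless.

`boltzmann_fit()` learns $(w, \theta)$ from a raster by either route:

- **`mflr`** — the mean-field + linear-response fixed point, a closed form in
  the data moments (see the README for the formulas). The temperature enters
  linearly in the weights and through a $T$-scaled logit in the thresholds,
  so fits at different temperatures are exact rescalings; $T = 1$ is the
  learning default, and the analysis temperatures $\{0.1, 0.5, 1.0\}$ are
  ordinary arguments. The naive mean-field linear-response form is used; it
  is deliberately kept swappable behind `learn_mf_lr()` should a
  higher-order correction be preferred.
- **`exact`** — gradient moment matching with model expectations computed by
  full state enumeration, guarded at $N \le 15$. This is the package's
  oracle: at convergence (default tolerance $10^{-3}$ on the largest
  absolute moment residual) model and data share means and pairwise
  correlations by construction. Initialization is random
  ($\mathcal{N}(0, 0.1^2)$, seedable); a zero-iteration call returns that
  initialization with its residuals, and exhausting `max_iter` returns the
  current fit with a warning rather than an error.

A singular covariance among non-degenerate units (near-duplicate subsystems
are the common cause in short rasters) raises an error that names the
remediation: an optional ridge $\lambda I$ (off by default; $10^{-6}$ is a
reasonable value when needed, and the pipeline uses $10^{-8}$ routinely since
simulated subsystems can shadow each other exactly).

Mean-field **entropy** is $S = \sum_i H_2(m_i)$ bits over included units,
with $0\log 0 = 0$; it depends only on the means, not on the fitted
parameters or temperature. Mean-field **energy** is
$E = -\tfrac12\sum_{i\ne j} w_{ij} m_i m_j + \sum_i \theta_i m_i$; lower
energy reads as a more stable network configuration. Weight summaries
(`weight_distribution_summary()`) follow the convention of the published
coupling tables: statistics over all $N^2$ entries, diagonal included, with
the sample ($n-1$) standard deviation — the convention that reproduces all
three printed table captions — plus excess kurtosis and a normal
quantile–quantile deviation score as non-Gaussianity diagnostics.

## Hebbian memory readout

The readout asks: which $p$ binary patterns, Hebbian-encoded as
$w^H_{ij} = \tfrac1N \sum_\mu \zeta^\mu_i \zeta^\mu_j$ with
$\zeta = 2\xi - 1$, best explain the learned couplings in least squares
(cost = sum over unordered pairs of squared differences)? The cost is
invariant under complementing any pattern and permuting patterns, so
solutions are canonicalized: each pattern is reported as the representative
of its complement class whose first bit is 0, and patterns are sorted
lexicographically.

- $p = 1$: `exhaustive_lse()` scans all $2^{N-1}$ complement classes
  (guarded at $N \le 22$, evaluated in vectorized chunks via the equivalent
  quadratic-form maximization), with a deterministic lexicographic
  tie-break — a zero matrix returns the all-zeros pattern, always.
- $p \ge 2$: `ga_lse()` runs the documented genetic algorithm — population
  100, 10% elitism (which makes the best-so-far cost non-increasing),
  tournament selection of size 2, single-point crossover applied to each of
  the $p$ vectors, and `max(1, population/10)` point mutations per
  generation, everything deterministic given the seed. The GA is a
  discrete-search heuristic, not a fine optimizer; tests hold it to the
  exhaustive pair minimum as a hard lower bound at small $N$ and to exact
  recovery of planted orthogonal pairs.

The $1/N$ factor in the encoding is itself a convention choice (the model
description leaves it ambiguous); $1/N$ is the standard associative-memory
normalization and is the default. Because learned coupling matrices can be
orders of magnitude larger than $1/N$-scaled Hebbian matrices, the readout
cost is dominated by scale mismatch in absolute terms — this is expected and
harmless, since only the *argmin* over patterns matters.

## Attractor validation and capacity

`glauber_run()` (compiled, incremental-field) implements sequential
stochastic dynamics: per elementary step one non-frozen unit, chosen
uniformly with replacement, is resampled with probability
$\sigma(h_i/T)$; one Monte Carlo step (MCS) is $N$ elementary steps.
`stability_test()` initializes at a candidate memory and averages the
distance $d = 1 - m$ (spin overlap $m \in [-1,1]$) after a transient
(default 10% of the run); the memory is declared stable when the mean
post-transient distance stays below 0.1. Both the tolerance and transient
are configurable since the underlying claim is qualitative
(escapes / does not escape).

**Coupling scale and temperature.** A subtlety worth recording: the 0/1-spin
model at temperature $T$ maps exactly onto the $\pm1$-spin model at
temperature $4T$. Consequently a $1/N$-scaled Hebbian matrix probed at
$T = 0.7$ sits deep in the paramagnetic phase and *no* pattern could be
stable there. Learned coupling matrices are order-1, which is the regime
where $T = 0.7$ produces small fluctuations around a retrieval state. For
planted-pattern stability experiments the package therefore encodes at scale
1 (`hebbian_weights(..., normalize = FALSE)`), keeping the $1/N$ convention
for the readout cost and for capacity, where zero-temperature dynamics are
scale-invariant.

`capacity_estimate()` measures the classical storage capacity: for each load
$\alpha$, encode $\lceil \alpha N \rceil$ independent equiprobable random
patterns with the $1/N$ rule, set thresholds $\theta_i = \tfrac12 \sum_j
w_{ij}$ (the 0/1 equivalent of the zero-threshold $\pm1$ network), start at a
stored pattern and relax under zero-temperature asynchronous updates (ties
keep the current state; early exit at a fixed point). Retrieval means final
overlap $\ge 0.97$; the critical load $\alpha_c$ is the largest with
retrieval frequency $\ge 0.5$. At $N = 500$ this estimator lands slightly
above the asymptotic critical load $\approx 0.138$: the transition is
smeared at finite size, and zero-temperature dynamics started *at* a pattern
freeze into near-pattern remanent states whose overlap exceeds the
equilibrium retrieval overlap. The estimate drifts downward toward the
asymptotic value as $N$ grows; the package reports the honest finite-size
number rather than correcting it.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized so a complete run takes
about a minute on one core: DMN simulations of 18 units for 1400 transitions
(600 for the 12-unit pipeline test), learner cross-checks at $N \le 10$ with
$10^5$ Glauber samples, detailed-balance checks at $N = 5$ against the exact
$2^N$ distribution with total-variation tolerance 0.01, genetic-algorithm
recovery at $N = 12$ with 300 generations and 20 seeds, and capacity at
$N = 500$ with 20 replicates per load. These sizes were chosen as the
smallest at which each property is comfortably outside its own Monte-Carlo
noise.

## Known limitations

- The flux-integration and allosteric functional forms are principled
  stand-ins, exchangeable via knot tables and documented update rules; exact
  reproduction of any specific published run would additionally require that
  run's (unpublished) network parameters.
- The mean-field entropy and energy inherit the factorization assumption;
  strongly coupled networks can have a substantially richer landscape than
  the mean-field summary suggests.
- The exact learner is deliberately capped at $N \le 15$ (enumeration), and
  Monte-Carlo gradient learning at large $N$ is out of scope.
- Memory readout stops at $p = 2$; for larger $p$ the inverse problem is
  increasingly ill-posed and is not attempted.
- Hidden-unit Boltzmann machines and synchronous (parallel) dynamics are out
  of scope.
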