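---
title: "Parallel synapse models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel synapse models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsyn)
```

# The scientific question

Pairs of cortical neurons are often connected by several synapses in
parallel. If all of those contacts had identical, linear transmission, the
duplication would be computationally redundant: a sum of linear functions of
the same input is still linear. But if each synapse applies its own
*nonlinear, monotone* transmission function to the shared presynaptic
activity, the axon's aggregate input-output curve becomes a learnable
nondecreasing function, and a single neuron gains considerable classification
power. This package implements two single-neuron models that make the idea
quantitative, the benchmark protocol that measures their capacity, and a
small feedforward network that reuses the same synapse construction.

# Models

## Restricted neuron

`restricted_neuron()` models a neuron with `N` input axons and a fixed number
`M` of sigmoidal synapses per axon:

$$z(x) = \sum_{i=1}^{N}\sum_{j=1}^{M} a_{ij}^2\,\sigma\!\big(s_{ij}(x_i -
t_{ij})\big), \qquad \hat y = \mathrm{sign}(z - \theta),$$

with amplitude $a_{ij}^2$ (squared so it remains nonnegative), slope
$s_{ij}\ge 0$ (monotone, excitatory transmission; loosely, Dale's law) and
threshold $t_{ij}$. There are no dendritic nonlinearities: currents add
across synapses and axons, and the only interaction between inputs is the
somatic threshold. Training minimises the margin hinge loss

$$L = \sum_{\mu} \max\{0,\ \epsilon - (z_\mu - \theta)\,y_\mu\}, \qquad
\epsilon = 0.1,$$

by synchronous full-batch gradient steps restricted to the *violation set*
$\Omega = \{\mu : \epsilon - (z_\mu-\theta)y_\mu > 0\}$ — the patterns that
are misclassified or correct by less than the margin. All gradients are
evaluated at the pre-update parameters, and the slope is projected back to
$s \ge 0$ after each step.

Internally the optimisation runs in an equivalent zero-centred
parameterization, $h(x) = a'^2\tanh(s'(x-t'))$, which makes the somatic
threshold easier to learn because the synaptic outputs are centred on zero.
Since $\tanh(u) = 2\sigma(2u)-1$, the forms are related by $a^2 = 2a'^2$,
$s = 2s'$, $t = t'$ and $\theta = \theta' + \sum_{ij} a'^2_{ij}$;
`as_sigmoid_form()` applies the map exactly and the test suite checks that
the decision function is preserved to $10^{-10}$.

**Dead-synapse resurrection.** Because every gradient of a synapse carries a
factor of its amplitude (or its square), a synapse whose amplitude collapses
stops learning permanently. Periodically (every `resurrect_every` epochs,
default 100 for interactive fits, 500 in the capacity protocol), any synapse
with $a^2$ below 0.01 has its amplitude raised to exactly 0.01 and its
threshold redrawn from an edge-weighted distribution — an equal mixture of
Beta(0.5, 3) and Beta(3, 0.5), U-shaped on $[0,1]$, mimicking where learned
thresholds concentrate. The floor and the mixture shapes are configurable;
the sign of $a$ is unidentifiable in $a^2$, so resurrection sets
$a = +\sqrt{0.01}$.

**Optimisation: a deliberate design choice.** The update rules above define
the exact hinge gradient restricted to the violation set, and
`gradient_step()` applies them literally (`optimizer = "gd"`); a
finite-difference oracle in the test suite verifies them to a relative
$10^{-4}$. For *measuring capacity*, however, fixed-rate full-batch descent
is impractical: the slope and threshold gradients carry an $a^2$ prefactor,
so with any fixed rates the dynamics linger in a quasi-linear regime whose
error plateau matches the best monotone-linear classifier (we verified this
plateau over a wide sweep of rates, initialisations, schedules and
resurrection cadences, with runs up to $1.5\times 10^5$ epochs). The
default trainer therefore applies the same summed hinge gradient through
adaptive per-parameter moment scaling (`optimizer = "adam"`, rate 0.01,
second-moment decay 0.99), which equalises the effective step across the
wildly different parameter scales and reaches zero training error well
beyond the quasi-linear plateau. Both optimisers share the violation set,
the synchronous update, the $s \ge 0$ projection and the resurrection rule.

**Initialisation** (a free design choice, fixed once):
$a \sim \mathcal N(0, 0.3)$, $s' = 5$ ($s' = 20$ in the capacity protocol),
$t \sim \mathcal U(0,1)$, $\theta' = 0$. Converged solutions are strongly bimodal — about half the
synapses end up with negligible amplitude, while the effective ones acquire
amplitudes of order 0.1–1 and slopes of order 20–100 — so the initial slope
mainly sets how long the sharpening phase takes.

## Unrestricted neuron

`unrestricted_neuron()` is the limiting model in which each axon may form
arbitrarily many synapses. On a dataset of size $P$, each axon's aggregate
transmission function is then an arbitrary nondecreasing staircase taking at
most $P$ values $I_1 \le \dots \le I_P$ (indexed in the axon's input order,
$I_1 = 0$ without loss of generality, step sizes $\rho_\beta^2 \ge 0$). For
fixed per-pattern importance weights $w$, each axon solves independently

$$\min_I\; -\sum_\alpha y_\alpha w_\alpha I_\alpha +
\lambda \sum_\alpha I_\alpha^2
\quad\text{s.t.}\quad 0 = I_1 \le I_2 \le \dots \le I_P,$$

where $\lambda$ discourages unrealistically large somatic currents.
`envelope_solve()` computes the exact minimiser by a convex-envelope
construction: treat $y_\alpha w_\alpha$ as the increments of a random walk,
plot its cumulative sums against the index, and take the greatest convex
minorant; the staircase value on each segment is the segment's slope divided
by $2\lambda$, clipped below at zero, and steps occur exactly where the
minorant touches the walk. Stationarity of the objective on an active
segment $(\beta_1, \beta_2]$ requires
$I = \frac{1}{2\lambda(\beta_2-\beta_1)}\sum_{\alpha=\beta_1+1}^{\beta_2}
y_\alpha w_\alpha$ — precisely the chord slope — and monotonicity forces the
chord slopes to be nondecreasing, which is the convex-minorant property.
The same solution equals the nonnegative isotonic regression of
$y_\alpha w_\alpha / 2\lambda$ with the first value pinned to zero; the test
suite cross-checks against an independent pool-adjacent-violators route and
against brute-force enumeration of all step partitions for $P \le 12$.

The outer loop is importance reweighting: solve all axons, predict
$\hat y_\mu = \mathrm{sign}(\sum_i I_i(x_{i,\mu}) - \theta)$, add 1 to the
weight of every misclassified pattern, and repeat until all patterns are
correct or `max_iter` is reached.

Conventions this implementation fixes, where the model itself does not
dictate one:

* **Somatic threshold.** The per-axon objective determines the staircases
  but not $\theta$. After each envelope pass we set $\theta$ to the midpoint of the
  best single split of the total currents (minimum training errors, ties
  resolved toward fewer false positives) — an exact $O(P\log P)$ scan that
  can only help the loop's stated goal.
* **Tied inputs.** Ties on one axon are merged into a single knot carrying
  the summed label weight and a multiplicity in the regulariser; ties are
  measure-zero under the benchmark's continuous inputs but occur in
  fixtures.
* **Off-knot evaluation** (held-out data only): right-continuous,
  left-constant extension, zero below the first knot.
* **Regularisation.** $\lambda = 1/(2P)$ by default so staircase values are
  order one; the solution depends on $\lambda$ only through an overall scale
  of $I$ (jointly with $w$), so the classification outcome is insensitive to
  it.
* **Effective synapses.** A step counts as an effective synapse when it
  exceeds 1/1000 of the *neuron-wide* maximum step size, strictly. A lone
  positive step is therefore always effective, and an all-flat neuron has
  zero effective synapses.

## Capacity protocol

A model's classification capacity is measured on random patterns: inputs
i.i.d. $\mathcal U(0,1)$, labels $\pm 1$ with equal probability; a trial is
a *success* when the trained model classifies every pattern of its dataset
correctly (margin violations with the correct sign still count as success).
For each problem size $P$ the protocol runs independent trials with derived,
recorded seeds; `fit_capacity()` fits a two-parameter logistic model of the
per-trial Bernoulli outcomes against the load $P/N$ by maximum likelihood
and reads the capacity $P^*/N$ off the 50% crossing; the confidence interval
is a nonparametric bootstrap (resampling trials with replacement within each
$P$ stratum, 100 resamples, 2.5–97.5 percentiles). When no grid is given,
`estimate_capacity()` brackets the transition by a doubling scan with probe
trials, tightens it by bisection, and runs a 5-point grid across the
bracket; probe trials are retained in the logistic fit, where they anchor
the tails.

The perceptron baseline needs no training: a pattern set is a success iff
it is linearly separable, decided exactly by a margin-1 feasibility QP
(`linearly_separable()`), with a bias term to match the neuron models'
somatic threshold (effective dimension $N+1$). `cover_fraction()` supplies
the closed-form counting probability, $2^{1-P}\sum_{k<D}\binom{P-1}{k}$,
exactly $1/2$ at $P = 2D$.

**Problem sizes used in the automated runs.** The test suite and the
acceptance script use desk-scale conditions: perceptron capacity at
$N = 50$ (20 trials per grid point), restricted capacity at $N = 100$,
$M = 2$ on the grid $P = 300, 350, \dots, 500$ with 3 trials per point, and
property checks at $N \le 20$. Larger sweeps (hundreds of axons, five or
more trials per point) use the same functions with larger arguments.

**What the trained-capacity numbers mean.** For the restricted model the
measured $P^*/N$ is a property of model *plus training configuration*.
Two configuration choices matter far more than the rest: the adaptive
optimiser (without it, fixed-rate descent never leaves the quasi-linear
plateau near $P^*/N \approx 2$), and a steep initial slope.
`restricted_capacity_control()` initialises $s' = 20$: converged solutions
are near-staircase (effective slopes of order 20–100), and starting steep
removes a long sharpening phase during which fixed thresholds act like a
frozen random feature bank. With that configuration the 50% crossing at
$N = 100$, $M = 2$ sits near $P^*/N \approx 5.5$–$6$ under the 60000-epoch
budget. The unrestricted model, whose per-axon subproblem is solved
exactly, reaches its ceiling (about 7–8 at $N = 100$) without tuning; the
dominance test (unrestricted at least as good as restricted $M=2$ on a
shared grid) confirms the representational ordering at small $N$.

## Network layer

`network_spec()` / `train_network()` embed the same synapse construction in
a two-layer network: linear input-to-hidden synapses, batch normalization of
the hidden pre-activations, Softplus hidden nonlinearity, and
hidden-to-output connections that are either `M` parallel sigmoidal synapses
per pair (aggregate nondecreasing, slopes projected to $s\ge 0$ every step)
or single nonnegative linear weights (the equal-parameter comparison
network, projected to $W \ge 0$). The learnable-parameter count is
$(D_\mathrm{in}+1)D_\mathrm{hidden} + (3M\,D_\mathrm{hidden}+1)D_\mathrm{out}$
for the parallel network and
$(D_\mathrm{in}+1)D_\mathrm{hidden} + (D_\mathrm{hidden}+1)D_\mathrm{out}$
for the linear one; batch-normalization scale/shift parameters are reported
separately (`include_norm = TRUE`) since the convention above excludes them.
Training uses softmax cross-entropy and adaptive-moment minibatch descent
(rate $10^{-3}$, batch 128 — conventional choices). The bundled `synthetic_digits()`
fixture provides tiny two-class images that are linearly separable in
expectation; it exercises the training loop and the monotonicity
projections, and says nothing about natural-image performance.

# What the synthetic benchmark does and does not show

The random-pattern ensemble is the standard capacity benchmark precisely
because it has no structure: i.i.d. uniform inputs, labels independent of
inputs. Passing tests on it demonstrates storage capacity, determinism and
the correctness of the optimisation machinery. It does not demonstrate
generalization (every pattern is memorised), robustness to correlated or
heavy-tailed inputs, or anything about temporal structure — real synaptic
transmission is dynamic, while these models are static rate maps.

# Numerical choices

* Tie rule: `sign(0)` predicts $-1$, consistently across all models.
* The envelope construction runs on exact cumulative sums with a final
  `cummax` guard against roundoff-level inversions; its stationarity
  residual on active steps is checked to $10^{-8}$ in the tests.
* `cover_fraction()` uses exact double-precision binomial sums where they
  are representable, the binomial half-sum identity at $P = 2D$, and
  log-space summation beyond.
* Pattern CSV files and neuron JSON files are written with 17 significant
  digits, which round-trips IEEE doubles exactly.
* Seeds: every public entry point takes an explicit seed and restores the
  caller's RNG state; capacity trials derive per-trial seeds from the base
  seed and record them, so any trial can be replayed in isolation.

# Known limitations

* The restricted-model capacity depends on the training budget; the
  reported numbers are lower bounds on what the architecture can store.
* The staircase model's biological interpretation (up to one synapse per
  data point) is a mathematical idealisation.
* The network module is a reference implementation in plain R; it is meant
  for small structured tasks and parameter accounting, not for large image
  benchmarks.
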