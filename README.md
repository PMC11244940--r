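# parsyn

Single-neuron models with **nonlinear parallel synapses** and the protocol
for measuring their classification capacity.

Cortical neurons frequently contact the same postsynaptic cell through
several synapses in parallel. If each contact applies its own monotone
sigmoidal transmission function to the shared axonal input, the axon's
aggregate input–output curve becomes a learnable nondecreasing function —
and a single neuron can store far more random input–label associations than
a perceptron. `parsyn` implements:

* **`restricted_neuron(x, y, M)`** — a neuron with `M` sigmoidal synapses
  per axon,
  `z = Σᵢⱼ aᵢⱼ² σ(sᵢⱼ(xᵢ − tᵢⱼ))`, `ŷ = sign(z − θ)`, trained by full-batch
  hinge-loss gradient descent (margin ε = 0.1) on the violation set, with
  periodic resurrection of dead synapses (amplitude floored at 0.01,
  threshold redrawn from an edge-weighted distribution).
* **`unrestricted_neuron(x, y)`** — the unlimited-synapse limit: each
  axon's aggregate function is a monotone staircase `I₁ = 0 ≤ I₂ ≤ …`,
  fitted *exactly* per axon by the convex-envelope solver
  `envelope_solve()` (greatest convex minorant of the cumulative
  label-weight walk) inside an importance-reweighting loop
  (`w ← w + 1` for misclassified patterns).
* **`estimate_capacity(model, N, M)`** — the random-pattern benchmark:
  inputs i.i.d. U(0,1), labels ±1; success = all patterns correct; logistic
  interpolation of the load `P/N` at 50% success gives the capacity `P*/N`,
  with a stratified bootstrap confidence interval.
* **`cover_fraction(P, D)`**, **`linearly_separable(x, y)`** — the exact
  perceptron baseline (Cover's counting formula; hard-margin feasibility
  QP), anchoring `P*/N → 2`.
* **`network_spec()` / `train_network()`** — a two-layer network whose
  hidden-to-output connections are monotone parallel synapses, with exact
  parameter accounting
  `(Dᵢₙ+1)Dₕ + (3M·Dₕ+1)Dₒᵤₜ`.

Fitted models are classed S3 objects with `print`, `summary`, `coef`,
`predict`, `plot` and `residuals` methods. A thin command-line front end
lives at `inst/cli/parsyn` (subcommands `generate`, `train-restricted`,
`train-unrestricted`, `capacity`).

## Worked example

```r
library(parsyn)

ps  <- pattern_fixture("xor4")          # 4 points, labels (+1,-1,-1,+1)
linearly_separable(ps)                  # FALSE: a perceptron must fail

fit <- restricted_neuron(ps, M = 2)     # two sigmoidal synapses per axon
fit$fit$converged                       # TRUE
predict(fit, ps$x)                      #  1 -1 -1  1

un <- unrestricted_neuron(ps)           # staircase model, exact per-axon solver
un
#> Unrestricted parallel-synapse neuron: N = 2 axons, trained on P = 4 patterns
#>   all patterns classified after 1 reweighting iterations (0 training errors); lambda = 0.125
#>   effective synapses per axon: median 1.0 (max 1)

cap <- estimate_capacity("perceptron", N = 20, trials_per_P = 10,
                         n_bootstrap = 30, seed = 1)
cap
#> Classification capacity (perceptron model, N = 20)
#>   P*/N = 2.122  [2.057, 2.195] (30-resample bootstrap, 95%)
#>   70 trials over 7 problem sizes, loads 1.00-4.00
```

The perceptron estimate sits near the finite-size value `2(N+1)/N = 2.1`;
the parallel-synapse models clear it by a wide margin (see the vignette for
what the trained-capacity numbers do and do not mean).

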