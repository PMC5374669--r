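# fgtails

Significance evaluation for additive scores on discrete, tree-structured
factor graphs.

## The problem

Many bioinformatics models — position weight matrices, higher-order Markov
motif models, Poisson-binomial mutation counts, phylogenetic substitution
models — are discrete factor graphs: a joint distribution

P(x) ∝ ∏<sub>a</sub> f<sub>a</sub>(x<sub>a</sub>)

over variables with finite state spaces, factored into potential tables on a
cycle-free bipartite graph. Signals are scored additively,

S(x) = Σ<sub>a</sub> g<sub>a</sub>(x<sub>a</sub>),

and the question that matters for genome-scale multiple testing is the tail
probability **z = P(S > t)** under the null model. Interesting hits have
z ≈ 10⁻⁶ or far smaller, so an estimator needs small *relative* — not
absolute — error deep in the tail. Exact computation is NP-hard even for
fully independent variables, so `fgtails` provides four complementary
estimators plus exact oracles for validating them:

* **Naive sampling** — forward sampling from the graph; unbiased, but the
  relative error diverges in the tail.
* **Importance sampling (IS)** — sampling from the exponentially tilted
  graph f̃<sub>a,α</sub> = f<sub>a</sub>·exp(α g<sub>a</sub>), which is again
  a factor graph with the same structure; weights
  w = exp(κ(α) − α S(x)) are exact. With the saddlepoint-guided choice
  α = θ(t) (**SG-IS**) the proposal's mean score sits exactly at the
  threshold.
* **Normal approximation** — moment matching with the exact mean κ′(0) and
  variance κ″(0); cheap, poor in the tail.
* **Saddlepoint approximation (SA)** — solve κ′(θ) = t by Newton-Raphson,
  then P(S > t) ≈ exp(κ(θ) − tθ + θ²v/2)·Φ̄(θ√v) with v = κ″(θ), optionally
  times the lattice correction K(θ, a) = a|θ|/(1 − e^(−a|θ|)) for scores on
  an arithmetic lattice.

The enabling machinery is a **moment-semiring extension of the sum-product
algorithm**: messages carry (mass, first score moment, second score moment)
triples, so the cumulant generating function κ(θ) = log E[e^{θS}] and its
first two derivatives are computed *exactly* in one leaf-to-root pass, for
any tree factor graph, at any θ. Everything runs in log space, so graphs
with 10⁵ factors and potentials spanning hundreds of orders of magnitude do
not underflow.

Model builders translate four standard applications into (graph, score)
pairs: `poissonBinomialModel()`, `pwmModel()` (JASPAR PFMs),
`markovModel()` (order-r chains made tree-structured by compounding
variables), and `phyloModel()` (Jukes-Cantor conservation scoring, where the
per-branch score table is the conditional expected number of substitutions
given the branch endpoints and the statistic of record is its posterior
expectation given an alignment column — evaluated by latent-variable IS).

## Worked example

How surprising are 18 or more successes out of 30 trials with success
probability 0.2 (exact tail 1.84 × 10⁻⁶)?

```r
library(fgtails)
m <- poissonBinomialModel(rep(0.2, 30))

saddlepointTail(modelGraph(m), modelScore(m), 17.5, lattice = 1)
#> TailEstimate [saddlepoint]: P = 1.81347e-06 (log -13.2203) at t = 17.5
#>   tilting parameter = 1.79176
#>   flags: lattice_corrected

importanceSampleTail(modelGraph(m), modelScore(m), 17.5, n = 10000, seed = 1)
#> TailEstimate [importance]: P = 1.8362e-06 (log -13.2078) at t = 17.5
#>   se = 3.71e-08, 95% CI [1.76344e-06, 1.90896e-06]
#>   tilting parameter = 1.72277

normalTail(modelGraph(m), modelScore(m), 17.5)
#> TailEstimate [normal]: P = 7.64603e-08 (log -16.3865) at t = 17.5
```

The saddlepoint estimate is within 1.6 % of the exact tail and SG-IS brackets
it with a 2 % relative standard error from 10⁴ samples — naive sampling at
the same budget sees zero exceedances. The normal approximation is off by a
factor of 24: exactly the regime it should not be trusted in. The tilting
parameter reported by both methods is the saddlepoint θ(17.5): IS sampled
from the graph tilted so that its mean score is the threshold.

A command-line interface wraps the same functions
(`exec/fgtails pb|pwm|markov|phylo|pvalue|sample`); run it without arguments
for usage.

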