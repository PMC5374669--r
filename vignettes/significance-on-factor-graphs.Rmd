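---
title: "Methods: tail probabilities for additive scores on factor graphs"
author: "fgtails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tail probabilities for additive scores on factor graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgtails)
```

## The model and its assumptions

`fgtails` works with discrete factor graphs: variables $x_1,\dots,x_n$ with
finite state spaces and non-negative potential tables $f_a(x_a)$ on the
factors $a$ of a bipartite graph, inducing
$P(x) \propto \prod_a f_a(x_a)$ with partition function
$Z = \sum_x \prod_a f_a(x_a)$. Two structural assumptions are load-bearing
and enforced by the `FactorGraph` validity method:

* **Cycle-free.** Exact message passing requires a tree (or forest).
  Cyclic models must be restructured first — the order-$r$ Markov builder
  shows the standard trick, compounding $r$ consecutive symbols into one
  variable so the chain becomes first-order and tree-structured.
* **Finite state spaces.** Continuous variables are out of scope;
  discretize before building the graph.

Graphs may be unnormalized ($Z \ne 1$); every probabilistic quantity is
defined relative to $Z$. Scores are additive, $S(x) = \sum_a g_a(x_a)$, with
one score table per factor, shaped like its potential. Two canonical scores
are provided: the negative log-likelihood $g_a = -\log f_a$ and the
foreground/background log-odds $g_a = \log(f^{fg}_a / f^{bg}_a)$. A `-Inf`
score entry is legal (a state the foreground excludes); `+Inf` is only legal
on states with zero potential, so $S$ is never $+\infty$ with positive
probability.

## Exact cumulants by moment-semiring message passing

All four estimators are driven by the cumulant generating function
$\kappa(\theta) = \log E[e^{\theta S}]$ and its derivatives
$\kappa'(\theta) = E_\theta[S]$ and $\kappa''(\theta) = V_\theta[S]$, the
mean and variance under the exponentially tilted measure. On a tree these
are computed *exactly* in one leaf-to-root sweep of messages that carry a
triple per variable state: the tilted mass $z$, the conditional mean part
$\mu$ (first moment of the subtree score over mass) and the second-moment
part $q$. Combining independent subtrees multiplies triples:

$$ (z_1,\mu_1,q_1) \otimes (z_2,\mu_2,q_2)
   = (z_1 z_2,\; \mu_1 + \mu_2,\; q_1 + 2\mu_1\mu_2 + q_2), $$

each factor contributes $(f_a e^{\theta g_a},\, g_a,\, g_a^2)$ per joint
state, and summing out states is mass-weighted averaging of the parts. At
the root, $\kappa(\theta) = \log \tilde Z(\theta) - \log Z$,
$\kappa' = \mu$, $\kappa'' = q - \mu^2$. The representation is scaled:
masses are stored as logs and parts as conditional averages, so no
intermediate ever overflows even when $|\theta|\,|S|$ is in the hundreds.
The test suite checks this machinery against an independent oracle —
direct summation over exhaustively enumerated configurations — to $10^{-8}$
relative on fifty random tree models, along with centered finite
differences of $\kappa$.

## The four estimators

**Normal approximation.** $P(S>t) \approx \bar\Phi\!\big((t - \kappa'(0)) /
\sqrt{\kappa''(0)}\big)$. The standardization uses the standard deviation
$\sqrt{\kappa''(0)}$ — this is the only internally consistent reading, since
the saddlepoint derivation approximates the tilted density with a normal of
variance $\kappa''$.

**Saddlepoint approximation.** Solve $\kappa'(\theta) = t$ (safeguarded
Newton with bracketing, tolerance $|\kappa'(\theta)-t| \le
10^{-9}\max(1,|t|)$, warm-startable for threshold scans), then

$$ P(S > t) \approx e^{\kappa(\theta) - t\theta + \theta^2 v/2}\,
   \bar\Phi(\theta\sqrt{v}), \qquad v = \kappa''(\theta), $$

assembled in log space (`pnorm(..., log.p = TRUE)`) so the product of a huge
exponential and a tiny tail never overflows. The equation has no solution
outside the exact score range, which is computed by min-/max-sum message
passing and checked first. A negative $\theta$ (threshold below the mean) is
returned with a warning flag rather than refused, and estimates above 0.1
are flagged as outside the approximation's intended regime.

**Lattice scores.** When the score support lies on an arithmetic lattice
with spacing $a$ (unit-weight counts being the common case), the strict
tail $P(S>t)$ equals the survivor function at the smallest lattice point
$t^+$ above $t$. Summing the tilted measure over lattice points instead of
integrating yields precisely the correction factor
$K(\theta,a) = a|\theta| / (1 - e^{-a|\theta|}) \ge 1$, so the package
evaluates $K \cdot \mathrm{SA}(t^+)$, anchoring the lattice at the score
minimum. On Binomial(1000, 0.01) this convention agrees with the exact tail
to about 0.1% down to $p = 10^{-20}$, whereas the uncorrected formula at
integer thresholds is low by a factor $e^{\theta}$-ish and midpoint
evaluation is 5–13% off. The spacing is **never auto-detected** (pairwise
gcds of float scores are unreliable); the caller declares it, and the
default is off.

**Sampling.** Forward sampling draws exact configurations root-to-leaves
from the upward messages, grouping the $n$ draws by the conditioning state
so the cost is linear in $n$. Importance sampling samples the tilted graph
$\tilde f_{a,\alpha} = f_a e^{\alpha g_a}$ and weights by
$w = e^{\kappa(\alpha) - \alpha S(x)}$ — exact, including unnormalized
graphs, because $\kappa$ absorbs $\log\tilde Z(\alpha) - \log Z$.
$\alpha = 0$ *is* naive sampling. The default $\alpha$ is the saddlepoint
$\theta(t)$ (SG-IS), which places the proposal's mean score at the
threshold; the classic untuned values (0.5, 1.5) remain available. The
standard error is the sample standard deviation of $w\,\mathbb 1(s>t)$ over
$\sqrt n$, with a normal-theory 95% interval truncated to $[0,1]$ — the
same construction used for the confidence bands in the replication tests.

**Latent-variable statistics.** When the statistic is a function of the
observed margin only — the phylogenetic conservation statistic is the
posterior expected substitution load given the leaves — it is not additive
and the saddlepoint machinery does not apply. IS still does: full
configurations are drawn from the tilted graph, the statistic is evaluated
on each sample's observed margin, and the full-data weights keep the
estimate unbiased (`latentStatisticTail()`). Lower tails (conservation)
negate score and threshold, preserving strictness.

## Tunable parameters

| parameter | where | default | rationale |
|---|---|---|---|
| `alpha` | IS | SG: $\theta(t)$ | proposal mean = threshold; the efficient tilt |
| `n` | sampling | 10 000 | $\sim$2% relative SE at SG-IS for $p\approx10^{-6}$ |
| `lattice` | SA | off | spacing is a modelling statement, not detectable |
| `tol`, `maxIter` | Newton | $10^{-9}\max(1,|t|)$, 100 | far below any approximation error |
| `pseudocount` | `pwmModel` | 0.01 per count cell | JASPAR PFMs contain zeros; value is a convention |
| `muTotal` | `phyloModel` | 1 | branch lengths already in expected substitutions/site |
| `mergeTol` | convolution oracle | $10^{-12}$ | merge float support without visible distortion |

The CLI defaults to the saddlepoint method for small threshold sets and to
IS for 40 or more thresholds: one saddlepoint evaluation costs about as much
as a small batch of importance samples, and a single IS batch serves many
thresholds of similar magnitude.

## Synthetic data: what the generators emulate

All test inputs are generated in code from seeds; none are measured data.

* `randomTreeFixture()` — random tree topologies, gamma potentials, normal
  scores; the enumeration-oracle workhorse (3–8 variables, 2–4 states, so
  exhaustive enumeration stays instant).
* `balancedTreeFixture()` — balanced trees whose edges share one doubly
  stochastic channel $(1-c)/k + c\,\mathbb I$ and (optionally) one score
  table, so every factor contribution has the same marginal law while the
  coupling $c$ tunes dependence, measured by the variance ratio
  $VR = V[S] / \sum_a V[g_a(X_a)]$. With `sharedScores = FALSE` each edge
  draws its own table from the same normal family, making the total score
  quasi-continuous — that variant backs the quantile-stability study,
  run on degree-1 trees (chains) of ten 4-state variables because only
  there do $10^{-8}$ quantiles sit in the smooth part of an enumerable
  distribution rather than on the discrete extreme atoms.
* `syntheticPfm()` — moderately informative motif columns (gamma draws with
  a floor). Strongly single-base-preferring columns are deliberately *not*
  the default: they make the score distribution effectively discrete, which
  is the documented failure mode of the saddlepoint approximation, and the
  package's accuracy claims are scoped to typical informative motifs.
* `syntheticMarkovMotif()` — inhomogeneous order-2 foreground over a
  homogeneous near-uniform order-2 background whose initial distribution is
  its stationary tuple law, so every window of a longer background sequence
  shares the single-match null distribution — the property the Poisson
  scan-maximum approximation $1 - e^{-Mp}$ relies on.
* The 11-leaf Newick fixture (`inst/extdata/balanced11.nwk`) is a synthetic
  stand-in tree with total length ≈ 13.3 expected substitutions, giving a
  quasi-continuous conservation statistic.

What passing these tests does *not* show: real PFMs include the pathological
near-deterministic columns; real genomic backgrounds are not stationary
homogeneous chains; real alignments have gaps, rate variation across clades
and sites, and non-JC substitution processes. The machinery is exact for the
*model*; the synthetic studies certify the approximations under the model,
not the model's fit to data.

## Numerical and design choices

* Everything is log-space end-to-end; `TailEstimate` stores $\log p$ and
  materializes $p$ only for display. Zero mass is $-\infty$, never `NaN`.
* Message schedule: two passes over a traversal rooted at the first
  declared variable of each component, ties broken by declaration order —
  repeated runs are bit-identical.
* Evidence is applied by zeroing potential slices, keeping the structure
  (and hence score tables) unchanged; clamping is idempotent and commutes
  across disjoint variable sets.
* State indices are 1-based throughout the R API, matching R convention.
* The interchange format is written as JSON (full 17-digit doubles, so
  round-trips are bit-exact) and read with a JSON-first/YAML-fallback
  parser; flat tables are row-major with the last scope variable fastest.
  Variable names are coerced to character on read — YAML 1.1 parses a bare
  `y` as a boolean, a classic trap.
* The convolution oracle folds components sequentially, re-merging support
  after every step: for lattice-valued scores the running support stays
  compact, where a balanced combination order would materialize enormous
  outer products. For the long-motif benchmark the log-odds tables are
  quantized to a $10^{-3}$ grid first — the quantized tables are the model
  under test for *both* the saddlepoint and the oracle, the standard device
  for exact PWM p-values.
* RNG: R's single stream, seeded per call; results are deterministic given
  `(graph, n, seed)`, but changing `n` changes the draws.

## Problem sizes

The shipped studies use: 50 random trees of ≤ 8 variables; Poisson-binomial
N = 1000; Binomial(30, 0.2) with 200-seed replication at n = 2000;
order-2 motifs of length 16 with 10⁵ naive draws and 10⁴ scanned 200-bp
sequences; 10⁵ simulated alignment columns on the 11-leaf tree; 10⁶ CTMC
paths per start state; and seven synthetic PWMs of lengths 14–20. These
sizes put every Monte-Carlo comparison at ≥ 3 significant digits while the
whole suite runs in about a minute.

## Known limitations

* Tree-structured graphs only; no junction-tree conversion or loopy
  inference.
* No higher-order (Lugannani–Rice-style) saddlepoint corrections beyond the
  lattice factor; accuracy on effectively-discrete non-lattice scores
  (highly informative PWMs) degrades accordingly — measured, not hidden.
* The saddlepoint route needs an additive score; latent-variable statistics
  are sampling-only.
* `maxScorePvalue()` ignores self-overlap clumping; it is flagged unreliable
  once the expected exceedance count $Mp$ exceeds 0.5 and assumes the motif
  is not low-complexity.
* No EM training of factor-graph parameters; models and parameters are
  taken as given.
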