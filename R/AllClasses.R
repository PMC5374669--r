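#' @import methods
NULL

#' Discrete tree-structured factor graph
#'
#' A factor graph is a bipartite graph of variable nodes and factor nodes.
#' Each variable has a finite state space; each factor carries a table of
#' non-negative potentials over the joint states of the variables in its
#' scope, and the joint distribution of all variables is proportional to the
#' product of the potentials. Only cycle-free (tree or forest) graphs are
#' admitted: exact message passing requires them.
#'
#' Potential tables are stored as R arrays whose dimensions follow the scope
#' order (ordinary column-major R indexing). Graphs may be unnormalized; all
#' probabilistic quantities are defined relative to the partition function Z.
#'
#' @slot varNames character vector of variable identifiers.
#' @slot varCards integer vector of state-space sizes (cardinalities).
#' @slot facNames character vector of factor identifiers.
#' @slot scopes list of integer vectors; each indexes `varNames`.
#' @slot potentials list of numeric arrays, one per factor, with
#'   `dim = varCards[scope]`.
#'
#' @seealso [factorGraph()], [sumProduct()], [setEvidence()]
#' @export
setClass("FactorGraph",
  representation(
    varNames   = "character",
    varCards   = "integer",
    facNames   = "character",
    scopes     = "list",
    potentials = "list"
  )
)

validFactorGraph <- function(object) {
  msgs <- character(0)
  nv <- length(object@varNames)
  nf <- length(object@facNames)
  if (anyDuplicated(object@varNames))
    msgs <- c(msgs, "variable identifiers must be unique")
  if (anyDuplicated(object@facNames))
    msgs <- c(msgs, "factor identifiers must be unique")
  if (length(object@varCards) != nv || any(object@varCards < 1L))
    msgs <- c(msgs, "every variable needs a cardinality >= 1")
  if (length(object@scopes) != nf || length(object@potentials) != nf)
    msgs <- c(msgs, "scopes/potentials must align with factor names")
  if (length(msgs)) return(msgs)

  for (a in seq_len(nf)) {
    sc <- object@scopes[[a]]
    if (length(sc) == 0L)
      msgs <- c(msgs, sprintf("factor '%s': arity-0 factors are not allowed",
                              object@facNames[a]))
    if (any(sc < 1L | sc > nv))
      msgs <- c(msgs, sprintf("factor '%s': scope references unknown variable",
                              object@facNames[a]))
    if (anyDuplicated(sc))
      msgs <- c(msgs, sprintf("factor '%s': repeated variable in scope",
                              object@facNames[a]))
    if (length(msgs)) return(msgs)
    pot <- object@potentials[[a]]
    want <- object@varCards[sc]
    got <- dim(pot) %||% length(pot)
    if (length(got) != length(want) || any(got != want))
      msgs <- c(msgs, sprintf(
        "factor '%s': potential shape (%s) does not match scope cardinalities (%s)",
        object@facNames[a], paste(got, collapse = "x"),
        paste(want, collapse = "x")))
    else {
      if (any(!is.finite(pot)) || any(pot < 0)) {
        bad <- which(!is.finite(pot) | pot < 0)[1L]
        msgs <- c(msgs, sprintf(
          "factor '%s': negative or non-finite potential entry at flat index %d",
          object@facNames[a], bad))
      } else if (all(pot == 0))
        msgs <- c(msgs, sprintf(
          "factor '%s': potential table has no strictly positive entry",
          object@facNames[a]))
    }
  }
  if (length(msgs)) return(msgs)

  touched <- sort(unique(unlist(object@scopes)))
  orphan <- setdiff(seq_len(nv), touched)
  if (length(orphan))
    msgs <- c(msgs, sprintf("variable '%s' appears in no factor scope",
                            object@varNames[orphan[1L]]))

  ## Acyclicity of the bipartite graph: a forest has
  ## #edges == #nodes - #components. Report one offending edge otherwise.
  edges <- sum(lengths(object@scopes))
  nodes <- nv + nf
  comp <- fgComponents(object)
  if (edges != nodes - comp$n) {
    cyc <- findCycleEdge(object)
    msgs <- c(msgs, sprintf(
      "graph contains an undirected cycle (e.g. through edge %s -- %s)",
      cyc[1L], cyc[2L]))
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("FactorGraph", validFactorGraph)

## Connected components of the bipartite graph; component label per variable.
fgComponents <- function(g) {
  nv <- length(g@varNames); nf <- length(g@facNames)
  varComp <- integer(nv); facComp <- integer(nf)
  varFacs <- vector("list", nv)
  for (a in seq_len(nf)) for (v in g@scopes[[a]])
    varFacs[[v]] <- c(varFacs[[v]], a)
  comp <- 0L
  for (v0 in seq_len(nv)) {
    if (varComp[v0] != 0L) next
    comp <- comp + 1L
    queue <- v0; varComp[v0] <- comp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (a in varFacs[[v]]) {
        if (facComp[a] != 0L) next
        facComp[a] <- comp
        for (w in g@scopes[[a]]) if (varComp[w] == 0L) {
          varComp[w] <- comp; queue <- c(queue, w)
        }
      }
    }
  }
  ## isolated variables (no factor) get their own components
  for (v in seq_len(nv)) if (varComp[v] == 0L) { comp <- comp + 1L; varComp[v] <- comp }
  list(n = comp, varComp = varComp, facComp = facComp)
}

## Locate one edge on a cycle: repeatedly strip leaves of the bipartite
## graph; any edge left belongs to a cycle.
findCycleEdge <- function(g) {
  nv <- length(g@varNames); nf <- length(g@facNames)
  ## adjacency as edge list (var, fac)
  ev <- integer(0); ef <- integer(0)
  for (a in seq_len(nf)) { ev <- c(ev, g@scopes[[a]]); ef <- c(ef, rep(a, length(g@scopes[[a]]))) }
  alive <- rep(TRUE, length(ev))
  repeat {
    degV <- tabulate(ev[alive], nv); degF <- tabulate(ef[alive], nf)
    leaf <- alive & (degV[ev] == 1L | degF[ef] == 1L)
    if (!any(leaf)) break
    alive[leaf] <- FALSE
  }
  if (any(alive)) {
    i <- which(alive)[1L]
    c(g@varNames[ev[i]], g@facNames[ef[i]])
  } else c("?", "?")
}

#' Per-factor score tables for an additive score
#'
#' A score specification assigns to each factor a table `g_a` shaped like its
#' potential table; the score of a configuration x is the sum
#' S(x) = sum_a g_a(x_a) of the per-factor contributions. `-Inf` entries are
#' permitted (states a foreground model excludes); `+Inf` is only permitted
#' on states whose potential is zero, so that S is never `+Inf` on a
#' positive-mass configuration.
#'
#' @slot facNames character, factor identifiers (declaration order of the
#'   graph the spec was built for).
#' @slot tables list of numeric arrays shaped like the factor potentials.
#' @seealso [scoreSpec()], [cgfMoments()], [saddlepointTail()]
#' @export
setClass("ScoreSpec",
  representation(facNames = "character", tables = "list"))

#' Result of sum-product inference
#'
#' @slot logZ log partition function (log of the total mass).
#' @slot varMarginals named list of per-variable marginal probability vectors.
#' @slot facMarginals named list of joint marginal tables, one per factor,
#'   over the factor's scope.
#' @seealso [sumProduct()]
#' @export
setClass("InferenceResult",
  representation(logZ = "numeric", varMarginals = "list", facMarginals = "list"))

#' Cumulant generating function of the score at a tilting parameter
#'
#' Holds kappa(theta), kappa'(theta) and kappa''(theta) for the score S under
#' the graph's (normalized) null distribution, computed exactly by
#' moment-semiring message passing.
#'
#' @slot theta tilting parameter.
#' @slot kappa value of the cgf; 0 at theta = 0.
#' @slot kappa1 first derivative: the mean of S under the tilted measure.
#' @slot kappa2 second derivative: the variance of S under the tilted measure.
#' @seealso [cgfMoments()]
#' @export
setClass("CgfResult",
  representation(theta = "numeric", kappa = "numeric",
                 kappa1 = "numeric", kappa2 = "numeric"))

#' Solution of the saddlepoint equation kappa'(theta) = t
#'
#' @slot theta the saddlepoint.
#' @slot cgf [CgfResult-class] evaluated at theta.
#' @slot iterations Newton iterations used.
#' @seealso [solveSaddlepoint()]
#' @export
setClass("SaddlepointSolution",
  representation(theta = "numeric", cgf = "CgfResult", iterations = "integer"))

#' A tail-probability estimate
#'
#' The p-value is carried in log form end-to-end (slot `logP`); the linear
#' form is materialized by [pValue()]. `flags` collects diagnostic markers
#' such as `"lattice_corrected"`, `"theta_negative_warning"`,
#' `"p_above_validity_warning"` and `"lower_tail_negated"`.
#'
#' @slot threshold score threshold t.
#' @slot logP log of the estimated P(S > t) (or P(S < t) for lower tails).
#' @slot method one of "normal", "saddlepoint", "naive", "importance", "exact".
#' @slot thetaAlpha tilting parameter used (saddlepoint theta or IS alpha);
#'   NA when not applicable.
#' @slot se standard error (sampling methods; NA otherwise).
#' @slot ciLow,ciHigh 95 percent confidence bounds (sampling methods).
#' @slot flags character vector of diagnostic flags.
#' @slot batch the [SampleBatch-class] behind a sampling estimate, or NULL.
#' @seealso [saddlepointTail()], [importanceSampleTail()], [pValue()]
#' @export
setClass("TailEstimate",
  representation(threshold = "numeric", logP = "numeric", method = "character",
                 thetaAlpha = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 flags = "character", batch = "ANY"),
  prototype(thetaAlpha = NA_real_, se = NA_real_,
            ciLow = NA_real_, ciHigh = NA_real_,
            flags = character(0), batch = NULL))

setValidity("TailEstimate", function(object) {
  if (length(object@logP) != 1L || is.na(object@logP) || object@logP > 1e-12)
    return("logP must be a single value <= 0")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh)) {
    p <- exp(object@logP)
    if (object@ciLow > p + 1e-12 || object@ciHigh < p - 1e-12)
      return("confidence interval must bracket the estimate")
  }
  TRUE
})

#' Scores and weights from one (tilted) sampling run
#'
#' @slot scores scores S(x_i) of the sampled configurations.
#' @slot logWeights log importance weights; all zero at alpha = 0.
#' @slot alpha tilting parameter of the proposal.
#' @slot seed RNG seed used.
#' @slot n number of samples.
#' @export
setClass("SampleBatch",
  representation(scores = "numeric", logWeights = "numeric",
                 alpha = "numeric", seed = "integer", n = "integer"))

setValidity("SampleBatch", function(object) {
  if (length(object@scores) != object@n || length(object@logWeights) != object@n)
    return("scores and logWeights must have length n")
  TRUE
})

#' An exact discrete score distribution
#'
#' Sorted support points with probabilities; the exact representation behind
#' the convolution oracle.
#'
#' @slot support strictly increasing numeric support.
#' @slot prob probabilities summing to one.
#' @seealso [scoreDistribution()], [convolutionTail()]
#' @export
setClass("ScoreDistribution",
  representation(support = "numeric", prob = "numeric"))

setValidity("ScoreDistribution", function(object) {
  if (length(object@support) != length(object@prob))
    return("support and prob must have equal length")
  if (is.unsorted(object@support, strictly = TRUE))
    return("support must be strictly increasing")
  if (any(object@prob < -1e-15))
    return("probabilities must be non-negative")
  if (abs(sum(object@prob) - 1) > 1e-9)
    return("probabilities must sum to 1")
  TRUE
})

#' A factor graph paired with a score specification
#'
#' The common currency of the model builders: a null model and the additive
#' score whose tail is to be evaluated.
#'
#' @slot graph the null-model [FactorGraph-class].
#' @slot score the [ScoreSpec-class].
#' @export
setClass("ScoredGraph",
  representation(graph = "FactorGraph", score = "ScoreSpec"))

#' A sequence-motif model compiled to a factor graph
#'
#' Produced by [pwmModel()] and [markovModel()]. The graph is the background
#' (null) model; the score is the foreground/background log-odds.
#'
#' @slot motifLength motif length in symbols (bp for DNA).
#' @slot alphabetSize alphabet size (4 for DNA).
#' @slot order Markov order of the representation (0 for a PWM).
#' @slot foreground foreground parameterization (PWM matrix, or list with
#'   initial distribution and transition tables).
#' @slot background background parameterization.
#' @export
setClass("MotifModel", contains = "ScoredGraph",
  representation(motifLength = "integer", alphabetSize = "integer",
                 order = "integer", foreground = "ANY", background = "ANY"))

#' A phylogenetic conservation model compiled to a factor graph
#'
#' One 4-state variable per tree node, a uniform root prior and one pairwise
#' factor per branch carrying Jukes-Cantor transition probabilities. The
#' score table of a branch factor is the conditional expected number of
#' substitutions on that branch given its endpoint states, so the full-data
#' score is the total substitution load of a configuration and the statistic
#' of record is its posterior expectation given a leaf column.
#'
#' @slot tree the `ape::phylo` tree the model was built from.
#' @slot muTotal total substitution rate per unit branch length.
#' @slot leafIndex named integer vector mapping tip labels to variable indices.
#' @seealso [phyloModel()], [phyloColumnStatistic()], [phyloTail()]
#' @export
setClass("PhyloModel", contains = "ScoredGraph",
  representation(tree = "ANY", muTotal = "numeric", leafIndex = "integer"))
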