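# Forward sampling from (tilted) factor graphs and tail estimation by
# naive / importance sampling. Sampling order is fixed by the inference
# module's rooting; draws use R's RNG seeded per call, so results are
# deterministic given (graph, n, seed).

#' Scores of explicit configurations
#'
#' Evaluates S(x) = sum_a g_a(x_a) for each row of a configuration matrix
#' (as returned by [forwardSample()]).
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param states n x nVariables integer matrix of 1-based state indices in
#'   variable declaration order.
#' @return numeric vector of n scores.
#' @export
configScores <- function(graph, score, states) {
  s <- numeric(nrow(states))
  for (a in seq_along(graph@scopes)) {
    sc <- graph@scopes[[a]]
    strides <- colMajorStrides(graph@varCards[sc])
    idx <- rep(1L, nrow(states))
    for (j in seq_along(sc))
      idx <- idx + (states[, sc[j]] - 1L) * strides[j]
    s <- s + as.vector(score@tables[[a]])[idx]
  }
  s
}

#' Exact forward sampling from a factor graph
#'
#' Draws independent configurations from the graph's normalized
#' distribution: the upward sum-product messages are computed once, each
#' component root is sampled from its marginal, and the tree is then
#' descended, sampling the remaining scope variables of each factor from the
#' factor potential times the downstream messages, conditional on the
#' already-assigned neighbours. All n draws for a factor are grouped by the
#' assigned parent state, so cost is linear in n with small constants.
#'
#' @param graph a [FactorGraph-class].
#' @param n number of draws (>= 1).
#' @param seed integer RNG seed.
#' @return an n x nVariables integer matrix of 1-based state indices, with
#'   variable names as column names.
#' @export
forwardSample <- function(graph, n, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  set.seed(as.integer(seed))
  str <- fgStructure(graph)
  up <- upwardMessages(graph, str)
  nv <- length(graph@varNames)
  states <- matrix(0L, nrow = n, ncol = nv,
                   dimnames = list(NULL, graph@varNames))

  sampleGrouped <- function(groupIdx, probTable) {
    ## groupIdx: integer vector in 1..nrow(probTable) per draw;
    ## probTable: rows = conditioning state, cols = outcome categories.
    out <- integer(length(groupIdx))
    for (gval in sort(unique(groupIdx))) {
      sel <- which(groupIdx == gval)
      p <- probTable[gval, ]
      tot <- sum(p)
      if (tot <= 0) stopf("zero conditional mass during forward sampling")
      out[sel] <- sample.int(length(p), length(sel), replace = TRUE,
                             prob = p / tot)
    }
    out
  }

  for (r in str$roots) {
    b <- up$msgVup[[r]]
    lz <- logSumExp(b)
    if (lz == -Inf) stopf("graph has zero partition function")
    p <- exp(b - lz)
    states[, r] <- sample.int(length(p), n, replace = TRUE, prob = p)
  }
  for (a in rev(str$facOrderUp)) {   # root-to-leaves
    kids <- str$facChildren[[a]]
    if (length(kids) == 0L) next
    sc <- graph@scopes[[a]]
    ppos <- match(str$facParent[a], sc)
    T <- up$logpot[[a]]
    for (w in kids) T <- addAlongDim(T, up$msgVup[[w]], match(w, sc))
    ## lay out as (parent state) x (joint state of the children)
    kidPos <- match(kids, sc)
    perm <- c(ppos, kidPos)
    M <- aperm(array(T, dim = dim(T) %||% length(T)), perm)
    dim(M) <- c(graph@varCards[str$facParent[a]],
                prod(graph@varCards[kids]))
    W <- exp(M - max(M[is.finite(M)]))
    joint <- sampleGrouped(states[, str$facParent[a]], W)
    dec <- arrayInd(joint, .dim = graph@varCards[kids])
    for (j in seq_along(kids)) states[, kids[j]] <- dec[, j]
  }
  states
}

#' Tail estimation by importance sampling on a tilted proposal
#'
#' Samples from the exponentially tilted graph [tiltGraph()] at strength
#' `alpha` and estimates P(S > t) as the mean of w_i * I(s_i > t), where the
#' weights w_i = exp(kappa(alpha) - alpha s_i) are exact (computed from the
#' cgf, which also covers unnormalized graphs). `alpha = 0` is naive
#' sampling with all weights equal to one; `alpha = NULL` uses the
#' saddlepoint-guided choice [saddlepointGuidedAlpha()], which places the
#' proposal's mean score at the threshold.
#'
#' The standard error is the sample standard deviation of w_i * I(s_i > t)
#' over sqrt(n); the 95 percent normal-theory confidence interval is
#' truncated to \[0, 1\].
#'
#' @inheritParams solveSaddlepoint
#' @param alpha tilting strength, or `NULL` for saddlepoint-guided.
#' @param n number of samples (>= 2; default 10000).
#' @param seed integer RNG seed.
#' @return a [TailEstimate-class] (method `"naive"` for alpha = 0,
#'   `"importance"` otherwise) carrying its [SampleBatch-class].
#' @export
importanceSampleTail <- function(graph, score, t, alpha = NULL, n = 10000L,
                                 seed = 1L) {
  if (n < 2) stopf("n must be >= 2")
  checkScoreMatches(graph, score)
  if (is.null(alpha)) alpha <- saddlepointGuidedAlpha(graph, score, t)
  proposal <- tiltGraph(graph, score, alpha)
  states <- forwardSample(proposal, n, seed)
  s <- configScores(graph, score, states)
  if (alpha == 0) {
    logw <- numeric(n)
  } else {
    kap <- cgfMoments(graph, score, alpha)@kappa
    logw <- kap - alpha * s
  }
  wInd <- exp(logw) * (s > t)
  p <- mean(wInd)
  se <- stats::sd(wInd) / sqrt(n)
  ci <- c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
  batch <- new("SampleBatch", scores = s, logWeights = logw,
               alpha = alpha, seed = as.integer(seed), n = as.integer(n))
  newTailEstimate(t, if (p > 0) log(p) else -Inf,
                  if (alpha == 0) "naive" else "importance",
                  thetaAlpha = alpha, se = se, ciLow = ci[1], ciHigh = ci[2],
                  batch = batch)
}

#' Naive-sampling tail estimate
#'
#' Convenience wrapper for [importanceSampleTail()] with `alpha = 0`.
#'
#' @inheritParams importanceSampleTail
#' @return a [TailEstimate-class] with method `"naive"`.
#' @export
naiveTail <- function(graph, score, t, n = 10000L, seed = 1L)
  importanceSampleTail(graph, score, t, alpha = 0, n = n, seed = seed)

#' Saddlepoint-guided tilting strength
#'
#' Returns the saddlepoint theta(t), i.e. the tilting strength at which the
#' proposal's mean score equals the threshold. Importance sampling with this
#' alpha concentrates samples exactly where the indicator switches, the
#' regime in which exponential tilting is efficient.
#'
#' @inheritParams solveSaddlepoint
#' @return a single numeric alpha.
#' @export
saddlepointGuidedAlpha <- function(graph, score, t)
  solveSaddlepoint(graph, score, t)@theta

#' Importance sampling for statistics of observed margins
#'
#' For models with latent variables the statistic of interest is often a
#' function of the observed variables only (e.g. the posterior expected
#' substitution load given the leaves of a tree); it is then not an additive
#' score and the saddlepoint machinery does not apply. Importance sampling
#' still does: full configurations are drawn from the tilted graph, the
#' statistic is evaluated on each sample's observed margin, and the
#' full-data weights exp(kappa(alpha) - alpha S(x)) make the estimate of
#' P(statistic > t) (or < t) unbiased.
#'
#' @inheritParams importanceSampleTail
#' @param observedVars character vector of observed variable names.
#' @param statistic function taking an n x length(observedVars) integer
#'   matrix of states (columns named) and returning n statistic values;
#'   `NULL` uses the posterior expected score given the observed margin
#'   (computed per distinct margin via [posteriorExpectedScore()]).
#' @param tailSide `"upper"` for P(stat > t), `"lower"` for P(stat < t).
#' @param alpha tilting strength (0 = naive sampling). For lower tails a
#'   negative alpha tilts toward low scores.
#' @return a [TailEstimate-class]; its [SampleBatch-class] carries the
#'   statistic values in place of scores.
#' @export
latentStatisticTail <- function(graph, score, observedVars, statistic = NULL,
                                t, alpha = 0, n = 10000L, seed = 1L,
                                tailSide = c("upper", "lower")) {
  tailSide <- match.arg(tailSide)
  checkScoreMatches(graph, score)
  ov <- match(observedVars, graph@varNames)
  if (anyNA(ov)) stopf("unknown observed variable '%s'",
                       observedVars[which(is.na(ov))[1L]])
  if (is.null(statistic)) {
    statistic <- function(m) {
      key <- apply(m, 1L, paste, collapse = ",")
      vals <- vapply(unique(key), function(k) {
        row <- m[match(k, key), , drop = TRUE]
        posteriorExpectedScore(graph, score,
                               setNames(as.integer(row), colnames(m)))
      }, numeric(1))
      as.numeric(vals[key])
    }
  }
  proposal <- tiltGraph(graph, score, alpha)
  states <- forwardSample(proposal, n, seed)
  sFull <- configScores(graph, score, states)
  logw <- if (alpha == 0) numeric(n)
          else cgfMoments(graph, score, alpha)@kappa - alpha * sFull
  obs <- states[, ov, drop = FALSE]
  colnames(obs) <- observedVars
  stat <- statistic(obs)
  ind <- if (tailSide == "upper") stat > t else stat < t
  wInd <- exp(logw) * ind
  p <- mean(wInd)
  se <- stats::sd(wInd) / sqrt(n)
  ci <- c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
  batch <- new("SampleBatch", scores = stat, logWeights = logw,
               alpha = alpha, seed = as.integer(seed), n = as.integer(n))
  newTailEstimate(t, if (p > 0) log(p) else -Inf,
                  if (alpha == 0) "naive" else "importance",
                  thetaAlpha = alpha, se = se, ciLow = ci[1], ciHigh = ci[2],
                  flags = if (tailSide == "lower") "lower_tail_statistic"
                          else character(0),
                  batch = batch)
}
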