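# Independent exact oracles (enumeration, convolution, CTMC path
# simulation) and seeded synthetic fixtures. These deliberately share no
# code with the message-passing algorithms they validate: enumeration works
# by direct products over explicitly enumerated configurations.

ENUM_CAP <- 2e6

## enumerate all configurations: returns list(states = K x nv matrix,
## logP = unnormalized log mass, S = scores)
enumerateConfigurations <- function(graph, score = NULL) {
  cards <- graph@varCards
  K <- prod(cards)
  if (K > ENUM_CAP)
    stopf("joint state space (%g configurations) exceeds the enumeration cap (%g)",
          K, ENUM_CAP)
  nv <- length(cards)
  ## configuration matrix via mixed-radix counting (column-major strides)
  states <- matrix(0L, K, nv)
  rep1 <- 1L
  for (v in seq_len(nv)) {
    states[, v] <- rep(rep(seq_len(cards[v]), each = rep1),
                       length.out = K)
    rep1 <- rep1 * cards[v]
  }
  logP <- numeric(K)
  S <- if (is.null(score)) NULL else numeric(K)
  for (a in seq_along(graph@scopes)) {
    sc <- graph@scopes[[a]]
    strides <- colMajorStrides(cards[sc])
    idx <- rep(1L, K)
    for (j in seq_along(sc)) idx <- idx + (states[, sc[j]] - 1L) * strides[j]
    f <- as.vector(graph@potentials[[a]])[idx]
    logP <- logP + ifelse(f > 0, log(f), -Inf)
    if (!is.null(S)) {
      gs <- as.vector(score@tables[[a]])[idx]
      S <- S + gs
    }
  }
  if (!is.null(S)) S[logP == -Inf] <- NA_real_
  list(states = states, logP = logP, S = S)
}

#' Exact tail probability by exhaustive enumeration
#'
#' Sums the normalized mass of every configuration whose score exceeds t.
#' The reference implementation for every approximate method; limited to
#' joint state spaces of at most 2e6 configurations.
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param t threshold.
#' @param inclusive if `TRUE` computes P(S >= t) instead of the strict
#'   P(S > t).
#' @return the exact tail probability.
#' @export
enumerateTail <- function(graph, score, t, inclusive = FALSE) {
  en <- enumerateConfigurations(graph, score)
  lz <- logSumExp(en$logP)
  if (lz == -Inf) stopf("graph has zero partition function")
  keep <- en$logP > -Inf & (if (inclusive) en$S >= t else en$S > t)
  if (!any(keep)) return(0)
  exp(logSumExp(en$logP[keep]) - lz)
}

#' Exact cgf by direct summation
#'
#' kappa, kappa' and kappa'' at theta from the enumerated score
#' distribution; the oracle for [cgfMoments()].
#'
#' @inheritParams enumerateTail
#' @param theta tilting parameter.
#' @return a list with `kappa`, `kappa1`, `kappa2`.
#' @export
enumerateCgf <- function(graph, score, theta) {
  en <- enumerateConfigurations(graph, score)
  ok <- en$logP > -Inf
  lp <- en$logP[ok] - logSumExp(en$logP[ok])   # normalized log probs
  s <- en$S[ok]
  lt <- lp + theta * s
  kap <- logSumExp(lt)
  w <- exp(lt - kap)
  m1 <- sum(w * s)
  m2 <- sum(w * s^2)
  list(kappa = kap, kappa1 = m1, kappa2 = m2 - m1^2)
}

#' Exact score distribution by enumeration
#'
#' @inheritParams enumerateTail
#' @param mergeTol support points closer than this are merged.
#' @return a [ScoreDistribution-class].
#' @export
enumerateDistribution <- function(graph, score, mergeTol = 1e-12) {
  en <- enumerateConfigurations(graph, score)
  ok <- en$logP > -Inf
  lz <- logSumExp(en$logP[ok])
  scoreDistribution(en$S[ok], exp(en$logP[ok] - lz), mergeTol = mergeTol)
}

#' Construct an exact discrete score distribution
#'
#' Sorts the support, merges near-equal points (summing their mass) and
#' validates that probabilities sum to one.
#'
#' @param support numeric support points (any order, duplicates allowed).
#' @param prob matching probabilities.
#' @param mergeTol absolute tolerance under which adjacent support points
#'   are merged; keeps float-score supports from exploding under
#'   convolution.
#' @return a [ScoreDistribution-class].
#' @export
scoreDistribution <- function(support, prob, mergeTol = 1e-12) {
  o <- order(support)
  s <- support[o]; p <- prob[o]
  if (length(s) > 1L) {
    grp <- cumsum(c(TRUE, diff(s) > mergeTol))
    ## representative = first point of each group: exact (no float drift)
    ## for lattice supports, and within mergeTol of every member otherwise
    first <- !duplicated(grp)
    pm <- as.vector(rowsum(p, grp))
    s <- s[first]
    p <- pm
  }
  new("ScoreDistribution", support = as.numeric(s), prob = as.numeric(p / sum(p)))
}

#' Exact distribution of a sum of independent scores by convolution
#'
#' Iterated pairwise convolution with support merging; exact for
#' independent components (e.g. the per-variable score distributions of a
#' fully disconnected graph). The sequential fold keeps the running support
#' merged after every step, so lattice-valued scores (counts, quantized
#' log-odds) never blow up; the cost for N same-range components is
#' O(N^2 / mergeTol-resolution) in the lattice case.
#'
#' @param components list of [ScoreDistribution-class] objects.
#' @param mergeTol support merge tolerance passed to [scoreDistribution()].
#' @return a [ScoreDistribution-class] for the sum.
#' @export
convolveDistributions <- function(components, mergeTol = 1e-12) {
  stopifnot(length(components) >= 1L)
  conv2 <- function(d1, d2) {
    s <- outer(d1@support, d2@support, "+")
    p <- outer(d1@prob, d2@prob)
    scoreDistribution(as.vector(s), as.vector(p), mergeTol = mergeTol)
  }
  acc <- components[[1L]]
  for (i in seq_along(components)[-1L]) acc <- conv2(acc, components[[i]])
  acc
}

#' Exact tail of a sum of independent scores
#'
#' @inheritParams convolveDistributions
#' @param t threshold.
#' @param inclusive if `TRUE` computes P(S >= t).
#' @return exact P(S > t) (or P(S >= t)).
#' @export
convolutionTail <- function(components, t, inclusive = FALSE,
                            mergeTol = 1e-12) {
  d <- convolveDistributions(components, mergeTol = mergeTol)
  keep <- if (inclusive) d@support >= t else d@support > t
  sum(d@prob[keep])
}

#' Tail of a score distribution
#'
#' @param dist a [ScoreDistribution-class].
#' @param t threshold.
#' @param inclusive if `TRUE`, P(S >= t).
#' @return exact tail mass above t.
#' @export
distributionTail <- function(dist, t, inclusive = FALSE) {
  keep <- if (inclusive) dist@support >= t else dist@support > t
  sum(dist@prob[keep])
}

#' Per-variable score components of a disconnected graph
#'
#' For a graph whose variables are all independent (each variable forms a
#' connected component with its unary factors), returns the exact score
#' distribution of each variable's total contribution - the input the
#' convolution oracle needs.
#'
#' @param graph a fully disconnected [FactorGraph-class] (unary factors
#'   only).
#' @param score a [ScoreSpec-class].
#' @return list of [ScoreDistribution-class], one per variable.
#' @export
componentDistributions <- function(graph, score) {
  if (any(lengths(graph@scopes) != 1L))
    stopf("componentDistributions requires a fully disconnected (unary-only) graph")
  nv <- length(graph@varNames)
  out <- vector("list", nv)
  for (v in seq_len(nv)) {
    facs <- which(vapply(graph@scopes, function(s) s[1L] == v, logical(1)))
    mass <- rep(1, graph@varCards[v]); sc <- rep(0, graph@varCards[v])
    for (a in facs) {
      mass <- mass * as.vector(graph@potentials[[a]])
      sc <- sc + as.vector(score@tables[[a]])
    }
    ok <- mass > 0
    out[[v]] <- scoreDistribution(sc[ok], mass[ok] / sum(mass[ok]))
  }
  out
}

#' Balanced-tree benchmark fixture
#'
#' A rooted balanced tree of variables (every internal variable has
#' `degree` children, `depth` levels below the root) with one pairwise
#' factor per edge. Every edge carries the same doubly stochastic channel
#' (1 - coupling)/k + coupling * I and the same seeded random score table,
#' so each factor's score contribution has an identical marginal
#' distribution while `coupling` tunes the dependence between contributions
#' - measured by [varianceRatio()]. The root carries a uniform unary prior
#' with zero score; the graph is normalized.
#'
#' @param depth number of edge levels below the root (>= 1).
#' @param degree children per internal variable (>= 1).
#' @param states states per variable (>= 2).
#' @param coupling dependence knob in \[0, 1): 0 = independent contributions.
#' @param seed integer seed for the score table.
#' @param scoreSd standard deviation of the normal score entries.
#' @param sharedScores if `TRUE` (default) every edge carries the same score
#'   table, making the per-factor contributions identically distributed; if
#'   `FALSE` each edge draws its own table from the same normal family,
#'   which keeps the family matched but makes the total score
#'   quasi-continuous (useful when probing deep quantiles).
#' @return a [ScoredGraph-class].
#' @export
balancedTreeFixture <- function(depth, degree, states = 2L, coupling = 0.5,
                                seed = 1L, scoreSd = 1, sharedScores = TRUE) {
  stopifnot(depth >= 1L, degree >= 1L, states >= 2L,
            coupling >= 0, coupling < 1)
  set.seed(as.integer(seed))
  k <- as.integer(states)
  channel <- matrix((1 - coupling) / k, k, k) + diag(k) * coupling
  gtab <- matrix(stats::rnorm(k * k, sd = scoreSd), k, k)
  nPerLevel <- degree^(0:depth)
  ids <- unlist(lapply(0:depth, function(d)
    sprintf("v%d_%d", d, seq_len(nPerLevel[d + 1L]))))
  vars <- setNames(rep(k, length(ids)), ids)
  facs <- list(root = list(scope = ids[1L], potential = rep(1 / k, k)))
  scs <- list(root = rep(0, k))
  for (d in seq_len(depth)) {
    for (j in seq_len(nPerLevel[d + 1L])) {
      child <- sprintf("v%d_%d", d, j)
      parent <- sprintf("v%d_%d", d - 1L, (j - 1L) %/% degree + 1L)
      fn <- sprintf("e_%s", child)
      facs[[fn]] <- list(scope = c(parent, child), potential = channel)
      scs[[fn]] <- if (sharedScores) gtab
                   else matrix(stats::rnorm(k * k, sd = scoreSd), k, k)
    }
  }
  g <- factorGraph(vars, facs)
  new("ScoredGraph", graph = g, score = scoreSpec(g, scs))
}

#' Seeded random tree-structured fixture
#'
#' A random tree over `nVars` variables (variable i attaches to a uniformly
#' chosen earlier variable through a pairwise factor), plus a unary factor
#' on the root; potentials are positive gamma draws and score tables are
#' normal draws. Deterministic given the seed; used by the oracle-agreement
#' test surfaces.
#'
#' @param nVars number of variables (>= 1).
#' @param maxStates each variable's cardinality is drawn from 2..maxStates.
#' @param seed integer seed.
#' @return a [ScoredGraph-class].
#' @export
randomTreeFixture <- function(nVars, maxStates = 4L, seed = 1L) {
  stopifnot(nVars >= 1L, maxStates >= 2L)
  set.seed(as.integer(seed))
  cards <- sample(2:maxStates, nVars, replace = TRUE)
  nm <- sprintf("x%d", seq_len(nVars))
  vars <- setNames(as.integer(cards), nm)
  facs <- list(u1 = list(scope = nm[1L],
                         potential = stats::rgamma(cards[1L], 2, 2)))
  scs <- list(u1 = stats::rnorm(cards[1L]))
  if (nVars > 1L) for (v in 2:nVars) {
    p <- if (v == 2L) 1L else sample.int(v - 1L, 1L)
    fn <- sprintf("f%d", v)
    facs[[fn]] <- list(scope = c(nm[p], nm[v]),
                       potential = matrix(stats::rgamma(cards[p] * cards[v], 2, 2),
                                          cards[p], cards[v]))
    scs[[fn]] <- matrix(stats::rnorm(cards[p] * cards[v]), cards[p], cards[v])
  }
  g <- factorGraph(vars, facs)
  new("ScoredGraph", graph = g, score = scoreSpec(g, scs))
}

#' Simulate substitution paths of the Jukes-Cantor process
#'
#' Continuous-time path simulation: the number of substitution events on
#' \[0, t\] is Poisson with mean muTotal * t (equivalent to exponential
#' waiting times at rate muTotal), and each event moves to one of the three
#' other bases uniformly. The empirical endpoint distribution and
#' conditional mean substitution counts are the independent oracle for
#' [jc69Transition()] and [jc69ExpectedSubstitutions()].
#'
#' @param muTotal total substitution rate.
#' @param t elapsed time (branch length).
#' @param start starting base (1..4).
#' @param nPaths number of simulated paths.
#' @param seed integer RNG seed.
#' @return list with `endState` (integer vector) and `nSubs` (substitution
#'   counts per path).
#' @export
simulateCTMC <- function(muTotal, t, start = 1L, nPaths = 1e5, seed = 1L) {
  stopifnot(nPaths >= 1)
  set.seed(as.integer(seed))
  nSubs <- stats::rpois(nPaths, muTotal * t)
  endState <- rep(as.integer(start), nPaths)
  mx <- max(nSubs)
  if (mx > 0) for (j in seq_len(mx)) {
    act <- nSubs >= j
    na <- sum(act)
    if (!na) break
    ## jump uniformly to one of the three other bases
    step <- sample.int(3L, na, replace = TRUE)
    cur <- endState[act]
    nxt <- step + (step >= cur)
    endState[act] <- nxt
  }
  list(endState = endState, nSubs = nSubs)
}

#' Seeded synthetic position frequency matrix
#'
#' Draws a random PFM with moderately informative columns (gamma draws with
#' a floor, so no column is a near-deterministic single-base preference;
#' such motifs are the known hard case for the saddlepoint approximation
#' because their score distribution is effectively discrete).
#'
#' @param length motif length N.
#' @param seed integer seed.
#' @param concentration gamma shape of the column draws; larger is flatter.
#' @param floor additive floor on the unnormalized column weights.
#' @param total count total per column.
#' @return a 4 x N count matrix (rows A,C,G,T).
#' @export
syntheticPfm <- function(length, seed = 1L, concentration = 2, floor = 0.15,
                         total = 1000L) {
  set.seed(as.integer(seed))
  m <- vapply(seq_len(length), function(i) {
    x <- stats::rgamma(4, concentration) + floor
    round(total * x / sum(x))
  }, numeric(4))
  rownames(m) <- DNA_ALPHABET
  m
}

#' Seeded synthetic higher-order Markov motif model
#'
#' A transcription-factor-like motif of inhomogeneous order-r transitions
#' (concentrated random rows, so positions carry context-dependent
#' preferences) over a homogeneous near-uniform order-r background whose
#' initial distribution is its stationary tuple distribution - so every
#' window of a longer background sequence shares the motif model's null
#' score distribution, as scan statistics require.
#'
#' @param length motif length L.
#' @param order Markov order r.
#' @param seed integer seed.
#' @return a [MotifModel-class].
#' @export
syntheticMarkovMotif <- function(length = 16L, order = 2L, seed = 1L) {
  set.seed(as.integer(seed))
  A <- 4L
  K <- as.integer(A^order)
  fgInit <- { x <- stats::rgamma(K, 1) * 3 + 0.2
              x <- stats::rgamma(K, x); x / sum(x) }
  fgTr <- lapply(seq_len(length - order), function(i)
    t(vapply(seq_len(K), function(k) {
      a <- stats::rgamma(A, 0.6) + 0.05
      x <- stats::rgamma(A, 1) * a
      x / sum(x)
    }, numeric(A))))
  bgTr <- t(vapply(seq_len(K), function(k) {
    x <- stats::rgamma(A, 8) + 2
    x / sum(x)
  }, numeric(A)))
  markovModel(order, A, fgInit, fgTr, length, bgTransitions = bgTr)
}
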