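# Model builders: translate the four standard applications into
# (FactorGraph, ScoreSpec) pairs. Alphabet order is A,C,G,T throughout
# (JASPAR row order); sequence coordinates are 0-based half-open in scan
# reporting.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Poisson-binomial model
#'
#' N independent Bernoulli trials Y_n ~ Bernoulli(p_n), optionally with
#' per-event weights s_n; the score is S = sum s_n Y_n (the number of
#' successes for unit weights). The graph is fully disconnected: one binary
#' variable with a unary factor (1 - p_n, p_n) per trial.
#'
#' @param p vector of success probabilities in \[0, 1\].
#' @param s optional vector of event weights (defaults to all ones).
#' @return a [ScoredGraph-class].
#' @examples
#' m <- poissonBinomialModel(rep(0.5, 10))
#' pValue(saddlepointTail(modelGraph(m), modelScore(m), 7.5, lattice = 1))
#' @export
poissonBinomialModel <- function(p, s = NULL) {
  if (length(p) == 0L) stopf("p must be non-empty")
  if (any(p < 0 | p > 1)) stopf("success probabilities must lie in [0, 1]")
  s <- s %||% rep(1, length(p))
  if (length(s) != length(p)) stopf("s must match p in length")
  nm <- sprintf("Y%d", seq_along(p))
  vars <- setNames(rep(2L, length(p)), nm)
  facs <- setNames(lapply(seq_along(p), function(i)
    list(scope = nm[i], potential = c(1 - p[i], p[i]))),
    sprintf("bern%d", seq_along(p)))
  g <- factorGraph(vars, facs)
  sc <- scoreSpec(g, lapply(seq_along(p), function(i) c(0, s[i])))
  new("ScoredGraph", graph = g, score = sc)
}

#' Position weight matrix motif model
#'
#' An i.i.d. background over A,C,G,T with per-position foreground
#' frequencies f_ji; the match score of a length-N window is the summed
#' log-odds sum_i log(f_{j_i i} / p_{j_i}). The graph has one 4-state
#' variable per motif position with the background as its unary potential;
#' the score tables are the per-position log-odds columns.
#'
#' @param pfm 4 x N matrix of counts or column frequencies, rows in A,C,G,T
#'   order (as in JASPAR records).
#' @param background strictly positive probability 4-vector (default
#'   uniform).
#' @param pseudocount added to every count cell before normalizing
#'   (default 0.01; only applied when `pfm` holds counts).
#' @param type `"auto"` detects frequencies by columns summing to one.
#' @return a [MotifModel-class].
#' @export
pwmModel <- function(pfm, background = rep(0.25, 4), pseudocount = 0.01,
                     type = c("auto", "counts", "frequencies")) {
  type <- match.arg(type)
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L || ncol(pfm) < 1L)
    stopf("pfm must be a 4 x N matrix (rows A,C,G,T)")
  if (any(pfm < 0)) stopf("pfm entries must be non-negative")
  if (length(background) != 4L || any(background <= 0))
    stopf("background must be a strictly positive 4-vector")
  background <- background / sum(background)
  N <- ncol(pfm)
  if (type == "auto")
    type <- if (all(abs(colSums(pfm) - 1) < 1e-6)) "frequencies" else "counts"
  freq <- if (type == "counts") {
    ct <- colSums(pfm)
    if (any(ct + 4 * pseudocount <= 0)) stopf("zero column total in pfm")
    sweep(pfm + pseudocount, 2, ct + 4 * pseudocount, "/")
  } else {
    sweep(pfm, 2, colSums(pfm), "/")
  }
  if (any(freq == 0))
    stopf("zero foreground frequency with zero pseudocount gives an unbounded score")
  rownames(freq) <- DNA_ALPHABET
  nm <- sprintf("pos%d", seq_len(N))
  vars <- setNames(rep(4L, N), nm)
  facs <- setNames(lapply(seq_len(N), function(i)
    list(scope = nm[i], potential = background)),
    sprintf("bg%d", seq_len(N)))
  g <- factorGraph(vars, facs)
  sc <- scoreSpec(g, lapply(seq_len(N), function(i) log(freq[, i] / background)))
  new("MotifModel", graph = g, score = sc,
      motifLength = N, alphabetSize = 4L, order = 0L,
      foreground = freq, background = background)
}

## stationary distribution over r-tuples of a homogeneous order-r chain
stationaryTupleDistribution <- function(transitions, A, r) {
  K <- as.integer(A^r)
  tr <- as.matrix(transitions)
  if (nrow(tr) != K || ncol(tr) != A)
    stopf("transition table must be %d x %d", K, A)
  Tz <- matrix(0, K, K)
  for (z in seq_len(K)) for (s2 in seq_len(A)) {
    znew <- (z - 1L) %% as.integer(A^(r - 1L)) * A + s2
    Tz[z, znew] <- Tz[z, znew] + tr[z, s2]
  }
  ev <- eigen(t(Tz))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  if (sum(v) < 0) v <- -v          # eigenvector sign is arbitrary
  v <- pmax(v, 0)
  v / sum(v)
}

## compound-state helpers: a state encodes an r-tuple of symbols, first
## symbol most significant, 1-based
compoundEncode <- function(symbols, A) {
  r <- length(symbols)
  sum((symbols - 1L) * A^((r - 1L):0L)) + 1L
}
compoundSuffix <- function(z, A, r) (z - 1L) %% A^(r - 1L)          # drops first symbol
compoundPrefix <- function(z, A) (z - 1L) %/% A                     # drops last symbol
compoundLastSymbol <- function(z, A) (z - 1L) %% A + 1L

## build the factor graph of an order-r chain over compounded variables
markovChainGraph <- function(order, A, initial, transitions, L, prefix = "z") {
  r <- order
  K <- as.integer(A^r)
  M <- L - r + 1L
  if (length(initial) != K) stopf("initial distribution must have length %d", K)
  perPos <- is.list(transitions)
  trList <- if (perPos) transitions else rep(list(transitions), max(M - 1L, 0L))
  if (length(trList) != M - 1L && M > 1L)
    stopf("need %d transition tables, got %d", M - 1L, length(trList))
  nm <- sprintf("%s%d", prefix, seq_len(M))
  vars <- setNames(rep(K, M), nm)
  facs <- list(init = list(scope = nm[1L], potential = as.numeric(initial)))
  if (M > 1L) {
    z <- seq_len(K)
    suff <- compoundSuffix(z, A, r)
    pref <- compoundPrefix(z, A)
    newSym <- compoundLastSymbol(z, A)
    for (i in seq_len(M - 1L)) {
      tr <- as.matrix(trList[[i]])
      if (nrow(tr) != K || ncol(tr) != A)
        stopf("transition table %d must be %d x %d", i, K, A)
      if (any(abs(rowSums(tr) - 1) > 1e-9))
        stopf("transition table %d: rows must sum to 1", i)
      pot <- matrix(0, K, K)
      for (zz in z) {
        ok <- which(pref == suff[zz])      # compatible successors
        pot[zz, ok] <- tr[zz, newSym[ok]]
      }
      facs[[sprintf("step%d", i)]] <- list(scope = c(nm[i], nm[i + 1L]),
                                           potential = pot)
    }
  }
  factorGraph(vars, facs)
}

#' Higher-order Markov motif model by variable compounding
#'
#' An order-r Markov chain contains cycles as a graphical model, but
#' compounding r consecutive symbols into one variable turns it into a
#' first-order chain over A^r-state variables, restoring tree structure.
#' The builder compiles foreground and background chains with identical
#' structure and scores by their log-odds; transitions between incompatible
#' compound states (suffix and prefix disagreeing) get zero potential and
#' zero score.
#'
#' @param order Markov order r >= 1.
#' @param alphabetSize alphabet size A (4 for DNA).
#' @param initial foreground initial distribution over A^r r-tuples (first
#'   symbol most significant).
#' @param transitions foreground transitions: an A^r x A matrix
#'   (homogeneous) or a list of L - r per-position matrices.
#' @param length sequence length L >= r.
#' @param bgInitial,bgTransitions background chain (homogeneous). Defaults:
#'   uniform i.i.d. transitions; when `bgTransitions` is given but
#'   `bgInitial` is not, the chain's stationary tuple distribution is used,
#'   so every scan window shares the same marginal score distribution.
#' @return a [MotifModel-class]; the graph is the background chain.
#' @export
markovModel <- function(order, alphabetSize = 4L, initial, transitions,
                        length, bgInitial = NULL, bgTransitions = NULL) {
  r <- as.integer(order); A <- as.integer(alphabetSize); L <- as.integer(length)
  if (r < 1L) stopf("order must be >= 1")
  if (L < r) stopf("length must be >= order")
  K <- as.integer(A^r)
  if (is.null(bgInitial))
    bgInitial <- if (is.null(bgTransitions)) rep(1 / K, K)
                 else stationaryTupleDistribution(bgTransitions, A, r)
  bgTransitions <- bgTransitions %||% matrix(1 / A, K, A)
  fgGraph <- markovChainGraph(r, A, initial, transitions, L)
  bgGraph <- markovChainGraph(r, A, bgInitial, bgTransitions, L)
  sc <- logOddsScore(bgGraph, fgGraph)
  new("MotifModel", graph = bgGraph, score = sc,
      motifLength = L, alphabetSize = A, order = r,
      foreground = list(initial = initial, transitions = transitions),
      background = list(initial = bgInitial, transitions = bgTransitions))
}

#' Jukes-Cantor transition probabilities
#'
#' Under JC69 with total substitution rate `muTotal` per unit time, the
#' probability of observing the same base after time t is
#' 1/4 + 3/4 exp(-4/3 mu t) and of each different base
#' 1/4 - 1/4 exp(-4/3 mu t); `muTotal * t` is the expected number of
#' substitution events on the branch.
#'
#' @param muTotal total substitution rate (> 0).
#' @param t branch length (>= 0), in time units (expected substitutions when
#'   `muTotal = 1`).
#' @return a 4 x 4 stochastic matrix, rows = ancestral base (A,C,G,T).
#' @export
jc69Transition <- function(muTotal = 1, t) {
  if (t < 0) stopf("branch length must be non-negative")
  if (muTotal <= 0) stopf("muTotal must be positive")
  e <- exp(-4 / 3 * muTotal * t)
  P <- matrix(1 / 4 - e / 4, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(P) <- 1 / 4 + 3 * e / 4
  P
}

#' Expected substitutions conditional on branch endpoints
#'
#' E\[N | a, b\] where N counts every substitution event on a branch of
#' length t (multiple events at a site can cancel, so N can exceed the
#' observed differences and is strictly positive even for identical
#' endpoints). Computed as M_ab / P_ab with
#' M(t) = integral_0^t P(s) C P(t - s) ds, C the rate matrix with its
#' diagonal zeroed. For JC69 the integral has the spectral closed form
#' M(t) = (mu t / 4) J + exp(-4/3 mu t) mu t (J/12 - I/3) (J the all-ones
#' matrix), which is evaluated exactly here; a generic-rate-matrix
#' quadrature fallback backs the internal cross-check.
#'
#' @inheritParams jc69Transition
#' @return a 4 x 4 matrix E\[N | ancestral = a, descendant = b\].
#' @export
jc69ExpectedSubstitutions <- function(muTotal = 1, t) {
  if (t <= 0) stopf("branch length must be positive")
  beta <- 4 / 3 * muTotal
  e <- exp(-beta * t)
  J <- matrix(1, 4, 4)
  ## M(t) = (mu t / 4) J + e^{-beta t} t mu (J/12 - I/3): spectral closed form
  M <- (muTotal * t / 4) * J + e * t * muTotal * (J / 12 - diag(4) / 3)
  P <- jc69Transition(muTotal, t)
  out <- M / P
  dimnames(out) <- list(DNA_ALPHABET, DNA_ALPHABET)
  out
}

## generic-rate-matrix fallback: Simpson quadrature of P(s) C P(t-s) with
## eigen-decomposed matrix exponentials; used to cross-check the closed form
expectedSubstitutionsQuad <- function(Q, t, nGrid = 201L) {
  ev <- eigen(Q)
  Pt <- function(s) Re(ev$vectors %*% diag(exp(ev$values * s)) %*% solve(ev$vectors))
  C <- Q; diag(C) <- 0
  ss <- seq(0, t, length.out = nGrid)
  h <- ss[2] - ss[1]
  wts <- rep(c(2, 4), length.out = nGrid); wts[c(1, nGrid)] <- 1
  M <- matrix(0, nrow(Q), ncol(Q))
  for (i in seq_len(nGrid)) M <- M + wts[i] * (Pt(ss[i]) %*% C %*% Pt(t - ss[i]))
  M <- M * h / 3
  M / Pt(t)
}

#' Phylogenetic conservation model from a Newick tree
#'
#' Converts a rooted tree with branch lengths into a factor graph: one
#' 4-state variable per node, a uniform prior factor at the root, and one
#' pairwise factor per branch carrying [jc69Transition()] probabilities.
#' Each branch factor's score table is [jc69ExpectedSubstitutions()], so the
#' full-data score of a configuration is its total substitution load and the
#' statistic of record is the posterior expected load given a leaf column
#' ([phyloColumnStatistic()]); low values indicate conservation, high values
#' acceleration.
#'
#' @param newick a Newick string or path to a Newick file, or an
#'   `ape::phylo` object; must be rooted with branch lengths.
#' @param muTotal total substitution rate per unit branch length (default 1:
#'   branch lengths are in expected substitutions per site).
#' @return a [PhyloModel-class].
#' @export
phyloModel <- function(newick, muTotal = 1) {
  tree <- if (inherits(newick, "phylo")) newick
          else if (is.character(newick) && length(newick) == 1L && file.exists(newick))
            ape::read.tree(newick)
          else ape::read.tree(text = newick)
  if (is.null(tree)) stopf("could not parse Newick input")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) stopf("branch lengths must be positive")
  nTip <- length(tree$tip.label)
  if (nTip < 2L) stopf("tree must have at least 2 leaves")
  nNode <- nTip + tree$Nnode
  root <- nTip + 1L
  nodeName <- character(nNode)
  nodeName[seq_len(nTip)] <- tree$tip.label
  nodeName[(nTip + 1L):nNode] <- sprintf("node%d", (nTip + 1L):nNode)

  ## declare the root variable first so inference roots the traversal there
  ord <- c(root, setdiff(seq_len(nNode), root))
  vars <- setNames(rep(4L, nNode), nodeName[ord])
  facs <- list(root_prior = list(scope = nodeName[root],
                                 potential = rep(0.25, 4)))
  scs <- list(root_prior = rep(0, 4))
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    bl <- tree$edge.length[i]
    fn <- sprintf("branch_%s", nodeName[chi])
    facs[[fn]] <- list(scope = c(nodeName[par], nodeName[chi]),
                       potential = jc69Transition(muTotal, bl))
    scs[[fn]] <- jc69ExpectedSubstitutions(muTotal, bl)
  }
  g <- factorGraph(vars, facs)
  sc <- scoreSpec(g, scs)
  leafIndex <- setNames(match(tree$tip.label, g@varNames), tree$tip.label)
  new("PhyloModel", graph = g, score = sc, tree = tree,
      muTotal = muTotal, leafIndex = leafIndex)
}

## vectorized pruning over many columns; columns: nTip x C integer (1..4)
## or character (A,C,G,T) matrix. Returns posterior expected substitution
## load per column. Identical to posteriorExpectedScore on the clamped
## graph, but linear-algebra-vectorized across columns.
#' Posterior expected substitutions for alignment columns
#'
#' Evaluates the conservation statistic - the expected total number of
#' substitutions on the tree given the observed bases at the leaves - for
#' many alignment columns at once, by Felsenstein pruning with per-branch
#' conditional expected-substitution tables folded in on the downward pass.
#'
#' @param model a [PhyloModel-class].
#' @param columns nTips x C matrix of leaf states, integer 1..4 or
#'   characters A,C,G,T; row names, if present, must match the tip labels
#'   (rows are reordered to them).
#' @return numeric vector of length C.
#' @export
phyloColumnStatistic <- function(model, columns) {
  tree <- model@tree
  nTip <- length(tree$tip.label)
  if (is.character(columns))
    columns <- matrix(match(columns, DNA_ALPHABET), nrow = nrow(columns))
  columns <- as.matrix(columns)
  if (nrow(columns) != nTip)
    stopf("columns must have one row per tip (%d)", nTip)
  if (!is.null(rownames(columns)))
    columns <- columns[tree$tip.label, , drop = FALSE]
  if (anyNA(columns) || any(columns < 1L | columns > 4L))
    stopf("leaf states must be in 1..4 (or A,C,G,T)")
  C <- ncol(columns)
  nNode <- nTip + tree$Nnode
  root <- nTip + 1L
  kids <- vector("list", nNode)
  Pmat <- vector("list", nNode)   # transition matrix of the branch above node
  Emat <- vector("list", nNode)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    kids[[par]] <- c(kids[[par]], chi)
    Pmat[[chi]] <- jc69Transition(model@muTotal, tree$edge.length[i])
    Emat[[chi]] <- jc69ExpectedSubstitutions(model@muTotal, tree$edge.length[i])
  }
  ## preorder from the root, then reversed: children before parents
  po <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    po <- c(po, v); stack <- c(kids[[v]], stack)
  }
  po <- rev(po)

  ## upward partial likelihoods L[[v]]: 4 x C
  L <- vector("list", nNode)
  for (v in po) {
    if (v <= nTip) {
      M <- matrix(0, 4, C)
      M[cbind(columns[v, ], seq_len(C))] <- 1
      L[[v]] <- M
    } else {
      M <- matrix(1, 4, C)
      for (w in kids[[v]]) M <- M * (Pmat[[w]] %*% L[[w]])
      L[[v]] <- M
    }
  }
  lik <- colSums(L[[root]] * 0.25)
  if (any(lik <= 0)) stopf("zero posterior mass for some column")

  ## downward messages U[[v]]: 4 x C, prior and everything outside v's subtree
  U <- vector("list", nNode)
  U[[root]] <- matrix(0.25, 4, C)
  stat <- numeric(C)
  for (v in rev(po)) {       # parents before children
    if (v > nTip) for (w in kids[[v]]) {
      Uw <- U[[v]]
      for (u in kids[[v]]) if (u != w) Uw <- Uw * (Pmat[[u]] %*% L[[u]])
      ## joint posterior of (v = a, w = b) per column is
      ## Uw[a,] * P[a,b] * L[[w]][b,] / lik; fold in E[N | a, b]
      Pw <- Pmat[[w]]; Ew <- Emat[[w]]; Lw <- L[[w]]
      acc <- numeric(C)
      for (a in 1:4) for (b in 1:4)
        acc <- acc + Uw[a, ] * (Pw[a, b] * Ew[a, b]) * Lw[b, ]
      stat <- stat + acc / lik
      U[[w]] <- crossprod(Pw, Uw)
    }
  }
  unname(stat)
}

#' Simulate alignment columns under the null
#'
#' Draws independent columns from the phylogenetic null model: a uniform
#' root base propagated down every branch with JC69 transition
#' probabilities.
#'
#' @param model a [PhyloModel-class].
#' @param n number of columns.
#' @param seed integer RNG seed.
#' @return nTips x n integer matrix of leaf states (rows named by tip).
#' @export
simulateAlignmentColumns <- function(model, n, seed = 1L) {
  set.seed(as.integer(seed))
  tree <- model@tree
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  root <- nTip + 1L
  state <- matrix(0L, nNode, n)
  state[root, ] <- sample.int(4L, n, replace = TRUE)
  ## process edges parent-before-child: order by preorder rank of the child
  kids <- vector("list", nNode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  pre <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    pre <- c(pre, v); stack <- c(kids[[v]], stack)
  }
  ord <- order(match(tree$edge[, 2L], pre))
  for (i in ord) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    P <- jc69Transition(model@muTotal, tree$edge.length[i])
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(n)
    state[chi, ] <- 1L + as.integer(rowSums(u > cum[state[par, ], , drop = FALSE]))
  }
  out <- state[seq_len(nTip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Tail probability of the phylogenetic conservation statistic
#'
#' Significance of the posterior expected substitution load by sampling:
#' naive for `alpha = 0`, importance sampling on the tilted full-data
#' distribution otherwise (the statistic is a function of the leaves only,
#' so this is latent-variable importance sampling). For conservation the
#' lower tail is significant; acceleration uses the upper tail.
#'
#' @param model a [PhyloModel-class].
#' @param t statistic threshold.
#' @param tailSide `"lower"` (conservation, default) or `"upper"`
#'   (acceleration).
#' @param alpha tilting strength; `NULL` picks the saddlepoint-guided value
#'   for the full-data score at t (negative for lower tails).
#' @param n number of sampled columns.
#' @param seed integer RNG seed.
#' @return a [TailEstimate-class].
#' @export
phyloTail <- function(model, t, tailSide = c("lower", "upper"), alpha = NULL,
                      n = 10000L, seed = 1L) {
  tailSide <- match.arg(tailSide)
  if (is.null(alpha))
    alpha <- saddlepointGuidedAlpha(model@graph, model@score, t)
  latentStatisticTail(model@graph, model@score,
                      observedVars = names(model@leafIndex),
                      statistic = function(m) phyloColumnStatistic(model, t(m)),
                      t = t, alpha = alpha, n = n, seed = seed,
                      tailSide = tailSide)
}

#' Poisson approximation for the maximum score over scan offsets
#'
#' A motif of length k can start at M = L - k + 1 offsets in a sequence of
#' length L. When threshold exceedances are rare and the motif is not
#' low-complexity, the number of offsets exceeding t is approximately
#' Poisson with mean M p, so P(max > t) is approximately 1 - exp(-M p).
#'
#' @param singleMatchP tail probability of a single match exceeding the
#'   threshold.
#' @param seqLength sequence length L.
#' @param motifLength motif length k <= L.
#' @param bothStrands double the number of offsets to account for scoring
#'   the reverse-complement strand as well (documented approximation).
#' @return the approximate P(max score > t); a warning is issued when
#'   M p > 0.5, where the approximation degrades.
#' @export
maxScorePvalue <- function(singleMatchP, seqLength, motifLength,
                           bothStrands = FALSE) {
  if (singleMatchP < 0 || singleMatchP > 1) stopf("singleMatchP must be in [0, 1]")
  if (seqLength < motifLength) stopf("seqLength must be >= motifLength")
  M <- (seqLength - motifLength + 1) * (if (bothStrands) 2 else 1)
  if (M * singleMatchP > 0.5)
    warnf("M * p = %.3g > 0.5: the Poisson approximation is unreliable here",
          M * singleMatchP)
  -expm1(-M * singleMatchP)
}

#' Simulate sequences from a motif model's background chain
#'
#' Draws i.i.d. sequences of arbitrary length from the (homogeneous)
#' background Markov chain of a [markovModel()] (or the i.i.d. background of
#' a [pwmModel()]), for scan-statistic simulations.
#'
#' @param model a [MotifModel-class].
#' @param n number of sequences.
#' @param seqLength length of each sequence (>= the model order).
#' @param seed integer RNG seed.
#' @return n x seqLength integer matrix of symbols (1-based).
#' @export
simulateMarkovSequences <- function(model, n, seqLength, seed = 1L) {
  set.seed(as.integer(seed))
  A <- model@alphabetSize
  r <- max(model@order, 1L)
  K <- as.integer(A^r)
  if (model@order == 0L) {
    init <- model@background
    trans <- matrix(model@background, 1L, A, byrow = TRUE)[rep(1L, K), , drop = FALSE]
  } else {
    init <- model@background$initial
    trans <- model@background$transitions
    if (is.list(trans)) stopf("background must be homogeneous for simulation")
  }
  if (seqLength < r) stopf("seqLength must be >= the model order")
  seqs <- matrix(0L, n, seqLength)
  ## first r symbols from the initial distribution over tuples
  z <- sample.int(K, n, replace = TRUE, prob = init)
  zz <- z - 1L
  for (j in r:1L) { seqs[, j] <- zz %% A + 1L; zz <- zz %/% A }
  if (seqLength > r) {
    cum <- t(apply(trans, 1L, cumsum))
    ctx <- z
    for (pos in (r + 1L):seqLength) {
      u <- stats::runif(n)
      nxt <- 1L + as.integer(rowSums(u > cum[ctx, , drop = FALSE]))
      seqs[, pos] <- nxt
      ctx <- (ctx - 1L) %% as.integer(A^(r - 1L)) * A + nxt  # shift context
    }
  }
  seqs
}

#' Motif log-odds scores of every scan window
#'
#' Scores every length-N window of each input sequence under the model's
#' foreground/background log-odds. Offsets are 0-based half-open: column j
#' holds the window starting at offset j - 1.
#'
#' @param model a [MotifModel-class] of motif length N.
#' @param seqs n x L integer matrix of symbols (1-based), L >= N.
#' @return n x (L - N + 1) matrix of window scores.
#' @export
motifScanScores <- function(model, seqs) {
  N <- model@motifLength
  A <- model@alphabetSize
  L <- ncol(seqs)
  if (L < N) stopf("sequences shorter than the motif")
  n <- nrow(seqs)
  r <- model@order
  if (r == 0L) {
    sc <- vapply(seq_len(N), function(i) log(model@foreground[, i] / model@background),
                 numeric(4))
    out <- matrix(0, n, L - N + 1L)
    for (off in seq_len(L - N + 1L))
      for (i in seq_len(N))
        out[, off] <- out[, off] + sc[seqs[, off + i - 1L], i]
    return(out)
  }
  ## compound-state encoding per position: z_j encodes symbols j..j+r-1
  K <- as.integer(A^r)
  M <- N - r + 1L                       # compound variables per window
  zpos <- matrix(0L, n, L - r + 1L)
  enc <- seqs[, 1L:r, drop = FALSE] %*% A^((r - 1L):0L) - sum(A^((r - 1L):0L)) + 1L
  zpos[, 1L] <- as.integer(enc)
  if (L - r >= 1L) for (j in 2L:(L - r + 1L))
    zpos[, j] <- (zpos[, j - 1L] - 1L) %% as.integer(A^(r - 1L)) * A +
                 seqs[, j + r - 1L]
  initScore <- as.vector(modelScore(model)@tables[[1L]])
  stepScores <- modelScore(model)@tables[-1L]
  out <- matrix(0, n, L - N + 1L)
  for (off in seq_len(L - N + 1L)) {
    acc <- initScore[zpos[, off]]
    if (M > 1L) for (i in seq_len(M - 1L)) {
      tab <- stepScores[[i]]
      acc <- acc + tab[cbind(zpos[, off + i - 1L], zpos[, off + i])]
    }
    out[, off] <- acc
  }
  out
}
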