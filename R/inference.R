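# Sum-product and max/min-sum message passing on tree factor graphs.
# All messages live in log space; zero mass is -Inf, never NaN. The traversal
# roots each connected component at its lowest-index (first declared)
# variable, with ties broken by declaration order, so repeated runs are
# bit-identical.

## Rooted traversal of the (forest) factor graph.
## Returns:
##   roots        integer vector of root variable indices (one per component)
##   facParent    int: parent variable of each factor
##   facChildren  list: child variables of each factor (scope minus parent)
##   varChildFacs list: child factors of each variable
##   varParentFac int: parent factor of each variable (NA at roots)
##   facOrderUp   factors in leaf-to-root (post) order
fgStructure <- function(g) {
  nv <- length(g@varNames); nf <- length(g@facNames)
  varFacs <- vector("list", nv)
  for (a in seq_len(nf)) for (v in g@scopes[[a]])
    varFacs[[v]] <- c(varFacs[[v]], a)

  facParent <- integer(nf)
  facChildren <- vector("list", nf)
  varChildFacs <- rep(list(integer(0)), nv)
  varParentFac <- rep(NA_integer_, nv)
  seenV <- logical(nv); seenF <- logical(nf)
  roots <- integer(0)
  facOrderUp <- integer(0)

  for (r in seq_len(nv)) {
    if (seenV[r]) next
    roots <- c(roots, r)
    seenV[r] <- TRUE
    ## BFS over the bipartite graph assigning parent/child roles
    queue <- r
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (a in varFacs[[v]]) {
        if (seenF[a]) next
        seenF[a] <- TRUE
        facParent[a] <- v
        varChildFacs[[v]] <- c(varChildFacs[[v]], a)
        kids <- setdiff(g@scopes[[a]], v)
        facChildren[[a]] <- kids
        for (w in kids) {
          seenV[w] <- TRUE
          varParentFac[w] <- a
          queue <- c(queue, w)
        }
      }
    }
    facOrderUp <- c(facOrderUp, postOrderFactors(r, varChildFacs, facChildren))
  }
  list(roots = roots, facParent = facParent, facChildren = facChildren,
       varChildFacs = varChildFacs, varParentFac = varParentFac,
       facOrderUp = facOrderUp)
}

## Explicit post-order (children before parent) over factors of one component.
postOrderFactors <- function(root, varChildFacs, facChildren) {
  out <- integer(0)
  ## iterative: process variable -> for each child factor, recurse into its
  ## child variables first, then emit the factor.
  stack <- list(list(kind = "var", id = root))
  emit <- integer(0)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node$kind == "var") {
      for (a in varChildFacs[[node$id]])
        stack[[length(stack) + 1L]] <- list(kind = "fac", id = a)
    } else {
      emit <- c(emit, node$id)
      for (w in facChildren[[node$id]])
        stack[[length(stack) + 1L]] <- list(kind = "var", id = w)
    }
  }
  rev(emit)
}

## Upward (leaf-to-root) log messages.
## msgFup[[a]]: vector over states of facParent[a].
## msgVup[[v]]: sum of msgFup over v's child factors (0 if none).
upwardMessages <- function(g, str = fgStructure(g), tables = NULL) {
  ## `tables` defaults to log potentials; callers may supply tilted tables.
  logpot <- tables %||% lapply(g@potentials, function(p) {
    out <- log(p); out[p == 0] <- -Inf; out
  })
  nv <- length(g@varNames); nf <- length(g@facNames)
  msgFup <- vector("list", nf)
  msgVup <- lapply(g@varCards, function(k) numeric(k))
  doneV <- logical(nv)
  for (a in str$facOrderUp) {
    T <- logpot[[a]]
    sc <- g@scopes[[a]]
    ppos <- match(str$facParent[a], sc)
    for (w in str$facChildren[[a]]) {
      if (!doneV[w]) { # fold child-factor messages into the variable message
        for (b in str$varChildFacs[[w]]) msgVup[[w]] <- msgVup[[w]] + msgFup[[b]]
        doneV[w] <- TRUE
      }
      T <- addAlongDim(T, msgVup[[w]], match(w, sc))
    }
    msgFup[[a]] <- logSumExpExcept(T, ppos)
  }
  for (v in seq_len(nv)) if (!doneV[v]) {
    for (b in str$varChildFacs[[v]]) msgVup[[v]] <- msgVup[[v]] + msgFup[[b]]
    doneV[v] <- TRUE
  }
  list(msgFup = msgFup, msgVup = msgVup, logpot = logpot)
}

#' Exact inference by sum-product message passing
#'
#' Computes the log partition function, the marginal distribution of every
#' variable, and the joint marginal over every factor's scope, with one
#' leaf-to-root and one root-to-leaf sweep. Cost is linear in the number of
#' nodes and in the potential-table sizes.
#'
#' @param graph a [FactorGraph-class].
#' @return an [InferenceResult-class].
#' @examples
#' g <- factorGraph(c(x = 2L), list(a = list(scope = "x", potential = c(.7, .3))))
#' sumProduct(g)@varMarginals$x
#' @export
sumProduct <- function(graph) {
  str <- fgStructure(graph)
  up <- upwardMessages(graph, str)
  nv <- length(graph@varNames); nf <- length(graph@facNames)

  ## log Z: product over components of the root belief mass
  logZ <- 0
  for (r in str$roots) {
    lz <- logSumExp(up$msgVup[[r]])
    if (lz == -Inf) stopf("graph has zero partition function")
    logZ <- logZ + lz
  }

  ## Downward messages. msgFdown[[v]]: from v's parent factor into v
  ## (zero vector at roots). Computed root-to-leaves, i.e. factors in
  ## reverse post-order.
  msgFdown <- lapply(graph@varCards, function(k) numeric(k))
  for (a in rev(str$facOrderUp)) {
    p <- str$facParent[a]
    sc <- graph@scopes[[a]]
    ## message from parent variable p into factor a: downward message into p
    ## plus upward messages from p's other child factors
    toFac <- msgFdown[[p]]
    for (b in str$varChildFacs[[p]]) if (b != a) toFac <- toFac + up$msgFup[[b]]
    base <- addAlongDim(up$logpot[[a]], toFac, match(p, sc))
    for (w in str$facChildren[[a]])
      base <- addAlongDim(base, up$msgVup[[w]], match(w, sc))
    for (w in str$facChildren[[a]]) {
      wpos <- match(w, sc)
      ## remove w's own upward contribution by rebuilding without it
      Tw <- addAlongDim(up$logpot[[a]], toFac, match(p, sc))
      for (u in str$facChildren[[a]]) if (u != w)
        Tw <- addAlongDim(Tw, up$msgVup[[u]], match(u, sc))
      msgFdown[[w]] <- logSumExpExcept(Tw, wpos)
    }
  }

  normalizeLog <- function(b) {
    lz <- logSumExp(b)
    if (lz == -Inf) rep(NaN, length(b)) else exp(b - lz)
  }
  varMarg <- vector("list", nv)
  for (v in seq_len(nv)) {
    b <- msgFdown[[v]] + up$msgVup[[v]]
    varMarg[[v]] <- normalizeLog(b)
  }
  names(varMarg) <- graph@varNames

  facMarg <- vector("list", nf)
  for (a in seq_len(nf)) {
    p <- str$facParent[a]
    sc <- graph@scopes[[a]]
    toFac <- msgFdown[[p]]
    for (b in str$varChildFacs[[p]]) if (b != a) toFac <- toFac + up$msgFup[[b]]
    T <- addAlongDim(up$logpot[[a]], toFac, match(p, sc))
    for (w in str$facChildren[[a]])
      T <- addAlongDim(T, up$msgVup[[w]], match(w, sc))
    lz <- logSumExp(T)
    M <- exp(T - lz)
    dim(M) <- dim(up$logpot[[a]]) %||% length(up$logpot[[a]])
    facMarg[[a]] <- M
  }
  names(facMarg) <- graph@facNames

  new("InferenceResult", logZ = logZ, varMarginals = varMarg,
      facMarginals = facMarg)
}

## max-sum (or min-sum via negation) over positive-mass configurations,
## summed across components. `tables` must carry -Inf on zero-mass states.
maxSumTotal <- function(g, tables) {
  str <- fgStructure(g)
  nv <- length(g@varNames)
  msgFup <- vector("list", length(g@facNames))
  msgVup <- lapply(g@varCards, function(k) numeric(k))
  doneV <- logical(nv)
  for (a in str$facOrderUp) {
    T <- tables[[a]]
    sc <- g@scopes[[a]]
    for (w in str$facChildren[[a]]) {
      if (!doneV[w]) {
        for (b in str$varChildFacs[[w]]) msgVup[[w]] <- msgVup[[w]] + msgFup[[b]]
        doneV[w] <- TRUE
      }
      T <- addAlongDim(T, msgVup[[w]], match(w, sc))
    }
    ppos <- match(str$facParent[a], sc)
    msgFup[[a]] <- if (length(sc) == 1L) as.vector(T) else apply(T, ppos, max)
  }
  for (v in seq_len(nv)) if (!doneV[v]) {
    for (b in str$varChildFacs[[v]]) msgVup[[v]] <- msgVup[[v]] + msgFup[[b]]
  }
  tot <- 0
  for (r in str$roots) {
    m <- max(msgVup[[r]])
    if (m == -Inf) stopf("graph has zero partition function")
    tot <- tot + m
  }
  tot
}

#' Exact score range
#'
#' Minimum and maximum of the additive score S(x) over configurations with
#' positive probability mass, by min-sum/max-sum message passing. Used to
#' guard the saddlepoint solve: the saddlepoint equation has no solution for
#' thresholds outside this range.
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class] for the graph.
#' @return numeric of length 2: `c(sMin, sMax)`.
#' @export
scoreRange <- function(graph, score) {
  checkScoreMatches(graph, score)
  maskInf <- function(gtab, pot, fill) {
    out <- gtab
    out[pot == 0] <- fill
    out
  }
  tabsMax <- mapply(maskInf, score@tables, graph@potentials,
                    MoreArgs = list(fill = -Inf), SIMPLIFY = FALSE)
  ## for the minimum, negate scores; zero-mass states must stay excluded
  tabsMin <- mapply(function(gtab, pot) {
    out <- -gtab
    out[pot == 0] <- -Inf
    out
  }, score@tables, graph@potentials, SIMPLIFY = FALSE)
  smax <- maxSumTotal(graph, tabsMax)
  smin <- -maxSumTotal(graph, tabsMin)
  c(sMin = smin, sMax = smax)
}

#' Posterior expectation of the score given evidence
#'
#' Clamps the observed variables and returns sum_a E\[g_a(X_a) | evidence\],
#' computed from the factor marginals of the clamped graph. For a
#' [phyloModel()] this is the expected number of substitutions on the tree
#' given a column of present-day bases.
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param evidence named integer vector of observed states (may be empty, in
#'   which case the prior expectation kappa'(0) is returned).
#' @return a single numeric value.
#' @export
posteriorExpectedScore <- function(graph, score, evidence = integer(0)) {
  checkScoreMatches(graph, score)
  g2 <- if (length(evidence)) setEvidence(graph, evidence) else graph
  inf <- sumProduct(g2)
  tot <- 0
  for (a in seq_along(score@tables)) {
    m <- inf@facMarginals[[a]]
    gt <- score@tables[[a]]
    pos <- m > 0
    tot <- tot + sum(m[pos] * gt[pos])
  }
  tot
}
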