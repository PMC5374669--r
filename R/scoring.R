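# Score specifications, exponential tilting, and exact kappa / kappa' /
# kappa'' by a moment-semiring extension of sum-product.
#
# A message is a triple per variable state: (log-mass, mean_part,
# second_part), where mean_part = (sum of mass * subtree-score) / mass and
# second_part the analogous second moment. The product of independent parts
# (combining subtrees) is, in this scaled representation,
#   logz = logz1 + logz2, mu = mu1 + mu2, q = q1 + 2 mu1 mu2 + q2,
# and summation over states is mass-weighted averaging of the parts. One
# leaf-to-root pass yields Z~(theta), E_theta[S] and E_theta[S^2] exactly.

#' Construct a score specification
#'
#' @param graph the [FactorGraph-class] the scores are for.
#' @param tables named (or graph-ordered) list of numeric arrays, one per
#'   factor, each shaped like the factor's potential table. `-Inf` entries
#'   are allowed; `+Inf` only on zero-potential states.
#' @return a [ScoreSpec-class].
#' @examples
#' g <- factorGraph(c(y = 2L), list(u = list(scope = "y", potential = c(.7, .3))))
#' s <- scoreSpec(g, list(u = c(0, 1)))   # S = Y, a Bernoulli score
#' scoreMeanVariance(g, s)
#' @export
scoreSpec <- function(graph, tables) {
  nf <- length(graph@facNames)
  if (length(tables) != nf)
    stopf("need one score table per factor (%d expected, %d given)",
          nf, length(tables))
  if (!is.null(names(tables))) {
    idx <- match(graph@facNames, names(tables))
    if (anyNA(idx)) stopf("score tables missing for factor '%s'",
                          graph@facNames[which(is.na(idx))[1L]])
    tables <- tables[idx]
  }
  out <- vector("list", nf)
  for (a in seq_len(nf)) {
    pot <- graph@potentials[[a]]
    gt <- tables[[a]]
    d <- dim(pot)
    if (length(gt) != length(pot))
      stopf("score table for factor '%s' has %d entries, expected %d",
            graph@facNames[a], length(gt), length(pot))
    gt <- array(as.numeric(gt), dim = d)
    if (any(is.nan(gt)))
      stopf("score table for factor '%s' contains NaN", graph@facNames[a])
    if (any(gt == Inf & pot > 0))
      stopf("factor '%s': +Inf score on a positive-mass state", graph@facNames[a])
    out[[a]] <- gt
  }
  new("ScoreSpec", facNames = graph@facNames, tables = out)
}

checkScoreMatches <- function(graph, score) {
  if (!identical(score@facNames, graph@facNames) ||
      length(score@tables) != length(graph@potentials))
    stopf("score specification does not match the graph's factors")
  for (a in seq_along(score@tables))
    if (length(score@tables[[a]]) != length(graph@potentials[[a]]))
      stopf("score table for factor '%s' has the wrong shape", graph@facNames[a])
  invisible(TRUE)
}

#' Negative log-likelihood score
#'
#' Sets g_a = -log f_a so that S(x) = -log P(x) for a normalized graph: high
#' scores flag configurations that are unlikely under the model. States with
#' zero potential receive `+Inf`; they are never realized under the null.
#'
#' @param graph a [FactorGraph-class]; a warning is issued if it is not
#'   normalized (the score is then -log of the unnormalized mass).
#' @return a [ScoreSpec-class].
#' @export
logLikelihoodScore <- function(graph) {
  if (!isNormalized(graph, 1e-6))
    warnf("graph is not normalized; score is -log of unnormalized mass")
  tabs <- lapply(graph@potentials, function(p) {
    out <- -log(p)
    out[p == 0] <- Inf
    out
  })
  scoreSpec(graph, setNames(tabs, graph@facNames))
}

#' Foreground/background log-odds score
#'
#' Sets g_a = log(f_a^fg / f_a^bg), so that S(x) is the log likelihood ratio
#' of the foreground model to the background model. Both graphs must share
#' structure (variables, cardinalities, scopes). States with positive
#' foreground but zero background mass would give unbounded odds and are
#' rejected; states excluded by both models get score 0.
#'
#' @param bg background (null) [FactorGraph-class].
#' @param fg foreground [FactorGraph-class] with identical structure.
#' @return a [ScoreSpec-class] for the background graph.
#' @export
logOddsScore <- function(bg, fg) {
  if (!identical(bg@varNames, fg@varNames) ||
      !identical(bg@varCards, fg@varCards) ||
      !identical(bg@facNames, fg@facNames) ||
      !identical(bg@scopes, fg@scopes))
    stopf("foreground and background graphs differ in structure")
  tabs <- vector("list", length(bg@facNames))
  for (a in seq_along(tabs)) {
    fb <- bg@potentials[[a]]; ff <- fg@potentials[[a]]
    if (any(fb == 0 & ff > 0))
      stopf("factor '%s': foreground mass on a zero-background state (unbounded odds)",
            bg@facNames[a])
    g <- log(ff) - log(fb)
    g[ff == 0 & fb == 0] <- 0
    tabs[[a]] <- g
  }
  scoreSpec(bg, setNames(tabs, bg@facNames))
}

#' Exponentially tilted graph
#'
#' Multiplies each potential by exp(alpha * g_a), yielding an (unnormalized)
#' factor graph with the same structure whose normalized distribution is the
#' exponentially tilted measure of the score. With a log-odds score,
#' alpha interpolates from the background (alpha = 0) to the foreground
#' (alpha = 1) model and beyond. Tables are built in log space; a factor is
#' rescaled by a constant only if its entries would otherwise leave the
#' double range (harmless: sampling and conditionals are scale-invariant).
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param alpha tilting strength; 0 returns the graph unchanged.
#' @return the tilted [FactorGraph-class].
#' @export
tiltGraph <- function(graph, score, alpha) {
  checkScoreMatches(graph, score)
  if (alpha == 0) return(graph)
  pots <- vector("list", length(graph@potentials))
  for (a in seq_along(pots)) {
    lp <- log(graph@potentials[[a]]) + alpha * score@tables[[a]]
    lp[graph@potentials[[a]] == 0] <- -Inf
    m <- max(lp[is.finite(lp)], -Inf)
    if (m > 700 || (is.finite(m) && m < -700)) lp <- lp - m
    pot <- exp(lp)
    dim(pot) <- dim(graph@potentials[[a]])
    pots[[a]] <- pot
  }
  out <- graph
  out@potentials <- pots
  validObject(out)
  out
}

## One moment-semiring pass: exact log Z~(theta), E_theta[S], E_theta[S^2].
## Per factor joint state the contribution triple is
##   (log f + theta g, g, g^2);
## child triples multiply in via the product rule and states are summed out
## by mass-weighted averaging.
cgfPass <- function(graph, score, theta, str = fgStructure(graph)) {
  nf <- length(graph@facNames); nv <- length(graph@varNames)
  LZf <- vector("list", nf); MUf <- vector("list", nf); QBf <- vector("list", nf)
  LZv <- lapply(graph@varCards, function(k) numeric(k))
  MUv <- lapply(graph@varCards, function(k) numeric(k))
  QBv <- lapply(graph@varCards, function(k) numeric(k))
  doneV <- logical(nv)

  foldVar <- function(w) {
    ## combine w's child-factor triples (product rule, scaled representation)
    lz <- numeric(graph@varCards[w]); A <- lz; B <- lz
    for (b in str$varChildFacs[[w]]) {
      lz <- lz + LZf[[b]]
      B <- B + (QBf[[b]] - MUf[[b]]^2)
      A <- A + MUf[[b]]
    }
    list(lz = lz, mu = A, qb = B + A^2)
  }

  for (a in str$facOrderUp) {
    sc <- graph@scopes[[a]]
    pot <- graph@potentials[[a]]
    gt <- score@tables[[a]]
    LZ <- log(pot) + theta * gt
    LZ[pot == 0] <- -Inf
    if (any(LZ == Inf, na.rm = TRUE))
      stopf("tilted mass diverges at theta = %g (infinite score on a positive-mass state)", theta)
    LZ[is.nan(LZ)] <- -Inf
    MU <- gt; MU[LZ == -Inf] <- 0
    A <- MU; B <- array(0, dim = dim(pot))
    for (w in str$facChildren[[a]]) {
      if (!doneV[w]) { fw <- foldVar(w); LZv[[w]] <- fw$lz; MUv[[w]] <- fw$mu
                       QBv[[w]] <- fw$qb; doneV[w] <- TRUE }
      wpos <- match(w, sc)
      LZ <- addAlongDim(LZ, LZv[[w]], wpos)
      A  <- addAlongDim(A, MUv[[w]], wpos)
      B  <- addAlongDim(B, QBv[[w]] - MUv[[w]]^2, wpos)
    }
    QB <- B + A^2
    MU <- A
    MU[LZ == -Inf] <- 0; QB[LZ == -Inf] <- 0
    ## sum over all scope dims except the parent: mass-weighted averaging
    ppos <- match(str$facParent[a], sc)
    lzOut <- logSumExpExcept(LZ, ppos)
    k <- graph@varCards[str$facParent[a]]
    muOut <- numeric(k); qbOut <- numeric(k)
    if (length(sc) == 1L) {
      lzOut <- as.vector(LZ); muOut <- as.vector(MU); qbOut <- as.vector(QB)
    } else {
      W <- exp(addAlongDim(LZ, -lzOut, ppos))   # conditional weights
      W[LZ == -Inf] <- 0
      muOut <- as.vector(apply(W * MU, ppos, sum))
      qbOut <- as.vector(apply(W * QB, ppos, sum))
      muOut[lzOut == -Inf] <- 0; qbOut[lzOut == -Inf] <- 0
    }
    LZf[[a]] <- as.vector(lzOut); MUf[[a]] <- muOut; QBf[[a]] <- qbOut
  }

  logZ <- 0; m1 <- 0; m2c <- 0  # m2c accumulates centered-part bookkeeping
  ## combine components: totals add for logZ; S is the sum of independent
  ## component scores, so means add and second moments follow the product rule.
  muTot <- 0; qbTot <- 0
  for (r in str$roots) {
    if (!doneV[r]) { fr <- foldVar(r); LZv[[r]] <- fr$lz; MUv[[r]] <- fr$mu
                     QBv[[r]] <- fr$qb; doneV[r] <- TRUE }
    lz <- logSumExp(LZv[[r]])
    if (lz == -Inf) stopf("tilted graph has zero mass at theta = %g", theta)
    w <- exp(LZv[[r]] - lz); w[LZv[[r]] == -Inf] <- 0
    mu <- sum(w * MUv[[r]]); qb <- sum(w * QBv[[r]])
    logZ <- logZ + lz
    qbTot <- qbTot + (qb - mu^2)
    muTot <- muTot + mu
  }
  qbTot <- qbTot + muTot^2
  list(logZ = logZ, m1 = muTot, m2 = qbTot)
}

#' Exact cumulant generating function of the score
#'
#' Computes kappa(theta) = log Z~(theta) - log Z, kappa'(theta) (the tilted
#' mean of S) and kappa''(theta) (the tilted variance) exactly, in a single
#' leaf-to-root pass of moment-triple messages per evaluation. This is the
#' quantity the saddlepoint machinery and the importance weights are built
#' from.
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param theta tilting parameter.
#' @return a [CgfResult-class].
#' @examples
#' g <- factorGraph(c(y = 2L), list(u = list(scope = "y", potential = c(.7, .3))))
#' s <- scoreSpec(g, list(u = c(0, 1)))
#' cgfMoments(g, s, 0)   # kappa = 0, kappa' = 0.3, kappa'' = 0.21
#' @export
cgfMoments <- function(graph, score, theta) {
  checkScoreMatches(graph, score)
  str <- fgStructure(graph)
  at <- cgfPass(graph, score, theta, str)
  a0 <- if (theta == 0) at else cgfPass(graph, score, 0, str)
  new("CgfResult", theta = theta, kappa = at$logZ - a0$logZ,
      kappa1 = at$m1, kappa2 = max(at$m2 - at$m1^2, 0))
}

#' Mean and variance of the score under the null
#'
#' Convenience wrapper returning `c(mean = kappa'(0), variance = kappa''(0))`.
#'
#' @inheritParams cgfMoments
#' @return named numeric of length 2.
#' @export
scoreMeanVariance <- function(graph, score) {
  r <- cgfMoments(graph, score, 0)
  c(mean = r@kappa1, variance = r@kappa2)
}

#' Variance ratio: a dependence diagnostic
#'
#' The ratio of the variance of the total score to the sum of the variances
#' of the per-factor contributions (the variance the score would have were
#' the contributions independent). Equals 1 on fully disconnected graphs;
#' deviations measure the correlation induced by shared variables.
#'
#' @inheritParams cgfMoments
#' @return a single numeric value.
#' @export
varianceRatio <- function(graph, score) {
  checkScoreMatches(graph, score)
  num <- cgfMoments(graph, score, 0)@kappa2
  inf <- sumProduct(graph)
  den <- 0
  for (a in seq_along(score@tables)) {
    m <- inf@facMarginals[[a]]
    gt <- score@tables[[a]]
    pos <- m > 0
    e1 <- sum(m[pos] * gt[pos]); e2 <- sum(m[pos] * gt[pos]^2)
    den <- den + (e2 - e1^2)
  }
  if (den <= 0) stopf("degenerate score: every factor contribution is constant")
  num / den
}
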