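test_that("poisson-binomial model: exact counts, binomial reduction, weights", {
  ## ten fair coins: P(S > 7.5) = (C(10,8)+C(10,9)+C(10,10)) / 2^10
  m <- poissonBinomialModel(rep(0.5, 10))
  g <- modelGraph(m); s <- modelScore(m)
  expect_equal(enumerateTail(g, s, 7.5), 56 / 1024, tolerance = 1e-12)
  expect_equal(convolutionTail(componentDistributions(g, s), 7.5), 56 / 1024,
               tolerance = 1e-12)

  ## identical rates: the full score distribution is Binomial(N, p)
  mb <- poissonBinomialModel(rep(0.3, 12))
  d <- enumerateDistribution(modelGraph(mb), modelScore(mb))
  expect_equal(d@support, as.numeric(0:12))
  expect_equal(d@prob, dbinom(0:12, 12, 0.3), tolerance = 1e-10)

  ## weighted events: support {0,1,2,3} with equal masses
  mw <- poissonBinomialModel(c(0.5, 0.5), s = c(1, 2))
  dw <- enumerateDistribution(modelGraph(mw), modelScore(mw))
  expect_equal(dw@support, as.numeric(0:3))
  expect_equal(dw@prob, rep(0.25, 4), tolerance = 1e-12)

  expect_error(poissonBinomialModel(numeric(0)), "non-empty")
  expect_error(poissonBinomialModel(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("pwm model: neutral motif, enumeration, count handling", {
  ## uniform single-column motif over a uniform background scores zero
  m0 <- pwmModel(matrix(0.25, 4, 1))
  expect_equal(unname(scoreRange(modelGraph(m0), modelScore(m0))), c(0, 0))

  ## 2-column PWM: tail vs direct sum over the 16 dinucleotides
  set.seed(5)
  pfm <- matrix(rgamma(8, 2) + 0.1, 4); pfm <- sweep(pfm, 2, colSums(pfm), "/")
  m2 <- pwmModel(pfm, type = "frequencies")
  g <- modelGraph(m2); s <- modelScore(m2)
  sc16 <- outer(log(4 * pfm[, 1]), log(4 * pfm[, 2]), "+")
  for (t0 in as.numeric(quantile(sc16, c(0.3, 0.8))))
    expect_equal(enumerateTail(g, s, t0), mean(sc16 > t0), tolerance = 1e-12)

  ## counts go through the pseudocount formula
  cts <- matrix(c(8, 0, 2, 0), 4, 1)
  mc <- pwmModel(cts, pseudocount = 0.5)
  expect_equal(unname(mc@foreground[, 1]), (c(8, 0, 2, 0) + 0.5) / 12,
               tolerance = 1e-12)
  expect_error(pwmModel(cts, pseudocount = 0), "pseudocount|zero")
})

test_that("a PWM expressed as an order-1 per-position chain gives identical tails", {
  set.seed(6)
  N <- 4
  pfm <- matrix(rgamma(4 * N, 2) + 0.1, 4); pfm <- sweep(pfm, 2, colSums(pfm), "/")
  mp <- pwmModel(pfm, type = "frequencies")
  ## order-1 chain with context-independent per-position transitions
  trans <- lapply(2:N, function(i) matrix(pfm[, i], 4, 4, byrow = TRUE))
  mm <- markovModel(1, 4, initial = pfm[, 1], transitions = trans, length = N)
  dp <- enumerateDistribution(modelGraph(mp), modelScore(mp))
  dm <- enumerateDistribution(modelGraph(mm), modelScore(mm))
  grid <- as.numeric(quantile(dp@support, c(0.1, 0.5, 0.9, 0.99)))
  for (t0 in grid)
    expect_equal(distributionTail(dm, t0), distributionTail(dp, t0),
                 tolerance = 1e-10)
})

test_that("markov compounding matches direct sequence enumeration", {
  set.seed(7)
  r <- 2; A <- 3; L <- 6
  K <- A^r
  fgInit <- rgamma(K, 2); fgInit <- fgInit / sum(fgInit)
  fgTr <- matrix(rgamma(K * A, 2), K); fgTr <- fgTr / rowSums(fgTr)
  bgInit <- rgamma(K, 5); bgInit <- bgInit / sum(bgInit)
  bgTr <- matrix(rgamma(K * A, 5), K); bgTr <- bgTr / rowSums(bgTr)
  m <- markovModel(r, A, fgInit, fgTr, L, bgInit, bgTr)
  expect_true(isNormalized(modelGraph(m)))

  seqs <- as.matrix(expand.grid(rep(list(1:A), L)))
  enc <- function(s1, s2) (s1 - 1L) * A + s2
  chainLP <- function(init, tr) {
    lp <- log(init[enc(seqs[, 1], seqs[, 2])])
    for (i in 1:(L - r))
      lp <- lp + log(tr[cbind(enc(seqs[, i], seqs[, i + 1]), seqs[, i + 2])])
    lp
  }
  lpBg <- chainLP(bgInit, bgTr); lpFg <- chainLP(fgInit, fgTr)
  sc <- lpFg - lpBg
  expect_equal(sum(exp(lpBg)), 1, tolerance = 1e-12)
  for (q in c(0.9, 0.99, 0.999)) {
    t0 <- as.numeric(quantile(sc, q))
    expect_equal(enumerateTail(modelGraph(m), modelScore(m), t0),
                 sum(exp(lpBg)[sc > t0]), tolerance = 1e-10)
  }
  ## cgf agrees with the direct sum over sequences
  for (th in c(-0.5, 1))
    expect_equal(cgfValue(cgfMoments(modelGraph(m), modelScore(m), th)),
                 log(sum(exp(lpBg + th * sc))), tolerance = 1e-10)

  ## r = 1 is an ordinary first-order chain
  tr1 <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  m1 <- markovModel(1, 2, initial = c(0.6, 0.4), transitions = tr1, length = 3,
                    bgInitial = c(0.5, 0.5),
                    bgTransitions = matrix(0.5, 2, 2))
  s8 <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  lpF <- log(c(0.6, 0.4)[s8[, 1]]) + log(tr1[cbind(s8[, 1], s8[, 2])]) +
    log(tr1[cbind(s8[, 2], s8[, 3])])
  lpB <- log(1 / 8)
  t0 <- median(lpF - lpB)
  expect_equal(enumerateTail(modelGraph(m1), modelScore(m1), t0),
               sum(exp(lpB)[1] * ((lpF - lpB) > t0)), tolerance = 1e-12)
})

test_that("jc69 transition matrices behave like a substitution process", {
  expect_equal(jc69Transition(1, 0), diag(4), ignore_attr = TRUE)
  expect_equal(jc69Transition(1, 1e6), matrix(0.25, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    mu <- runif(1, 0.3, 3); t0 <- runif(1, 0.05, 2)
    P <- jc69Transition(mu, t0)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(P > 0 | t0 == 0))
  }
  expect_error(jc69Transition(1, -0.1), "non-negative")
})

test_that("conditional expected substitutions satisfy their identities", {
  set.seed(9)
  for (i in 1:4) {
    mu <- runif(1, 0.5, 2); t0 <- runif(1, 0.1, 1.5)
    P <- jc69Transition(mu, t0)
    E <- jc69ExpectedSubstitutions(mu, t0)
    ## law of total expectation: sum_b P_ab E[N|a,b] = mu t for every a
    expect_equal(unname(rowSums(P * E)), rep(mu * t0, 4), tolerance = 1e-10)
    ## identity endpoints still carry positive expected substitutions
    expect_true(all(diag(E) > 0))
    ## generic-rate-matrix quadrature fallback agrees with the closed form
    Q <- matrix(mu / 3, 4, 4); diag(Q) <- -mu
    expect_equal(fgtails:::expectedSubstitutionsQuad(Q, t0, 401L), unname(E),
                 tolerance = 1e-8)
  }
  expect_error(jc69ExpectedSubstitutions(1, 0), "positive")
})

test_that("ctmc path simulation validates the jc69 formulas", {
  mu <- 1; t0 <- 0.4; n <- 2e5
  sim <- simulateCTMC(mu, t0, start = 2L, nPaths = n, seed = 17)
  P <- jc69Transition(mu, t0); E <- jc69ExpectedSubstitutions(mu, t0)
  for (b in 1:4) {
    pe <- mean(sim$endState == b)
    expect_lt(abs(pe - P[2, b]), 3 * sqrt(P[2, b] * (1 - P[2, b]) / n) + 1e-12)
    sel <- sim$endState == b
    se <- sd(sim$nSubs[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(sim$nSubs[sel]) - E[2, b]), 3 * se)
  }
  ## unconditional mean is mu t
  expect_lt(abs(mean(sim$nSubs) - mu * t0), 3 * sqrt(mu * t0 / n))
  ## t -> 0: virtually no substitutions
  s0 <- simulateCTMC(1, 1e-6, 1L, 1e4, seed = 3)
  expect_lt(mean(s0$nSubs), 1e-3)
})

test_that("phylo model structure and 2-leaf hand enumeration", {
  m <- phyloModel("(A:0.3,B:0.5);", muTotal = 1)
  g <- modelGraph(m)
  ## one variable per node, one pairwise factor per branch plus the root prior
  expect_length(varNames(g), 3L)
  expect_length(facNames(g), 3L)
  expect_true(isNormalized(g))

  ## statistic for an observed column by direct summation over root states
  PA <- jc69Transition(1, 0.3); PB <- jc69Transition(1, 0.5)
  EA <- jc69ExpectedSubstitutions(1, 0.3); EB <- jc69ExpectedSubstitutions(1, 0.5)
  for (col in list(c(A = 1L, B = 1L), c(A = 2L, B = 4L))) {
    wj <- 0.25 * PA[, col["A"]] * PB[, col["B"]]
    manual <- sum(wj * (EA[, col["A"]] + EB[, col["B"]])) / sum(wj)
    expect_equal(posteriorExpectedScore(g, modelScore(m), col), manual,
                 tolerance = 1e-12)
    cmat <- matrix(col, 2, 1, dimnames = list(c("A", "B"), NULL))
    expect_equal(phyloColumnStatistic(m, cmat), manual, tolerance = 1e-12)
  }
  ## complete identity still scores positive on any tree
  m11 <- phyloModel(extdata("balanced11.nwk"))
  idc <- matrix("A", 11, 1, dimnames = list(m11@tree$tip.label, NULL))
  expect_gt(phyloColumnStatistic(m11, idc), 0)

  expect_error(phyloModel("(A,B);"), "branch lengths")
  expect_error(phyloModel("(A:1);"), "2 leaves|parse")
})

test_that("simulated alignment columns follow the leaf marginals", {
  m <- phyloModel("((A:0.2,B:0.3):0.2,C:0.4);")
  cols <- simulateAlignmentColumns(m, 4e4, seed = 13)
  expect_identical(rownames(cols), m@tree$tip.label)
  ## each leaf is marginally uniform under JC69 with a uniform root
  for (tip in rownames(cols)) {
    fr <- tabulate(cols[tip, ], 4) / ncol(cols)
    expect_lt(max(abs(fr - 0.25)), 4 * sqrt(0.25 * 0.75 / ncol(cols)))
  }
  ## pairwise identity fraction matches the closed-form path probability
  dAB <- 0.2 + 0.3
  pSame <- 0.25 + 0.75 * exp(-4 / 3 * dAB)
  emp <- mean(cols["A", ] == cols["B", ])
  expect_lt(abs(emp - pSame), 4 * sqrt(pSame * (1 - pSame) / ncol(cols)))
})

test_that("max-score significance via the Poisson approximation", {
  expect_equal(maxScorePvalue(0, 200, 16), 0)
  ## first-order expansion for rare matches
  p1 <- 1e-6
  expect_equal(maxScorePvalue(p1, 200, 16), (200 - 16 + 1) * p1,
               tolerance = 1e-3)
  ## reverse-complement scanning doubles the offsets
  expect_equal(maxScorePvalue(p1, 200, 16, bothStrands = TRUE),
               2 * (200 - 16 + 1) * p1, tolerance = 1e-3)
  expect_warning(maxScorePvalue(0.01, 200, 16), "unreliable")
  expect_error(maxScorePvalue(1.2, 200, 16), "\\[0, 1\\]")
})

test_that("scan scores equal per-window rescoring", {
  ## order-0: window sums of per-position log-odds
  set.seed(14)
  pfm <- matrix(rgamma(4 * 3, 2) + 0.2, 4); pfm <- sweep(pfm, 2, colSums(pfm), "/")
  mp <- pwmModel(pfm, type = "frequencies")
  seqs <- matrix(sample(1:4, 5 * 8, replace = TRUE), 5, 8)
  sc <- motifScanScores(mp, seqs)
  expect_equal(dim(sc), c(5L, 6L))
  lo <- log(4 * pfm)
  for (i in 1:5) for (off in 1:6)
    expect_equal(sc[i, off],
                 sum(lo[cbind(seqs[i, off:(off + 2)], 1:3)]), tolerance = 1e-12)

  ## order-2: every window score equals the model score of that window
  mm <- syntheticMarkovMotif(length = 6, order = 2, seed = 15)
  seqs2 <- simulateMarkovSequences(mm, 50, 10, seed = 16)
  sc2 <- motifScanScores(mm, seqs2)
  for (i in c(1, 25)) for (off in c(1, 3, 5)) {
    win <- seqs2[i, off:(off + 5)]
    z <- vapply(1:5, function(j) (win[j] - 1L) * 4L + win[j + 1L], numeric(1))
    st <- matrix(z, 1)
    colnames(st) <- varNames(modelGraph(mm))
    expect_equal(sc2[i, off],
                 as.numeric(fgtails:::configScores(modelGraph(mm),
                                                   modelScore(mm), st)),
                 tolerance = 1e-12)
  }

  ## simulated background sequences follow the background transitions
  tr <- mm@background$transitions
  z <- (seqs2[, 3] - 1L) * 4L + seqs2[, 4]   # context at positions 3:4
  emp <- mean(seqs2[z == z[1], 5] == 1L)
  expect_lt(abs(emp - tr[z[1], 1]), 6 * sqrt(0.25 / max(sum(z == z[1]), 1)) + 0.2)
})
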