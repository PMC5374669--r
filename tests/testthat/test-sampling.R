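test_that("forward sampling reproduces the target distribution", {
  ## Bernoulli frequency within 4 binomial sigmas
  b <- bernoulliScored(0.3)
  st <- forwardSample(b$graph, 1e5, seed = 4)
  phat <- mean(st[, "y"] == 2L)
  expect_lt(abs(phat - 0.3), 4 * sqrt(0.3 * 0.7 / 1e5))

  ## two-variable joint vs enumeration, chi-square goodness of fit
  fa <- c(0.5, 0.5); fb <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  g <- twoVarGraph(fa, fb)
  st2 <- forwardSample(g, 2e4, seed = 5)
  obs <- table(factor(st2[, 1], 1:2), factor(st2[, 2], 1:2))
  expect_gt(chisq.test(as.vector(obs), p = as.vector(twoVarJoint(fa, fb)))$p.value,
            1e-4)

  ## clamped variables sample at the clamped state only
  gc <- setEvidence(g, c(x1 = 2L))
  st3 <- forwardSample(gc, 500, seed = 6)
  expect_true(all(st3[, "x1"] == 2L))
})

test_that("importance weights: unit at alpha 0, exact product identity", {
  m <- poissonBinomialModel(c(0.2, 0.5, 0.7, 0.4))
  g <- modelGraph(m); s <- modelScore(m)
  e0 <- importanceSampleTail(g, s, 1.5, alpha = 0, n = 200, seed = 1)
  expect_identical(estMethod(e0), "naive")
  expect_true(all(sampleBatch(e0)@logWeights == 0))

  ## w = P(x) / P~_alpha(x) recomputed per sample from raw potentials
  al <- 0.8
  est <- importanceSampleTail(g, s, 1.5, alpha = al, n = 500, seed = 2)
  batch <- sampleBatch(est)
  tg <- tiltGraph(g, s, al)
  st <- forwardSample(tg, 500, seed = 2)
  logZ <- sumProduct(g)@logZ; logZt <- sumProduct(tg)@logZ
  lpRaw <- lpTilt <- numeric(500)
  for (a in seq_along(facNames(g))) {
    sc <- match(scopes(g)[[a]], varNames(g))
    strides <- fgtails:::colMajorStrides(varCards(g)[sc])
    idx <- rep(1L, 500)
    for (j in seq_along(sc)) idx <- idx + (st[, sc[j]] - 1L) * strides[j]
    lpRaw <- lpRaw + log(as.vector(potentials(g)[[a]])[idx])
    lpTilt <- lpTilt + log(as.vector(potentials(tg)[[a]])[idx])
  }
  manual <- (lpRaw - logZ) - (lpTilt - logZt)
  expect_equal(batch@logWeights, manual, tolerance = 1e-10)
})

test_that("saddlepoint-guided alpha puts the proposal mean at the threshold", {
  m <- poissonBinomialModel(rep(0.2, 30))
  g <- modelGraph(m); s <- modelScore(m)
  expect_equal(saddlepointGuidedAlpha(g, s, 6), 0, tolerance = 1e-8)  # t = mean
  t0 <- 14.5
  al <- saddlepointGuidedAlpha(g, s, t0)
  expect_identical(al, solveSaddlepoint(g, s, t0)@theta)
  expect_equal(cgfMean(cgfMoments(g, s, al)), t0, tolerance = 1e-7)
  ## the sampled mean score under the tilted proposal sits at the threshold
  st <- forwardSample(tiltGraph(g, s, al), 2e4, seed = 3)
  sc <- fgtails:::configScores(g, s, st)
  expect_lt(abs(mean(sc) - t0), 4 * sd(sc) / sqrt(2e4))
})

test_that("estimates are unbiased across seeds for naive and guided tilts", {
  m <- poissonBinomialModel(rep(0.2, 30))
  g <- modelGraph(m); s <- modelScore(m)
  t0 <- 10.5                                     # p ~ 5e-3: reachable naively
  exact <- pbinom(10, 30, 0.2, lower.tail = FALSE)
  alStar <- saddlepointGuidedAlpha(g, s, t0)
  for (al in c(0, alStar / 2, alStar)) {
    ests <- vapply(1:200, function(sd0)
      pValue(importanceSampleTail(g, s, t0, alpha = al, n = 500,
                                  seed = 10000 + sd0)), numeric(1))
    seMean <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - exact), 4 * seMean)
  }
})

test_that("sampling is reproducible given the seed", {
  m <- poissonBinomialModel(rep(0.2, 30))
  e1 <- importanceSampleTail(modelGraph(m), modelScore(m), 12.5, alpha = 1,
                             n = 1000, seed = 99)
  e2 <- importanceSampleTail(modelGraph(m), modelScore(m), 12.5, alpha = 1,
                             n = 1000, seed = 99)
  expect_identical(logPValue(e1), logPValue(e2))
  expect_identical(sampleBatch(e1)@scores, sampleBatch(e2)@scores)
  e3 <- importanceSampleTail(modelGraph(m), modelScore(m), 12.5, alpha = 1,
                             n = 1000, seed = 100)
  expect_false(identical(logPValue(e1), logPValue(e3)))
})

test_that("latent-statistic sampling: reduction and exact enumeration", {
  ## with every variable observed and the plain score as statistic, the
  ## estimate equals importance_sample_tail on the same draw
  m <- poissonBinomialModel(c(0.3, 0.6, 0.2))
  g <- modelGraph(m); s <- modelScore(m)
  stat <- function(mm) as.numeric(fgtails:::configScores(g, s, mm))
  e1 <- latentStatisticTail(g, s, varNames(g), stat, t = 1.5, alpha = 0.5,
                            n = 400, seed = 12)
  e2 <- importanceSampleTail(g, s, 1.5, alpha = 0.5, n = 400, seed = 12)
  expect_equal(logPValue(e1), logPValue(e2), tolerance = 1e-12)

  ## 3-leaf tree, naive draws vs exact enumeration of the leaf-pattern law
  pm <- phyloModel("((A:0.4,B:0.5):0.3,C:0.6);")
  pg <- modelGraph(pm); ps <- modelScore(pm)
  pats <- as.matrix(expand.grid(A = 1:4, B = 1:4, C = 1:4))
  pPat <- apply(pats, 1, function(r)
    exp(sumProduct(setEvidence(pg, setNames(as.integer(r), colnames(pats))))@logZ))
  statPat <- phyloColumnStatistic(pm, t(pats))
  ## place the threshold between two distinct support atoms near the 10% point
  sv <- sort(unique(round(statPat, 9)))   # group numerically equal atoms
  cum <- vapply(sv, function(v) sum(pPat[statPat <= v + 1e-12]), numeric(1))
  k <- which(cum >= 0.1)[1L]
  t0 <- mean(sv[k:(k + 1L)])
  exact <- cum[k]
  est <- phyloTail(pm, t0, alpha = 0, n = 3e4, seed = 21)
  expect_lt(abs(pValue(est) - exact), 4 * standardError(est))

  ## default statistic (posterior expected score) agrees with the
  ## vectorized phylo implementation
  eDef <- latentStatisticTail(pg, ps, c("A", "B", "C"), NULL, t = t0,
                              alpha = 0, n = 300, seed = 33, tailSide = "lower")
  eVec <- latentStatisticTail(pg, ps, c("A", "B", "C"),
                              function(mm) phyloColumnStatistic(pm, t(mm)),
                              t = t0, alpha = 0, n = 300, seed = 33,
                              tailSide = "lower")
  expect_equal(logPValue(eDef), logPValue(eVec), tolerance = 1e-10)
})
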