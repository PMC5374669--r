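test_that("likelihood and log-odds scores take their defining forms", {
  g <- factorGraph(c(x = 2L), list(u = list(scope = "x", potential = c(0.7, 0.3))))
  s <- logLikelihoodScore(g)
  expect_equal(as.vector(scoreTables(s)$u), -log(c(0.7, 0.3)), tolerance = 1e-12)

  ## uniform unary scores log 2 everywhere
  gu <- factorGraph(c(x = 2L), list(u = list(scope = "x", potential = c(0.5, 0.5))))
  expect_equal(as.vector(scoreTables(logLikelihoodScore(gu))$u), rep(log(2), 2))

  ## two-variable graph: S(x) = -log p(x) for all four configurations
  g2 <- twoVarGraph()
  s2 <- logLikelihoodScore(g2)
  en <- fgtails:::enumerateConfigurations(g2, s2)
  expect_equal(en$S, -en$logP, tolerance = 1e-12)

  ## fg = bg log-odds vanishes identically
  expect_true(all(vapply(scoreTables(logOddsScore(g2, g2)),
                         function(x) all(x == 0), logical(1))))

  ## PWM column vs uniform background: g = log(4 f)
  f <- c(0.97, 0.01, 0.01, 0.01)
  bgG <- factorGraph(c(p1 = 4L), list(u = list(scope = "p1", potential = rep(0.25, 4))))
  fgG <- factorGraph(c(p1 = 4L), list(u = list(scope = "p1", potential = f)))
  expect_equal(as.vector(scoreTables(logOddsScore(bgG, fgG))$u), log(4 * f),
               tolerance = 1e-12)

  ## foreground mass on a zero-background state is unbounded odds
  z0 <- factorGraph(c(x = 2L), list(u = list(scope = "x", potential = c(1, 0))))
  z1 <- factorGraph(c(x = 2L), list(u = list(scope = "x", potential = c(0.5, 0.5))))
  expect_error(logOddsScore(z0, z1), "unbounded")

  ## structural mismatch
  expect_error(logOddsScore(g2, g), "structure")
})

test_that("score spec construction enforces the infinity rules", {
  g <- factorGraph(c(x = 2L), list(u = list(scope = "x", potential = c(0.7, 0.3))))
  expect_error(scoreSpec(g, list(u = c(Inf, 1))), "\\+Inf")
  expect_error(scoreSpec(g, list(u = c(NaN, 1))), "NaN")
  expect_error(scoreSpec(g, list(u = c(1, 2, 3))), "entries")
  ## +Inf is fine on a zero-mass state
  g0 <- factorGraph(c(x = 2L), list(u = list(scope = "x", potential = c(1, 0))))
  expect_s4_class(scoreSpec(g0, list(u = c(0, Inf))), "ScoreSpec")
})

test_that("tilting reweights potentials by exp(alpha g)", {
  b <- bernoulliScored(0.3)
  ## closed form: unary becomes (0.7, 0.3 e^theta)
  tg <- tiltGraph(b$graph, b$score, 0.9)
  expect_equal(as.vector(potentials(tg)$u), c(0.7, 0.3 * exp(0.9)),
               tolerance = 1e-12)
  ## alpha = 0 returns the graph unchanged
  expect_identical(potentials(tiltGraph(b$graph, b$score, 0)), potentials(b$graph))
  ## alpha = 1 under a log-odds score recovers the foreground tables
  set.seed(3)
  fb <- matrix(rgamma(4, 2), 2); fb <- fb / sum(fb)
  bg <- twoVarGraph(); fg <- twoVarGraph(fa = c(0.4, 0.6), fb = fb)
  sc <- logOddsScore(bg, fg)
  tg1 <- tiltGraph(bg, sc, 1)
  expect_equal(potentials(tg1)$a, potentials(fg)$a, tolerance = 1e-12)
  expect_equal(potentials(tg1)$b, potentials(fg)$b, tolerance = 1e-12)
})

test_that("cgf matches closed forms, enumeration, and finite differences", {
  b <- bernoulliScored(0.3)
  r0 <- cgfMoments(b$graph, b$score, 0)
  expect_equal(cgfValue(r0), 0)
  expect_equal(cgfMean(r0), 0.3, tolerance = 1e-12)
  expect_equal(cgfVariance(r0), 0.21, tolerance = 1e-12)
  for (th in c(-1, 0.5, 2))
    expect_equal(cgfValue(cgfMoments(b$graph, b$score, th)),
                 log(0.7 + 0.3 * exp(th)), tolerance = 1e-12)

  for (seed in 1:6) {
    fx <- randomTreeFixture(sample(2:6, 1), maxStates = 4, seed = 300 + seed)
    g <- modelGraph(fx); s <- modelScore(fx)
    for (th in c(-2, -0.5, 0, 0.5, 2)) {
      r <- cgfMoments(g, s, th); e <- enumerateCgf(g, s, th)
      expect_equal(cgfValue(r), e$kappa, tolerance = 1e-9)
      expect_equal(cgfMean(r), e$kappa1, tolerance = 1e-9)
      expect_equal(cgfVariance(r), e$kappa2, tolerance = 1e-8)
      expect_gt(cgfVariance(r), 0)       # strict convexity, non-degenerate score
    }
    ## kappa' strictly increasing over the theta grid
    k1 <- vapply(c(-2, -0.5, 0, 0.5, 2),
                 function(th) cgfMean(cgfMoments(g, s, th)), numeric(1))
    expect_true(all(diff(k1) > 0))
    ## centered finite differences of kappa reproduce kappa' and kappa''
    h <- 1e-5
    for (th in c(-0.5, 0.5)) {
      km <- cgfValue(cgfMoments(g, s, th - h))
      kp <- cgfValue(cgfMoments(g, s, th + h))
      k0 <- cgfValue(cgfMoments(g, s, th))
      expect_equal((kp - km) / (2 * h), cgfMean(cgfMoments(g, s, th)),
                   tolerance = 1e-4)
      expect_equal((kp - 2 * k0 + km) / h^2, cgfVariance(cgfMoments(g, s, th)),
                   tolerance = 1e-3)
    }
  }

  ## additivity across disconnected components
  fxa <- randomTreeFixture(3, seed = 1); fxb <- randomTreeFixture(3, seed = 2)
  ga <- modelGraph(fxa); gb <- modelGraph(fxb)
  vb <- setNames(varCards(gb), paste0("b_", varNames(gb)))
  merged <- factorGraph(
    c(varCards(ga), vb),
    c(mapply(function(sc, pot) list(scope = sc, potential = pot),
             scopes(ga), potentials(ga), SIMPLIFY = FALSE),
      setNames(mapply(function(sc, pot)
        list(scope = paste0("b_", sc), potential = pot),
        scopes(gb), potentials(gb), SIMPLIFY = FALSE),
        paste0("b_", facNames(gb)))))
  tb <- scoreTables(modelScore(fxb))
  names(tb) <- paste0("b_", names(tb))
  mergedScore <- scoreSpec(merged, c(scoreTables(modelScore(fxa)), tb))
  for (th in c(-1, 0.7))
    expect_equal(cgfValue(cgfMoments(merged, mergedScore, th)),
                 cgfValue(cgfMoments(ga, modelScore(fxa), th)) +
                   cgfValue(cgfMoments(gb, modelScore(fxb), th)),
                 tolerance = 1e-10)
})

test_that("score mean and variance wrapper", {
  mb <- poissonBinomialModel(rep(0.5, 10))
  expect_equal(unname(scoreMeanVariance(modelGraph(mb), modelScore(mb))),
               c(5, 2.5), tolerance = 1e-12)
  mp <- poissonBinomialModel(c(0.1, 0.2, 0.3))
  expect_equal(unname(scoreMeanVariance(modelGraph(mp), modelScore(mp))),
               c(0.6, 0.09 + 0.16 + 0.21), tolerance = 1e-12)
  mw <- poissonBinomialModel(c(0.1, 0.2, 0.3), s = c(2, 3, 5))
  expect_equal(unname(scoreMeanVariance(modelGraph(mw), modelScore(mw)))[1],
               sum(c(2, 3, 5) * c(0.1, 0.2, 0.3)), tolerance = 1e-12)
})

test_that("variance ratio measures dependence between factor contributions", {
  ## fully disconnected graph: VR = 1
  m <- poissonBinomialModel(c(0.2, 0.5, 0.8))
  expect_equal(varianceRatio(modelGraph(m), modelScore(m)), 1, tolerance = 1e-10)
  ## one binary variable scored twice: V[2X] / (2 V[X]) = 2
  g <- factorGraph(c(x = 2L),
                   list(u = list(scope = "x", potential = c(0.5, 0.5)),
                        v = list(scope = "x", potential = c(1, 1))))
  s <- scoreSpec(g, list(u = c(0, 1), v = c(0, 1)))
  expect_equal(varianceRatio(g, s), 2, tolerance = 1e-10)
  ## chain fixture vs enumeration oracle
  fx <- balancedTreeFixture(4, 1, 3, coupling = 0.5, seed = 8)
  g2 <- modelGraph(fx); s2 <- modelScore(fx)
  num <- enumerateCgf(g2, s2, 0)$kappa2
  en <- fgtails:::enumerateConfigurations(g2, s2)
  P <- exp(en$logP - fgtails:::logSumExp(en$logP))
  den <- 0
  for (a in seq_along(facNames(g2))) {
    sc <- match(scopes(g2)[[a]], varNames(g2))
    strides <- fgtails:::colMajorStrides(varCards(g2)[sc])
    idx <- rep(1L, length(P))
    for (j in seq_along(sc)) idx <- idx + (en$states[, sc[j]] - 1L) * strides[j]
    gv <- as.vector(scoreTables(s2)[[a]])[idx]
    den <- den + (sum(P * gv^2) - sum(P * gv)^2)
  }
  expect_equal(varianceRatio(g2, s2), num / den, tolerance = 1e-8)
  ## constant scores are degenerate
  sConst <- scoreSpec(g, list(u = c(1, 1), v = c(0, 0)))
  expect_error(varianceRatio(g, sConst), "degenerate")
})
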