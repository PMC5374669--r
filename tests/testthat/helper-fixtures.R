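# shared test helpers; fixtures themselves come from the package's seeded
# generators

relErr <- function(est, truth) abs(est - truth) / abs(truth)

## the two-variable example graph: unary a on x1, pairwise b on (x1, x2)
twoVarGraph <- function(fa = c(0.5, 0.5),
                        fb = matrix(c(0.9, 0.2, 0.1, 0.8), 2)) {
  factorGraph(c(x1 = 2L, x2 = 2L),
              list(a = list(scope = "x1", potential = fa),
                   b = list(scope = c("x1", "x2"), potential = fb)))
}

## brute-force joint table of the two-variable graph
twoVarJoint <- function(fa, fb) {
  m <- outer(fa, rep(1, 2)) * fb
  m / sum(m)
}

bernoulliScored <- function(p = 0.3) {
  g <- factorGraph(c(y = 2L), list(u = list(scope = "y", potential = c(1 - p, p))))
  list(graph = g, score = scoreSpec(g, list(u = c(0, 1))))
}

extdata <- function(f) system.file("extdata", f, package = "fgtails")
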