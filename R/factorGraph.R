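# graph construction, evidence clamping, normalization check

#' Build and validate a discrete factor graph
#'
#' Constructs a [FactorGraph-class] from variable declarations and factor
#' tables and validates it: the bipartite variable/factor graph must be
#' cycle-free, every potential entry non-negative with at least one strictly
#' positive entry per table, table shapes must match the scope cardinalities,
#' and every variable must appear in at least one scope. Unnormalized graphs
#' are accepted; probabilistic quantities are always relative to the
#' partition function Z.
#'
#' @param variables named integer vector of state-space sizes, e.g.
#'   `c(x1 = 2, x2 = 2)`; declaration order is kept and the first variable
#'   roots the message-passing traversal.
#' @param factors named list; each element is a list with `scope` (character
#'   vector of variable names) and `potential` (numeric array with
#'   `dim = varCards[scope]`, or a flat vector in R's column-major order; a
#'   matrix for a 2-ary scope).
#' @return a validated [FactorGraph-class].
#' @examples
#' ## two binary variables: a unary factor on x1 and a pairwise factor
#' g <- factorGraph(
#'   c(x1 = 2L, x2 = 2L),
#'   list(a = list(scope = "x1", potential = c(0.5, 0.5)),
#'        b = list(scope = c("x1", "x2"),
#'                 potential = matrix(c(0.9, 0.2, 0.1, 0.8), 2))))
#' sumProduct(g)
#' @export
factorGraph <- function(variables, factors) {
  if (is.null(names(variables)) || any(names(variables) == ""))
    stopf("variables must be a named vector of cardinalities")
  varNames <- names(variables)
  varCards <- as.integer(variables)
  if (is.null(names(factors)) || any(names(factors) == ""))
    stopf("factors must be a named list")
  facNames <- names(factors)
  scopes <- vector("list", length(factors))
  pots <- vector("list", length(factors))
  for (a in seq_along(factors)) {
    fc <- factors[[a]]
    if (!is.list(fc) || is.null(fc$scope) || is.null(fc$potential))
      stopf("factor '%s' needs 'scope' and 'potential'", facNames[a])
    if (length(fc$scope) == 0L)
      stopf("factor '%s': arity-0 factors are not allowed", facNames[a])
    idx <- match(fc$scope, varNames)
    if (anyNA(idx))
      stopf("factor '%s': scope references undeclared variable '%s'",
            facNames[a], fc$scope[which(is.na(idx))[1L]])
    cards <- varCards[idx]
    pot <- fc$potential
    if (is.null(dim(pot))) {
      if (length(pot) != prod(cards))
        stopf("factor '%s': potential has %d entries, scope needs %d",
              facNames[a], length(pot), prod(cards))
      pot <- array(as.numeric(pot), dim = cards)
    } else {
      pot <- array(as.numeric(pot), dim = dim(pot))
    }
    scopes[[a]] <- idx
    pots[[a]] <- pot
  }
  new("FactorGraph", varNames = varNames, varCards = varCards,
      facNames = facNames, scopes = scopes, potentials = pots)
}

#' Clamp observed variables
#'
#' Returns a graph in which every state other than the observed one carries
#' zero mass for each observed variable, implemented by zeroing the
#' corresponding potential slices; graph structure (variables, factors,
#' scopes) is unchanged, and since score tables are untouched the score of
#' any surviving configuration is unchanged too. Clamping is idempotent and
#' commutes across disjoint variable sets.
#'
#' @param graph a [FactorGraph-class].
#' @param evidence named integer vector mapping variable names to observed
#'   state indices (1-based).
#' @return the clamped [FactorGraph-class].
#' @examples
#' g <- factorGraph(
#'   c(x1 = 2L, x2 = 2L),
#'   list(a = list(scope = "x1", potential = c(0.5, 0.5)),
#'        b = list(scope = c("x1", "x2"),
#'                 potential = matrix(c(0.9, 0.2, 0.1, 0.8), 2))))
#' sumProduct(setEvidence(g, c(x2 = 1L)))@logZ  # log sum_x1 fa(x1) fb(x1, 1)
#' @export
setEvidence <- function(graph, evidence) {
  if (length(evidence) == 0L) return(graph)
  if (is.null(names(evidence)) || any(names(evidence) == ""))
    stopf("evidence must be a named vector")
  if (anyDuplicated(names(evidence)))
    stopf("evidence names a variable more than once")
  vi <- match(names(evidence), graph@varNames)
  if (anyNA(vi))
    stopf("evidence references unknown variable '%s'",
          names(evidence)[which(is.na(vi))[1L]])
  st <- as.integer(evidence)
  bad <- which(st < 1L | st > graph@varCards[vi])
  if (length(bad))
    stopf("evidence state %d out of range for variable '%s' (%d states)",
          st[bad[1L]], names(evidence)[bad[1L]], graph@varCards[vi[bad[1L]]])
  pots <- graph@potentials
  for (k in seq_along(vi)) {
    v <- vi[k]
    for (a in seq_along(graph@scopes)) {
      pos <- match(v, graph@scopes[[a]])
      if (is.na(pos)) next
      pot <- pots[[a]]
      d <- dim(pot)
      keep <- slice.index(pot, pos) == st[k]
      pot[!keep] <- 0
      pots[[a]] <- pot
    }
  }
  out <- graph
  out@potentials <- pots
  validObject(out)
  out
}

#' Is the graph normalized?
#'
#' A factor graph is normalized when its partition function Z (the sum over
#' all configurations of the product of potentials) equals one; only then is
#' the product of potentials itself a probability distribution.
#'
#' @param graph a [FactorGraph-class].
#' @param tolerance allowed |Z - 1|.
#' @return `TRUE` iff |Z - 1| <= tolerance.
#' @export
isNormalized <- function(graph, tolerance = 1e-8) {
  abs(exp(sumProduct(graph)@logZ) - 1) <= tolerance
}
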