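# Analytical tail approximations. p-values are carried in log space
# end-to-end; the linear form is materialized only for display.

newTailEstimate <- function(threshold, logP, method, thetaAlpha = NA_real_,
                            se = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                            flags = character(0), batch = NULL) {
  new("TailEstimate", threshold = threshold, logP = min(logP, 0),
      method = method, thetaAlpha = thetaAlpha, se = se,
      ciLow = ciLow, ciHigh = ciHigh, flags = flags, batch = batch)
}

#' Normal approximation to the upper tail
#'
#' Approximates the score distribution by a normal with the score's exact
#' mean and variance and returns P(S > t) = 1 - Phi((t - m) / sqrt(v)).
#' Cheap and adequate near the center, but its relative error grows without
#' bound in the tail.
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param t score threshold.
#' @return a [TailEstimate-class] with method `"normal"`.
#' @export
normalTail <- function(graph, score, t) {
  mv <- scoreMeanVariance(graph, score)
  if (mv[["variance"]] <= 0) stopf("score variance is zero; normal approximation undefined")
  logp <- stats::pnorm((t - mv[["mean"]]) / sqrt(mv[["variance"]]),
                       lower.tail = FALSE, log.p = TRUE)
  newTailEstimate(t, logp, "normal")
}

#' Solve the saddlepoint equation kappa'(theta) = t
#'
#' Safeguarded Newton-Raphson: theta <- theta + (t - kappa') / kappa'',
#' with bisection fallback whenever a step leaves the current bracket.
#' The solution exists and is unique for t strictly inside the score range
#' (kappa is strictly convex for non-degenerate scores); outside it the
#' equation has no solution and an error is raised.
#'
#' @param graph a [FactorGraph-class].
#' @param score a [ScoreSpec-class].
#' @param t score threshold, strictly inside `scoreRange(graph, score)`.
#' @param thetaInit warm start (e.g. the previous saddlepoint when scanning
#'   consecutive thresholds).
#' @param tol convergence tolerance on |kappa'(theta) - t|, relative to
#'   max(1, |t|).
#' @param maxIter iteration cap.
#' @return a [SaddlepointSolution-class].
#' @export
solveSaddlepoint <- function(graph, score, t, thetaInit = 0,
                             tol = 1e-9, maxIter = 100L) {
  rng <- scoreRange(graph, score)
  if (!(t > rng[["sMin"]] && t < rng[["sMax"]]))
    stopf("saddlepoint equation has no solution: t = %g outside score range (%g, %g)",
          t, rng[["sMin"]], rng[["sMax"]])
  str <- fgStructure(graph)
  evalAt <- function(th) cgfPass(graph, score, th, str)
  base <- evalAt(0)
  tolAbs <- tol * max(1, abs(t))

  theta <- thetaInit
  lo <- -Inf; hi <- Inf   # bracket: kappa'(lo) < t < kappa'(hi)
  res <- evalAt(theta)
  for (it in seq_len(maxIter)) {
    k1 <- res$m1
    if (abs(k1 - t) <= tolAbs) {
      cgf <- new("CgfResult", theta = theta, kappa = res$logZ - base$logZ,
                 kappa1 = res$m1, kappa2 = max(res$m2 - res$m1^2, 0))
      return(new("SaddlepointSolution", theta = theta, cgf = cgf,
                 iterations = it))
    }
    if (k1 < t) lo <- max(lo, theta) else hi <- min(hi, theta)
    k2 <- max(res$m2 - res$m1^2, 0)
    prop <- if (k2 > 0) theta + (t - k1) / k2 else NA_real_
    if (!is.finite(prop) || prop <= lo || prop >= hi) {
      ## bisect, growing the bracket geometrically while one side is open
      prop <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
              else if (is.finite(lo)) max(2 * lo, lo + 1)
              else if (is.finite(hi)) min(2 * hi, hi - 1)
              else 0
    }
    theta <- prop
    res <- evalAt(theta)
  }
  stopf("saddlepoint solve did not converge in %d iterations (t = %g, last theta = %g, kappa' = %g)",
        maxIter, t, theta, res$m1)
}

#' Lattice correction factor
#'
#' For scores supported on an arithmetic lattice the continuous saddlepoint
#' formula underestimates the tail; the multiplicative correction
#' K = a|theta| / (1 - exp(-a|theta|)) >= 1 (with K -> 1 as theta -> 0)
#' restores the discrete Esscher sum.
#'
#' @param theta saddlepoint.
#' @param spacing lattice spacing a > 0.
#' @return the correction factor K >= 1.
#' @export
latticeCorrection <- function(theta, spacing) {
  if (spacing <= 0) stopf("lattice spacing must be positive")
  x <- spacing * abs(theta)
  if (x < 1e-12) return(1)
  x / (1 - exp(-x))
}

#' Saddlepoint approximation to the upper tail
#'
#' Evaluates P(S > t) by tilting the score distribution to mean t and
#' approximating the tilted density by a normal:
#' p = exp(kappa(theta) - t theta + theta^2 v / 2) * Phi_bar(theta sqrt(v)),
#' with v = kappa''(theta) and Phi_bar the standard normal upper tail,
#' assembled in log space so the product never over- or underflows.
#'
#' For scores on a declared lattice the strict tail P(S > t) equals the
#' survivor function at the smallest lattice point above t; the formula is
#' then evaluated at that point and multiplied by [latticeCorrection()].
#' Lattice spacing is never auto-detected: the caller declares it.
#'
#' The approximation targets small p-values; estimates above 0.1 are flagged
#' (`p_above_validity_warning`), as is a negative saddlepoint
#' (`theta_negative_warning`), which is returned with a warning rather than
#' refused.
#'
#' @inheritParams solveSaddlepoint
#' @param lattice optional lattice spacing of the score support (e.g. 1 for
#'   unit-weight counts); `NULL` for continuous scores.
#' @return a [TailEstimate-class] with method `"saddlepoint"`.
#' @examples
#' pb <- poissonBinomialModel(rep(0.5, 10))
#' pValue(saddlepointTail(modelGraph(pb), modelScore(pb), 7.5, lattice = 1))
#' @export
saddlepointTail <- function(graph, score, t, lattice = NULL, thetaInit = 0) {
  flags <- character(0)
  tEval <- t
  if (!is.null(lattice)) {
    rng <- scoreRange(graph, score)
    ## smallest lattice point strictly above t, anchored at sMin
    steps <- floor((t - rng[["sMin"]]) / lattice + 1e-9) + 1
    tEval <- rng[["sMin"]] + steps * lattice
    if (tEval >= rng[["sMax"]] - 1e-9 * lattice)
      stopf("threshold t = %g leaves no lattice point strictly below the score maximum", t)
    flags <- c(flags, "lattice_corrected")
  }
  sol <- solveSaddlepoint(graph, score, tEval, thetaInit = thetaInit)
  th <- sol@theta
  v <- sol@cgf@kappa2
  logp <- sol@cgf@kappa - tEval * th + th^2 * v / 2 +
    stats::pnorm(th * sqrt(v), lower.tail = FALSE, log.p = TRUE)
  if (!is.null(lattice)) logp <- logp + log(latticeCorrection(th, lattice))
  if (th < 0) {
    flags <- c(flags, "theta_negative_warning")
    warnf("saddlepoint theta = %g is negative: t is below the mean; the approximation targets the upper tail", th)
  }
  if (logp > log(0.1)) flags <- c(flags, "p_above_validity_warning")
  newTailEstimate(t, logp, "saddlepoint", thetaAlpha = th, flags = flags)
}

#' Lower-tail probability P(S < t)
#'
#' Computed by negating the score tables and the threshold and delegating to
#' the corresponding upper-tail method (strict inequality is preserved:
#' P(S < t) = P(-S > -t)). The returned estimate keeps the original
#' threshold and records the transformation in its flags.
#'
#' @inheritParams saddlepointTail
#' @param method one of `"saddlepoint"`, `"normal"`, `"importance"`,
#'   `"naive"`.
#' @param ... passed to the delegated method ([importanceSampleTail()]
#'   arguments such as `alpha`, `n`, `seed` for the sampling methods).
#' @return a [TailEstimate-class] flagged `lower_tail_negated`.
#' @export
lowerTail <- function(graph, score, t,
                      method = c("saddlepoint", "normal", "importance", "naive"),
                      lattice = NULL, ...) {
  method <- match.arg(method)
  neg <- new("ScoreSpec", facNames = score@facNames,
             tables = lapply(score@tables, function(x) -x))
  est <- switch(method,
    saddlepoint = saddlepointTail(graph, neg, -t, lattice = lattice),
    normal = normalTail(graph, neg, -t),
    importance = importanceSampleTail(graph, neg, -t, ...),
    naive = importanceSampleTail(graph, neg, -t, alpha = 0, ...))
  est@threshold <- t
  est@flags <- c(est@flags, "lower_tail_negated")
  est
}
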