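# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these are the supported surface.

#' @rdname FactorGraph-accessors
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))
#' @rdname FactorGraph-accessors
#' @export
setGeneric("varCards", function(x) standardGeneric("varCards"))
#' @rdname FactorGraph-accessors
#' @export
setGeneric("facNames", function(x) standardGeneric("facNames"))
#' @rdname FactorGraph-accessors
#' @export
setGeneric("scopes", function(x) standardGeneric("scopes"))
#' @rdname FactorGraph-accessors
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))

#' Accessors for factor graphs
#'
#' @param x a [FactorGraph-class] (or [ScoredGraph-class] for the graph/score
#'   accessors).
#' @return `varNames`/`facNames` return character vectors; `varCards` an
#'   integer vector named by variable; `scopes` a named list of character
#'   scope vectors; `potentials` a named list of numeric arrays.
#' @name FactorGraph-accessors
#' @aliases varNames,FactorGraph-method varCards,FactorGraph-method
#'   facNames,FactorGraph-method scopes,FactorGraph-method
#'   potentials,FactorGraph-method
#' @examples
#' g <- factorGraph(c(x = 2L), list(a = list(scope = "x", potential = c(.7, .3))))
#' varNames(g); varCards(g); potentials(g)
NULL

setMethod("varNames", "FactorGraph", function(x) x@varNames)
setMethod("varCards", "FactorGraph", function(x) setNames(x@varCards, x@varNames))
setMethod("facNames", "FactorGraph", function(x) x@facNames)
setMethod("scopes", "FactorGraph", function(x)
  setNames(lapply(x@scopes, function(s) x@varNames[s]), x@facNames))
setMethod("potentials", "FactorGraph", function(x)
  setNames(x@potentials, x@facNames))

#' @rdname ScoredGraph-accessors
#' @export
setGeneric("modelGraph", function(x) standardGeneric("modelGraph"))
#' @rdname ScoredGraph-accessors
#' @export
setGeneric("modelScore", function(x) standardGeneric("modelScore"))
#' @rdname ScoredGraph-accessors
#' @export
setGeneric("scoreTables", function(x) standardGeneric("scoreTables"))

#' Accessors for scored models
#'
#' @param x a [ScoredGraph-class] (including [MotifModel-class] and
#'   [PhyloModel-class]) or a [ScoreSpec-class].
#' @return `modelGraph` the underlying [FactorGraph-class]; `modelScore` the
#'   [ScoreSpec-class]; `scoreTables` the named list of per-factor score
#'   arrays.
#' @name ScoredGraph-accessors
#' @aliases modelGraph,ScoredGraph-method modelScore,ScoredGraph-method
#'   scoreTables,ScoreSpec-method
NULL

setMethod("modelGraph", "ScoredGraph", function(x) x@graph)
setMethod("modelScore", "ScoredGraph", function(x) x@score)
setMethod("scoreTables", "ScoreSpec", function(x) setNames(x@tables, x@facNames))

#' @rdname TailEstimate-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("logPValue", function(x) standardGeneric("logPValue"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("estFlags", function(x) standardGeneric("estFlags"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("estMethod", function(x) standardGeneric("estMethod"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("tiltingParameter", function(x) standardGeneric("tiltingParameter"))
#' @rdname TailEstimate-accessors
#' @export
setGeneric("sampleBatch", function(x) standardGeneric("sampleBatch"))

#' Accessors for tail estimates
#'
#' @param x a [TailEstimate-class].
#' @return `pValue` the estimate on the probability scale; `logPValue` its
#'   natural log (the internal representation); `standardError` the Monte
#'   Carlo standard error or NA; `confInt` a length-2 vector (low, high) or
#'   NAs; `estFlags` the diagnostic flags; `estMethod` the method label;
#'   `tiltingParameter` the saddlepoint theta or IS alpha (NA if none);
#'   `sampleBatch` the [SampleBatch-class] behind a sampling estimate, or
#'   NULL.
#' @name TailEstimate-accessors
#' @aliases pValue,TailEstimate-method logPValue,TailEstimate-method
#'   standardError,TailEstimate-method confInt,TailEstimate-method
#'   estFlags,TailEstimate-method estMethod,TailEstimate-method
#'   tiltingParameter,TailEstimate-method sampleBatch,TailEstimate-method
NULL

setMethod("pValue", "TailEstimate", function(x) exp(x@logP))
setMethod("logPValue", "TailEstimate", function(x) x@logP)
setMethod("standardError", "TailEstimate", function(x) x@se)
setMethod("confInt", "TailEstimate", function(x) c(x@ciLow, x@ciHigh))
setMethod("estFlags", "TailEstimate", function(x) x@flags)
setMethod("estMethod", "TailEstimate", function(x) x@method)
setMethod("tiltingParameter", "TailEstimate", function(x) x@thetaAlpha)
setMethod("sampleBatch", "TailEstimate", function(x) x@batch)

#' @rdname CgfResult-accessors
#' @export
setGeneric("cgfTheta", function(x) standardGeneric("cgfTheta"))
#' @rdname CgfResult-accessors
#' @export
setGeneric("cgfValue", function(x) standardGeneric("cgfValue"))
#' @rdname CgfResult-accessors
#' @export
setGeneric("cgfMean", function(x) standardGeneric("cgfMean"))
#' @rdname CgfResult-accessors
#' @export
setGeneric("cgfVariance", function(x) standardGeneric("cgfVariance"))

#' Accessors for cgf evaluations and saddlepoint solutions
#'
#' @param x a [CgfResult-class] or [SaddlepointSolution-class].
#' @return `cgfTheta` the tilting parameter; `cgfValue` kappa(theta);
#'   `cgfMean` kappa'(theta); `cgfVariance` kappa''(theta).
#' @name CgfResult-accessors
#' @aliases cgfTheta,CgfResult-method cgfValue,CgfResult-method
#'   cgfMean,CgfResult-method cgfVariance,CgfResult-method
#'   cgfTheta,SaddlepointSolution-method cgfValue,SaddlepointSolution-method
#'   cgfMean,SaddlepointSolution-method cgfVariance,SaddlepointSolution-method
NULL

setMethod("cgfTheta", "CgfResult", function(x) x@theta)
setMethod("cgfValue", "CgfResult", function(x) x@kappa)
setMethod("cgfMean", "CgfResult", function(x) x@kappa1)
setMethod("cgfVariance", "CgfResult", function(x) x@kappa2)
setMethod("cgfTheta", "SaddlepointSolution", function(x) x@theta)
setMethod("cgfValue", "SaddlepointSolution", function(x) x@cgf@kappa)
setMethod("cgfMean", "SaddlepointSolution", function(x) x@cgf@kappa1)
setMethod("cgfVariance", "SaddlepointSolution", function(x) x@cgf@kappa2)

setMethod("show", "FactorGraph", function(object) {
  cat(sprintf("FactorGraph: %d variable(s), %d factor(s)\n",
              length(object@varNames), length(object@facNames)))
  cat("  states per variable: ",
      paste(sprintf("%s=%d", head(object@varNames, 8L),
                    head(object@varCards, 8L)), collapse = ", "),
      if (length(object@varNames) > 8L) ", ..." else "", "\n", sep = "")
  arity <- lengths(object@scopes)
  cat(sprintf("  factor arities: %s\n",
              paste(sprintf("%d-ary x%d", sort(unique(arity)),
                            tabulate(arity)[sort(unique(arity))]),
                    collapse = ", ")))
})

setMethod("show", "ScoreSpec", function(object) {
  cat(sprintf("ScoreSpec: score tables for %d factor(s)\n",
              length(object@facNames)))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult: logZ = %.10g; %d variable marginal(s)\n",
              object@logZ, length(object@varMarginals)))
})

setMethod("show", "CgfResult", function(object) {
  cat(sprintf("CgfResult: theta = %g, kappa = %.8g, kappa' = %.8g, kappa'' = %.8g\n",
              object@theta, object@kappa, object@kappa1, object@kappa2))
})

setMethod("show", "SaddlepointSolution", function(object) {
  cat(sprintf("SaddlepointSolution: theta = %.8g (%d Newton iteration(s)), kappa'' = %.8g\n",
              object@theta, object@iterations, object@cgf@kappa2))
})

setMethod("show", "TailEstimate", function(object) {
  cat(sprintf("TailEstimate [%s]: P = %.6g (log %.6g) at t = %g\n",
              object@method, exp(object@logP), object@logP, object@threshold))
  if (!is.na(object@se))
    cat(sprintf("  se = %.3g, 95%% CI [%.6g, %.6g]\n",
                object@se, object@ciLow, object@ciHigh))
  if (!is.na(object@thetaAlpha))
    cat(sprintf("  tilting parameter = %.6g\n", object@thetaAlpha))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SampleBatch", function(object) {
  cat(sprintf("SampleBatch: n = %d, alpha = %g, seed = %d\n",
              object@n, object@alpha, object@seed))
})

setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf("ScoreDistribution: %d support point(s) in [%g, %g]\n",
              length(object@support), min(object@support), max(object@support)))
})

setMethod("show", "ScoredGraph", function(object) {
  cat("ScoredGraph\n")
  show(object@graph)
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel: length %d, alphabet %d, order %d\n",
              object@motifLength, object@alphabetSize, object@order))
})

setMethod("show", "PhyloModel", function(object) {
  cat(sprintf("PhyloModel: %d leaves, %d nodes, muTotal = %g\n",
              length(object@leafIndex), length(object@graph@varNames),
              object@muTotal))
})
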