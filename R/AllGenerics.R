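#' Number of compartments
#'
#' @param x a [HierarchyParams-class] or [ProjectionMatrix-class] object.
#' @return integer, the number of compartments `n`.
#' @export
setGeneric("nCompartments", function(x) standardGeneric("nCompartments"))

#' @rdname nCompartments
#' @export
setMethod("nCompartments", "HierarchyParams", function(x) x@n)

#' @rdname nCompartments
#' @export
setMethod("nCompartments", "ProjectionMatrix", function(x) nrow(x@entries))

#' Accessors for resident hierarchy parameters
#'
#' `divisionRates`, `selfRenewalProb` and `diffProb` return the per-compartment
#' vectors for the dividing compartments `1..n-1`; `removalRate` returns the
#' terminal removal rate `d`; `effectiveSelfRenewal` returns the diagonal
#' rates `r * (p - q)` that drive selection.
#'
#' @param x a [HierarchyParams-class] object.
#' @return numeric vector (length `n-1`) or scalar.
#' @export
setGeneric("divisionRates", function(x) standardGeneric("divisionRates"))

#' @rdname divisionRates
#' @export
setMethod("divisionRates", "HierarchyParams", function(x) x@r)

#' @rdname divisionRates
#' @export
setGeneric("selfRenewalProb", function(x) standardGeneric("selfRenewalProb"))

#' @rdname divisionRates
#' @export
setMethod("selfRenewalProb", "HierarchyParams", function(x) x@p)

#' @rdname divisionRates
#' @export
setGeneric("diffProb", function(x) standardGeneric("diffProb"))

#' @rdname divisionRates
#' @export
setMethod("diffProb", "HierarchyParams", function(x) x@q)

#' @rdname divisionRates
#' @export
setGeneric("removalRate", function(x) standardGeneric("removalRate"))

#' @rdname divisionRates
#' @export
setMethod("removalRate", "HierarchyParams", function(x) x@d)

#' @rdname divisionRates
#' @export
setGeneric("effectiveSelfRenewal",
           function(x) standardGeneric("effectiveSelfRenewal"))

#' @rdname divisionRates
#' @export
setMethod("effectiveSelfRenewal", "HierarchyParams",
          function(x) x@r * (x@p - x@q))

#' Accessors for de-differentiation specifications
#'
#' `dediffMode` returns the mode, `dediffScale` the influx scale `rho`,
#' `redistributingFactor` the factor `kappa`, and `dediffProb` the derived
#' per-compartment probabilities `delta[i] = rho / (2 * r[i])` (which are
#' never stored; `rho` is the single source of truth).
#'
#' @param x a [DedifferentiationSpec-class] object.
#' @param params a [HierarchyParams-class] object (for `dediffProb`).
#' @return character, scalar, or numeric vector of length `n-1`.
#' @export
setGeneric("dediffMode", function(x) standardGeneric("dediffMode"))

#' @rdname dediffMode
#' @export
setMethod("dediffMode", "DedifferentiationSpec", function(x) x@mode)

#' @rdname dediffMode
#' @export
setGeneric("dediffScale", function(x) standardGeneric("dediffScale"))

#' @rdname dediffMode
#' @export
setMethod("dediffScale", "DedifferentiationSpec", function(x) x@rho)

#' @rdname dediffMode
#' @export
setGeneric("redistributingFactor",
           function(x) standardGeneric("redistributingFactor"))

#' @rdname dediffMode
#' @export
setMethod("redistributingFactor", "DedifferentiationSpec", function(x) x@kappa)

#' @rdname dediffMode
#' @export
setGeneric("dediffProb", function(x, params) standardGeneric("dediffProb"))

#' @rdname dediffMode
#' @export
setMethod("dediffProb",
          signature(x = "DedifferentiationSpec", params = "HierarchyParams"),
          function(x, params) x@rho / (2 * params@r))

#' Accessors for projection matrices
#'
#' `matrixTag` returns the structural tag; `as.matrix` the dense entries.
#'
#' @param x a [ProjectionMatrix-class] object.
#' @param ... ignored.
#' @return character tag or numeric matrix.
#' @export
setGeneric("matrixTag", function(x) standardGeneric("matrixTag"))

#' @rdname matrixTag
#' @export
setMethod("matrixTag", "ProjectionMatrix", function(x) x@tag)

#' @rdname matrixTag
#' @export
setMethod("as.matrix", "ProjectionMatrix", function(x, ...) x@entries)

#' Accessors for spectral summaries
#'
#' @param x a [SpectralSummary-class] object.
#' @return scalar, integer index, or numeric vector of length `n`.
#' @export
setGeneric("dominantEigenvalue",
           function(x) standardGeneric("dominantEigenvalue"))

#' @rdname dominantEigenvalue
#' @export
setMethod("dominantEigenvalue", "SpectralSummary", function(x) x@lam)

#' @rdname dominantEigenvalue
#' @export
setGeneric("leftEigenvector", function(x) standardGeneric("leftEigenvector"))

#' @rdname dominantEigenvalue
#' @export
setMethod("leftEigenvector", "SpectralSummary", function(x) x@mu)

#' @rdname dominantEigenvalue
#' @export
setGeneric("rightEigenvector", function(x) standardGeneric("rightEigenvector"))

#' @rdname dominantEigenvalue
#' @export
setMethod("rightEigenvector", "SpectralSummary", function(x) x@eta)

#' @rdname dominantEigenvalue
#' @export
setGeneric("leadingIndex", function(x) standardGeneric("leadingIndex"))

#' @rdname dominantEigenvalue
#' @export
setMethod("leadingIndex", "SpectralSummary", function(x) x@j0)

#' @rdname dominantEigenvalue
#' @export
setGeneric("spectralGap", function(x) standardGeneric("spectralGap"))

#' @rdname dominantEigenvalue
#' @export
setMethod("spectralGap", "SpectralSummary", function(x) x@gap)

#' @rdname dominantEigenvalue
#' @export
setGeneric("isSimple", function(x) standardGeneric("isSimple"))

#' @rdname dominantEigenvalue
#' @export
setMethod("isSimple", "SpectralSummary", function(x) x@simple)

#' Accessors for selection results
#'
#' @param x a [SelectionResult-class] object.
#' @return scalar, character, or data.frame of Gamma terms.
#' @export
setGeneric("deltaLambda", function(x) standardGeneric("deltaLambda"))

#' @rdname deltaLambda
#' @export
setMethod("deltaLambda", "SelectionResult", function(x) x@deltaLambda)

#' @rdname deltaLambda
#' @export
setGeneric("gradientMethod", function(x) standardGeneric("gradientMethod"))

#' @rdname deltaLambda
#' @export
setMethod("gradientMethod", "SelectionResult", function(x) x@method)

#' @rdname deltaLambda
#' @export
setGeneric("gammaTerms", function(x) standardGeneric("gammaTerms"))

#' @rdname deltaLambda
#' @export
setMethod("gammaTerms", "SelectionResult", function(x) x@gammaTerms)

#' @rdname deltaLambda
#' @export
setGeneric("kappaCriticalValue",
           function(x) standardGeneric("kappaCriticalValue"))

#' @rdname deltaLambda
#' @export
setMethod("kappaCriticalValue", "SelectionResult", function(x) x@kappaCritical)

setMethod("show", "HierarchyParams", function(object) {
  cat(sprintf("HierarchyParams: n = %d compartments, d = %g\n",
              object@n, object@d))
  cat("  r:", paste(format(object@r), collapse = " "), "\n")
  cat("  p:", paste(format(object@p), collapse = " "), "\n")
  cat("  q:", paste(format(object@q), collapse = " "), "\n")
  cat("  effective self-renewal r*(p-q):",
      paste(format(effectiveSelfRenewal(object)), collapse = " "), "\n")
})

setMethod("show", "DedifferentiationSpec", function(object) {
  cat(sprintf("DedifferentiationSpec: mode = %s, rho = %g, kappa = %g\n",
              object@mode, object@rho, object@kappa))
})

setMethod("show", "ProjectionMatrix", function(object) {
  cat(sprintf("ProjectionMatrix <%s>, %d x %d (params %s)\n", object@tag,
              nrow(object@entries), ncol(object@entries), object@paramsHash))
  print(object@entries)
})

setMethod("show", "SpectralSummary", function(object) {
  cat(sprintf(
    "SpectralSummary: lambda = %.10g, gap = %.4g, simple = %s, j0 = %s\n",
    object@lam, object@gap, object@simple,
    ifelse(is.na(object@j0), "NA", object@j0)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s, %s]: delta lambda = %.10g (kappa = %g)\n",
              object@mode, object@method, object@deltaLambda, object@kappa))
  if (nrow(object@gammaTerms) > 0) {
    cat("  Gamma terms:\n")
    print(object@gammaTerms, row.names = FALSE)
  }
  if (!is.na(object@kappaCritical))
    cat(sprintf("  kappa* = %.6g\n", object@kappaCritical))
})
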