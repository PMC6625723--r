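gammaRow <- function(params, j, k, l) {
  data.frame(j = as.integer(j), k = as.integer(k), l = as.integer(l),
             value = gammaTerm(params, j, k, l))
}

emptyGammaTable <- function() {
  data.frame(j = integer(), k = integer(), l = integer(), value = numeric())
}

# kappa* stored on a SelectionResult only when it falls in [0,1]
clampKappaStar <- function(kstar) {
  if (!is.na(kstar) && kstar >= 0 && kstar <= 1) kstar else NA_real_
}

#' Closed-form selection gradient, stepwise de-differentiation
#'
#' The first-order change of the dominant eigenvalue per unit
#' de-differentiation scale `rho`, by the leading compartment `j0`:
#' `Gamma[1,1,2]` when `j0 = 1` (kappa-independent, always positive);
#' `Gamma[j0-1,j0,j0-1] + Gamma[j0,j0,j0+1] - kappa` when `1 < j0 < n-1`;
#' `Gamma[n-2,n-1,n-2] - kappa` when `j0 = n-1`.
#'
#' @param params a [HierarchyParams-class] object with a simple, non-negative
#'   dominant eigenvalue.
#' @param kappa redistributing factor in `[0,1]`.
#' @return a [SelectionResult-class] with method `"closed_form"`; the Gamma
#'   terms used are recorded, and `kappaCriticalValue()` holds the zero
#'   crossing when it falls in `[0,1]`.
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' deltaLambda(gradientStepwiseClosed(hp, kappa = 0.5))
#' @export
gradientStepwiseClosed <- function(params, kappa) {
  stopifnot(is(params, "HierarchyParams"))
  stopifnot(kappa >= 0, kappa <= 1)
  lead <- leadingCompartment(params)
  j0 <- lead$j0
  n <- params@n
  if (j0 == 1) {
    gt <- gammaRow(params, 1, 1, 2)
    dl <- gt$value
    kstar <- NA_real_
  } else if (j0 < n - 1) {
    gt <- rbind(gammaRow(params, j0 - 1, j0, j0 - 1),
                gammaRow(params, j0, j0, j0 + 1))
    dl <- sum(gt$value) - kappa
    kstar <- clampKappaStar(sum(gt$value))
  } else {
    gt <- gammaRow(params, n - 2, n - 1, n - 2)
    dl <- gt$value - kappa
    kstar <- clampKappaStar(gt$value)
  }
  new("SelectionResult", deltaLambda = dl, method = "closed_form",
      gammaTerms = gt, kappaCritical = kstar, mode = "stepwise",
      j0 = as.integer(j0), kappa = as.numeric(kappa))
}

#' Closed-form selection gradient, jumpwise de-differentiation
#'
#' By the leading compartment `j0`: the product
#' `prod(Gamma[i,j0,i], i < j0) * prod(Gamma[i-1,j0,i], i > j0)` over dividing
#' compartments when `j0 < n-1` (kappa-independent, always positive), and
#' `prod(Gamma[i,n-1,i], i = 1..n-2) - kappa` when `j0 = n-1`.
#'
#' @inheritParams gradientStepwiseClosed
#' @return a [SelectionResult-class] with method `"closed_form"`.
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' deltaLambda(gradientJumpwiseClosed(hp, kappa = 1))  # -1/3
#' @export
gradientJumpwiseClosed <- function(params, kappa) {
  stopifnot(is(params, "HierarchyParams"))
  stopifnot(kappa >= 0, kappa <= 1)
  lead <- leadingCompartment(params)
  j0 <- lead$j0
  n <- params@n
  if (j0 < n - 1) {
    gt <- emptyGammaTable()
    for (i in seq_len(j0 - 1)) gt <- rbind(gt, gammaRow(params, i, j0, i))
    for (i in seq(j0 + 1, n - 1)) gt <- rbind(gt, gammaRow(params, i - 1, j0, i))
    dl <- prod(gt$value)
    kstar <- NA_real_
  } else {
    gt <- emptyGammaTable()
    for (i in seq_len(n - 2)) gt <- rbind(gt, gammaRow(params, i, n - 1, i))
    dl <- prod(gt$value) - kappa
    kstar <- clampKappaStar(prod(gt$value))
  }
  new("SelectionResult", deltaLambda = dl, method = "closed_form",
      gammaTerms = gt, kappaCritical = kstar, mode = "jumpwise",
      j0 = as.integer(j0), kappa = as.numeric(kappa))
}

#' Closed-form selection gradient for either mode
#'
#' @inheritParams gradientStepwiseClosed
#' @param mode `"stepwise"` or `"jumpwise"`, or a
#'   [DedifferentiationSpec-class] (whose `kappa` is then the default).
#' @param kappa redistributing factor; defaults to the spec's when `mode` is
#'   a [DedifferentiationSpec-class].
#' @return a [SelectionResult-class].
#' @export
gradientClosed <- function(params, mode, kappa = NULL) {
  if (is(mode, "DedifferentiationSpec")) {
    if (is.null(kappa)) kappa <- mode@kappa
    mode <- mode@mode
  }
  if (is.null(kappa))
    stop("kappa must be supplied")
  switch(match.arg(mode, c("stepwise", "jumpwise")),
         stepwise = gradientStepwiseClosed(params, kappa),
         jumpwise = gradientJumpwiseClosed(params, kappa))
}

#' Selection gradient by numerical eigenvalue perturbation
#'
#' Evaluates `t(mu) %*% B %*% eta`, where `B = dA/drho` at `rho = 0` is the
#' constant matrix of the affine mutant family for the requested mode (it
#' depends on `kappa` but not on `rho`), and `mu`, `eta` are the left and
#' right eigenvectors of the resident matrix at its dominant eigenvalue,
#' normalised to `crossprod(mu, eta) = 1`. Independent of the closed-form
#' route: agreement between the two is a structural check of both.
#'
#' @param params a [HierarchyParams-class] object.
#' @param dediff a [DedifferentiationSpec-class] (only `mode` and `kappa`
#'   enter; the gradient is the derivative at `rho = 0`).
#' @return a [SelectionResult-class] with method `"perturbation_numeric"`.
#' @export
gradientPerturbation <- function(params, dediff) {
  stopifnot(is(params, "HierarchyParams"), is(dediff, "DedifferentiationSpec"))
  lead <- leadingCompartment(params)
  sp <- dominantSpectrum(buildA0(params))
  b <- dAdRho(params@n, dediff@mode, dediff@kappa)
  dl <- drop(crossprod(sp@mu, b %*% sp@eta))
  new("SelectionResult", deltaLambda = dl, method = "perturbation_numeric",
      gammaTerms = emptyGammaTable(), kappaCritical = NA_real_,
      mode = dediff@mode, j0 = as.integer(lead$j0),
      kappa = dediff@kappa)
}

#' Selection gradient from exact eigenvalue differences
#'
#' The finite-`rho` quantity `(lambda(A_mode(rho)) - lambda0) / rho`, with
#' both eigenvalues computed exactly (LAPACK for the perturbed matrix, the
#' triangular maximum for the resident). This is the "exact numerical
#' solution" against which the first-order routes are validated; it differs
#' from them by O(rho). With `richardson = TRUE` the extrapolation
#' `2*g(rho/2) - g(rho)` removes the leading error term.
#'
#' @param params a [HierarchyParams-class] object.
#' @param dediff a [DedifferentiationSpec-class] with `rho > 0`.
#' @param richardson logical, apply one Richardson step over `(rho, rho/2)`.
#' @return a [SelectionResult-class] with method `"exact_difference"`.
#' @export
gradientExact <- function(params, dediff, richardson = FALSE) {
  stopifnot(is(params, "HierarchyParams"), is(dediff, "DedifferentiationSpec"))
  if (dediff@rho <= 0)
    stop("gradientExact requires rho > 0 (finite eigenvalue difference)")
  lead <- leadingCompartment(params)
  lam0 <- lead$lambda0
  gAt <- function(rho) {
    spec <- new("DedifferentiationSpec", mode = dediff@mode, rho = rho,
                kappa = dediff@kappa)
    lamM <- dominantSpectrum(buildMutantMatrix(params, spec))@lam
    (lamM - lam0) / rho
  }
  dl <- if (richardson) 2 * gAt(dediff@rho / 2) - gAt(dediff@rho)
        else gAt(dediff@rho)
  new("SelectionResult", deltaLambda = dl, method = "exact_difference",
      gammaTerms = emptyGammaTable(), kappaCritical = NA_real_,
      mode = dediff@mode, j0 = as.integer(lead$j0), kappa = dediff@kappa)
}

#' All three gradient routes at once
#'
#' Convenience wrapper returning the closed-form, perturbation and exact
#' gradients for one parameter set and de-differentiation spec.
#'
#' @inheritParams gradientExact
#' @return named list of three [SelectionResult-class] objects
#'   (`closed_form`, `perturbation`, `exact`).
#' @export
gradientAll <- function(params, dediff) {
  list(closed_form = gradientClosed(params, dediff),
       perturbation = gradientPerturbation(params, dediff),
       exact = gradientExact(params, dediff))
}
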