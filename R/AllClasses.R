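#' @import methods
#' @importFrom stats lm coef runif setNames
#' @importFrom utils write.table modifyList
NULL

# Tolerance used to decide whether two effective self-renewal rates tie
# (degenerate dominant eigenvalue). Relative to max(1, |lambda0|).
simplicityTol <- function() {
  getOption("hierDediff.simplicity.tol", 1e-9)
}

#' Resident hierarchy parameters
#'
#' Parameters of a hierarchically structured cell population with `n`
#' compartments: compartment 1 holds stem cells, compartments `2..n-1`
#' progressively differentiated dividing cells, and compartment `n` terminally
#' differentiated cells that no longer divide and are removed at rate `d`.
#' A cell in compartment `i < n` divides at rate `r[i]`; the division is
#' symmetric self-renewal (two daughters in compartment `i`) with probability
#' `p[i]` or symmetric differentiation (two daughters in compartment `i+1`)
#' with probability `q[i]`, and `p[i] + q[i] = 1` for resident cells.
#'
#' @slot n integer, number of compartments (at least 3).
#' @slot r numeric of length `n-1`, positive division rates per unit time.
#' @slot p numeric of length `n-1`, self-renewal probabilities in `[0,1]`.
#' @slot q numeric of length `n-1`, differentiation probabilities in `[0,1]`.
#' @slot d numeric, positive removal rate of the terminal compartment.
#'
#' @seealso [hierarchyParams()], [validateModel()], [buildA0()]
#' @export
setClass("HierarchyParams",
  slots = c(n = "integer", r = "numeric", p = "numeric", q = "numeric",
            d = "numeric"))

setValidity("HierarchyParams", function(object) {
  msg <- residentViolations(object@n, object@r, object@p, object@q, object@d)
  if (length(msg) == 0) TRUE else msg
})

#' Mutant de-differentiation specification
#'
#' Describes how a mutant lineage de-differentiates. In `stepwise` mode a cell
#' in compartment `i+1` can produce two daughters in the adjacent upstream
#' compartment `i`; in `jumpwise` mode a cell in compartment `n-1` produces
#' two daughters directly in the stem-cell compartment. The influx rate due to
#' de-differentiation is `rho = 2 * r[i] * delta[i]`, assumed equal across
#' compartments, so the per-division de-differentiation probability is derived
#' as `delta[i] = rho / (2 * r[i])` and never stored. The redistributing
#' factor `kappa` splits the probability cost between self-renewal
#' (`p - kappa * delta`) and differentiation (`q - (1 - kappa) * delta`).
#'
#' @slot mode character, `"stepwise"` or `"jumpwise"`.
#' @slot rho numeric, non-negative de-differentiation influx scale.
#' @slot kappa numeric in `[0,1]`, redistributing factor.
#'
#' @seealso [dediffSpec()], [buildAS()], [buildAJ()]
#' @export
setClass("DedifferentiationSpec",
  slots = c(mode = "character", rho = "numeric", kappa = "numeric"))

setValidity("DedifferentiationSpec", function(object) {
  msg <- character()
  if (length(object@mode) != 1 ||
      !object@mode %in% c("stepwise", "jumpwise"))
    msg <- c(msg, "mode must be 'stepwise' or 'jumpwise'")
  if (length(object@rho) != 1 || !is.finite(object@rho) || object@rho < 0)
    msg <- c(msg, "rho must be a single non-negative number")
  if (length(object@kappa) != 1 || !is.finite(object@kappa) ||
      object@kappa < 0 || object@kappa > 1)
    msg <- c(msg, "kappa must lie in [0, 1]")
  if (length(msg) == 0) TRUE else msg
})

#' Asymmetric-division extension of the resident model
#'
#' Adds asymmetric division (one daughter staying in compartment `i`, one
#' moving to `i+1`) with probability `s[i]`, relaxing the resident probability
#' closure to `p + q + s = 1`. The effective self-renewal rate is unchanged,
#' while the differentiation influx shifts from `2*r*q` to `2*r*q + r*s`; the
#' dominant eigenvalue is therefore identical to the symmetric model with the
#' same `r*(p - q)` diagonal.
#'
#' @slot s numeric of length `n-1`, asymmetric-division probabilities.
#'
#' @seealso [asymmetricExtension()], [buildA0Asymmetric()]
#' @export
setClass("AsymmetricExtension", slots = c(s = "numeric"))

setValidity("AsymmetricExtension", function(object) {
  if (any(!is.finite(object@s)) || any(object@s < 0) || any(object@s > 1))
    return("all s must lie in [0, 1]")
  TRUE
})

#' Projection matrix of the linear compartment dynamics
#'
#' The constant generator `A` of `dN/dt = A N`. Tags identify the variant:
#' `A0` (resident, lower triangular), `AS` (stepwise mutant: `A0` plus a
#' `rho` superdiagonal and redistribution corrections), `AJ` (jumpwise mutant:
#' `A0` plus a single `rho` entry at `(1, n-1)` and corrections in column
#' `n-1`), and `A0_asym` (resident with asymmetric division). All variants
#' are essentially non-negative: every off-diagonal entry is `>= 0`.
#'
#' @slot entries numeric `n x n` matrix, rates per unit time.
#' @slot tag character, one of `"A0"`, `"AS"`, `"AJ"`, `"A0_asym"`.
#' @slot paramsHash character, identifier of the generating parameter set.
#'
#' @seealso [buildA0()], [buildAS()], [buildAJ()], [dominantSpectrum()]
#' @export
setClass("ProjectionMatrix",
  slots = c(entries = "matrix", tag = "character", paramsHash = "character"))

setValidity("ProjectionMatrix", function(object) {
  m <- object@entries
  msg <- character()
  n <- nrow(m)
  if (!is.numeric(m) || n != ncol(m) || n < 3)
    return("entries must be a square numeric matrix with n >= 3")
  if (any(!is.finite(m)))
    return("entries must be finite")
  if (length(object@tag) != 1 ||
      !object@tag %in% c("A0", "AS", "AJ", "A0_asym"))
    msg <- c(msg, "tag must be one of A0, AS, AJ, A0_asym")
  off <- m; diag(off) <- 0
  if (any(off < 0))
    msg <- c(msg, "all off-diagonal entries must be non-negative")
  if (any(m[seq_len(n - 1), n] != 0))
    msg <- c(msg, "terminal compartment has no outgoing flux: column n must be zero above the diagonal")
  if (m[n, n] >= 0)
    msg <- c(msg, "entry (n, n) must be the negative removal rate -d")
  # structural sparsity allowed per tag
  if (length(msg) == 0 && object@tag %in% c("A0", "AS", "AJ", "A0_asym")) {
    allowed <- lower.tri(m, diag = TRUE)
    if (object@tag == "AS") {
      allowed[cbind(seq_len(n - 2), seq_len(n - 2) + 1)] <- TRUE
    } else if (object@tag == "AJ") {
      allowed[1, n - 1] <- TRUE
    }
    if (any(m[!allowed] != 0))
      msg <- c(msg, sprintf("entries outside the %s sparsity pattern must be zero", object@tag))
  }
  if (length(msg) == 0) TRUE else msg
})

#' Dominant-eigenvalue summary of a projection matrix
#'
#' The dominant (real largest) eigenvalue `lam`, its left and right
#' eigenvectors `mu` and `eta` normalised so that `crossprod(mu, eta) = 1`,
#' the leading compartment `j0` (argmax of the effective self-renewal rates;
#' defined for the resident matrix only, `NA` otherwise), the spectral gap to
#' the nearest other eigenvalue, and a simplicity flag.
#'
#' @slot lam numeric, dominant eigenvalue (per unit time).
#' @slot mu numeric of length `n`, left eigenvector.
#' @slot eta numeric of length `n`, right eigenvector.
#' @slot j0 integer, leading compartment (`NA` for non-resident matrices).
#' @slot gap numeric, distance from `lam` to the nearest other eigenvalue.
#' @slot simple logical, whether `lam` is simple at the configured tolerance.
#'
#' @seealso [dominantSpectrum()]
#' @export
setClass("SpectralSummary",
  slots = c(lam = "numeric", mu = "numeric", eta = "numeric", j0 = "integer",
            gap = "numeric", simple = "logical"))

#' Selection gradient for a de-differentiating mutant
#'
#' The first-order rate of change `deltaLambda` of the dominant eigenvalue
#' with respect to the de-differentiation scale `rho`, together with the route
#' that produced it, the Gamma terms entering the closed form, and the
#' critical redistributing factor `kappaCritical` where the gradient crosses
#' zero (`NA` when the gradient does not depend on `kappa` or never crosses).
#'
#' @slot deltaLambda numeric, the selection gradient.
#' @slot method character: `"closed_form"`, `"perturbation_numeric"` or
#'   `"exact_difference"`.
#' @slot gammaTerms data.frame with columns `j`, `k`, `l`, `value`.
#' @slot kappaCritical numeric, critical `kappa` in `[0,1]` or `NA`.
#' @slot mode character, de-differentiation mode the gradient refers to.
#' @slot j0 integer, leading compartment of the resident.
#' @slot kappa numeric, redistributing factor at which the gradient was
#'   evaluated.
#'
#' @seealso [gradientClosed()], [gradientPerturbation()], [gradientExact()]
#' @export
setClass("SelectionResult",
  slots = c(deltaLambda = "numeric", method = "character",
            gammaTerms = "data.frame", kappaCritical = "numeric",
            mode = "character", j0 = "integer", kappa = "numeric"))

setValidity("SelectionResult", function(object) {
  if (!object@method %in%
      c("closed_form", "perturbation_numeric", "exact_difference"))
    return("unknown method")
  TRUE
})
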