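# Semantic checks shared by the S4 validity method and validateModel().
# Returns a character vector of human-readable violations (empty when valid).
residentViolations <- function(n, r, p, q, d, tol = simplicityTol(),
                               checkSpectrum = TRUE) {
  msg <- character()
  if (length(n) != 1 || is.na(n) || n < 3)
    return("n must be a single integer >= 3 (de-differentiation needs at least one dividing non-stem compartment)")
  if (length(r) != n - 1 || length(p) != n - 1 || length(q) != n - 1)
    return(sprintf("r, p, q must each have length n - 1 = %d", n - 1))
  if (any(!is.finite(r)) || any(!is.finite(p)) || any(!is.finite(q)) ||
      length(d) != 1 || !is.finite(d))
    return("r, p, q, d must be finite")
  bad <- which(r <= 0)
  if (length(bad))
    msg <- c(msg, sprintf("division rate r[%d] must be positive", bad))
  bad <- which(p < 0 | p > 1)
  if (length(bad))
    msg <- c(msg, sprintf("self-renewal probability p[%d] outside [0, 1]", bad))
  bad <- which(q < 0 | q > 1)
  if (length(bad))
    msg <- c(msg, sprintf("differentiation probability q[%d] outside [0, 1]", bad))
  bad <- which(abs(p + q - 1) > 1e-12)
  if (length(bad))
    msg <- c(msg, sprintf(
      "p[%d] + q[%d] = %.6g but resident divisions have exactly two outcomes (p + q = 1)",
      bad, bad, (p + q)[bad]))
  if (d <= 0)
    msg <- c(msg, "removal rate d must be positive")
  if (length(msg) == 0 && checkSpectrum) {
    eff <- r * (p - q)
    lam0 <- max(eff)
    if (lam0 < 0)
      msg <- c(msg, sprintf(
        "max effective self-renewal rate %.6g is negative: the resident population is shrinking",
        lam0))
    ties <- sum(abs(eff - lam0) < tol * max(1, abs(lam0)))
    if (ties > 1)
      msg <- c(msg, sprintf(
        "dominant eigenvalue is degenerate: %d compartments tie for the maximum effective self-renewal rate %.6g",
        ties, lam0))
  }
  msg
}

# Joint checks of a de-differentiation spec against resident parameters:
# the derived probabilities p - kappa*delta and q - (1-kappa)*delta must stay
# non-negative for every compartment the mode affects.
jointViolations <- function(n, r, p, q, spec) {
  delta <- spec@rho / (2 * r)
  affected <- if (spec@mode == "stepwise") seq(2, n - 1) else n - 1
  msg <- character()
  for (i in affected) {
    if (p[i] - spec@kappa * delta[i] < 0)
      msg <- c(msg, sprintf(
        "mutant self-renewal probability p[%d] - kappa*delta[%d] = %.6g < 0",
        i, i, p[i] - spec@kappa * delta[i]))
    if (q[i] - (1 - spec@kappa) * delta[i] < 0)
      msg <- c(msg, sprintf(
        "mutant differentiation probability q[%d] - (1-kappa)*delta[%d] = %.6g < 0",
        i, i, q[i] - (1 - spec@kappa) * delta[i]))
  }
  msg
}

#' Construct resident hierarchy parameters
#'
#' Builds a validated [HierarchyParams-class] object. `q` defaults to `1 - p`
#' (the resident probability closure). Construction fails with the full list
#' of violated invariants when the parameter set is invalid; use
#' [validateModel()] to probe a candidate set without erroring.
#'
#' @param n integer, number of compartments (>= 3).
#' @param r numeric of length `n-1`, positive division rates.
#' @param p numeric of length `n-1`, self-renewal probabilities.
#' @param q numeric of length `n-1`, differentiation probabilities
#'   (default `1 - p`).
#' @param d positive removal rate of the terminal compartment.
#' @return a [HierarchyParams-class] object.
#' @examples
#' hp <- hierarchyParams(n = 4, r = c(0.99, 0.44, 0.3),
#'                       p = c(0.8, 0.55, 0.6), d = 0.05)
#' effectiveSelfRenewal(hp)
#' @export
hierarchyParams <- function(n, r, p, q = 1 - p, d) {
  viol <- residentViolations(as.integer(n), r, p, q, d)
  if (length(viol))
    stop("invalid hierarchy parameters:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  new("HierarchyParams", n = as.integer(n), r = as.numeric(r),
      p = as.numeric(p), q = as.numeric(q), d = as.numeric(d))
}

#' Construct a de-differentiation specification
#'
#' @param mode `"stepwise"` or `"jumpwise"`.
#' @param rho non-negative de-differentiation influx scale
#'   (`rho = 2 * r[i] * delta[i]`, assumed equal across compartments).
#' @param kappa redistributing factor in `[0,1]`: the fraction of the
#'   probability cost of de-differentiation taken from self-renewal.
#' @return a [DedifferentiationSpec-class] object.
#' @examples
#' dediffSpec("jumpwise", rho = 0.01, kappa = 1)
#' @export
dediffSpec <- function(mode = c("stepwise", "jumpwise"), rho, kappa) {
  mode <- match.arg(mode)
  new("DedifferentiationSpec", mode = mode, rho = as.numeric(rho),
      kappa = as.numeric(kappa))
}

#' Construct an asymmetric-division extension
#'
#' @param s numeric of length `n-1`, asymmetric-division probabilities in
#'   `[0,1]`. The joint closure `p + q + s = 1` is checked when the extension
#'   is combined with resident parameters in [buildA0Asymmetric()].
#' @return an [AsymmetricExtension-class] object.
#' @export
asymmetricExtension <- function(s) {
  new("AsymmetricExtension", s = as.numeric(s))
}

#' Report violated model invariants
#'
#' Checks a resident parameter set, and optionally a de-differentiation
#' specification against it, returning every violated invariant as a
#' character vector (empty when the model is valid). Unlike the constructors,
#' this never errors on semantic violations, so it can be used to probe
#' candidate parameter sets, e.g. grid points in a scan. `params` may be a
#' [HierarchyParams-class] object or a plain list with elements
#' `n, r, p, q, d` (with `q` defaulting to `1 - p`).
#'
#' @param params resident parameters (object or list, see above).
#' @param dediff optional [DedifferentiationSpec-class].
#' @param tol relative tolerance for declaring two effective self-renewal
#'   rates tied (degenerate dominant eigenvalue).
#' @return character vector of violations; `character(0)` when valid.
#' @examples
#' validateModel(list(n = 4, r = c(0.99, 0.44, 0.3),
#'                    p = c(0.8, 0.55, 0.6), d = 0.05))
#' @export
validateModel <- function(params, dediff = NULL, tol = simplicityTol()) {
  if (is(params, "HierarchyParams")) {
    n <- params@n; r <- params@r; p <- params@p; q <- params@q; d <- params@d
  } else if (is.list(params)) {
    n <- as.integer(params$n); r <- params$r; p <- params$p
    q <- if (is.null(params$q)) 1 - p else params$q
    d <- params$d
  } else {
    stop("params must be a HierarchyParams object or a list")
  }
  msg <- residentViolations(n, r, p, q, d, tol = tol)
  if (!is.null(dediff)) {
    if (!is(dediff, "DedifferentiationSpec"))
      stop("dediff must be a DedifferentiationSpec")
    if (length(residentViolations(n, r, p, q, d, checkSpectrum = FALSE)) == 0)
      msg <- c(msg, jointViolations(n, r, p, q, dediff))
  }
  msg
}

# Short stable identifier of a parameter set, used to tag derived matrices.
hashValues <- function(n, r, p, q, d) {
  key <- paste(format(c(n, r, p, q, d), digits = 15), collapse = ",")
  # tiny FNV-style rolling hash; only needs to distinguish parameter sets
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  sprintf("hp-%08x", h)
}

paramsHash <- function(params) {
  hashValues(params@n, params@r, params@p, params@q, params@d)
}
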