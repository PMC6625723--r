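#' Critical redistributing factor
#'
#' For the kappa-dependent mode/leading-compartment combinations (stepwise
#' with `j0 > 1`, jumpwise with `j0 = n-1`) the gradient is affine in `kappa`
#' with slope exactly `-1`, so the zero crossing is the Gamma sum (stepwise)
#' or Gamma product (jumpwise). When the crossing falls outside `[0,1]` the
#' gradient keeps one sign on the whole admissible range; when the mode is
#' kappa-independent (stepwise with `j0 = 1`, jumpwise with `j0 < n-1`) the
#' gradient is positive for every `kappa`.
#'
#' @param params a [HierarchyParams-class] object.
#' @param mode `"stepwise"` or `"jumpwise"`.
#' @return list with elements `status` (`"critical"`, `"always_positive"` or
#'   `"always_negative"`), `kappaCritical` (the crossing in `[0,1]`, else
#'   `NA`), `kappaDependent` (logical) and `gradient` (the kappa-independent
#'   gradient value when there is one, else `NA`).
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' criticalKappa(hp, "jumpwise")  # kappa* = 2/3
#' @export
criticalKappa <- function(params, mode = c("stepwise", "jumpwise")) {
  mode <- match.arg(mode)
  res0 <- gradientClosed(params, mode, kappa = 0)
  res1 <- gradientClosed(params, mode, kappa = 1)
  dependent <- abs(res0@deltaLambda - res1@deltaLambda) > 0
  if (!dependent)
    return(list(status = "always_positive", kappaCritical = NA_real_,
                kappaDependent = FALSE, gradient = res0@deltaLambda))
  kstar <- res0@deltaLambda  # affine with slope -1: crossing = value at kappa 0
  if (kstar >= 1)
    list(status = "always_positive", kappaCritical = NA_real_,
         kappaDependent = TRUE, gradient = NA_real_)
  else if (kstar <= 0)
    # unreachable when the Gamma terms are positive; guarded anyway
    list(status = "always_negative", kappaCritical = NA_real_,
         kappaDependent = TRUE, gradient = NA_real_)
  else
    list(status = "critical", kappaCritical = kstar, kappaDependent = TRUE,
         gradient = NA_real_)
}

#' Critical division rate at which invasion ceases
#'
#' Solves `deltaLambda(kappa = 1) = 0` in one division rate `r[rateIndex]`
#' over a bracket by bisection on the closed form (absolute tolerance on the
#' root). The leading compartment must not change across the bracket: it is
#' checked at both ends and at the returned root. The root is cross-checked
#' against the exact finite-`rho` gradient, which should be O(rho) small
#' there; a larger residual raises a warning, not an error.
#'
#' @param params a [HierarchyParams-class] object supplying all parameters
#'   except the scanned rate.
#' @param mode `"stepwise"` or `"jumpwise"`.
#' @param rateIndex compartment whose division rate is scanned (`1..n-1`).
#' @param bracket numeric length-2 interval for the rate; the closed-form
#'   gradient at `kappa = 1` must change sign over it.
#' @param tol absolute tolerance of the bisection root.
#' @param rho de-differentiation scale for the exact-gradient cross-check.
#' @return the critical rate (numeric scalar).
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' criticalRate(hp, "jumpwise", rateIndex = 1, bracket = c(0.01, 0.6))  # 0.45
#' @export
criticalRate <- function(params, mode = c("stepwise", "jumpwise"), rateIndex,
                         bracket, tol = 1e-6, rho = 0.01) {
  mode <- match.arg(mode)
  stopifnot(is(params, "HierarchyParams"))
  rateIndex <- as.integer(rateIndex)
  if (rateIndex < 1 || rateIndex > params@n - 1)
    stop("rateIndex must lie in 1..n-1")
  if (length(bracket) != 2 || bracket[1] <= 0 || diff(bracket) <= 0)
    stop("bracket must be an increasing positive interval")
  withRate <- function(rate) {
    r <- params@r
    r[rateIndex] <- rate
    hierarchyParams(params@n, r = r, p = params@p, q = params@q, d = params@d)
  }
  evalAt <- function(rate) {
    pr <- withRate(rate)
    res <- gradientClosed(pr, mode, kappa = 1)
    list(value = res@deltaLambda, j0 = res@j0, params = pr)
  }
  lo <- evalAt(bracket[1]); hi <- evalAt(bracket[2])
  if (lo$j0 != hi$j0)
    stop("leading compartment changes across the bracket (j0 = ", lo$j0,
         " vs ", hi$j0, "); threshold in this rate is not well defined")
  if (sign(lo$value) == sign(hi$value))
    stop("closed-form gradient at kappa = 1 does not change sign over the bracket [",
         bracket[1], ", ", bracket[2], "]")
  a <- bracket[1]; fa <- lo$value
  b <- bracket[2]
  while (b - a > tol) {
    mid <- (a + b) / 2
    fm <- evalAt(mid)$value
    if (fm == 0) { a <- b <- mid; break }
    if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
  }
  root <- (a + b) / 2
  atRoot <- evalAt(root)
  if (atRoot$j0 != lo$j0)
    stop("leading compartment changes at the root; threshold ill defined")
  exact <- gradientExact(atRoot$params,
                         dediffSpec(mode, rho = rho, kappa = 1))
  if (abs(exact@deltaLambda) > 10 * rho)
    warning("exact finite-rho gradient at the closed-form root is ",
            format(exact@deltaLambda),
            ", larger than the O(rho) band; check the bracket")
  root
}
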