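# Analytic left/right eigenvectors of a lower-triangular generator at the
# eigenvalue sitting at diagonal position j0. Forward/backward recursions in
# the subdiagonal; exact up to floating point, no LAPACK involved.
triangularEigenvectors <- function(m, j0) {
  n <- nrow(m)
  lam <- m[j0, j0]
  eta <- numeric(n)
  eta[j0] <- 1
  if (j0 < n) for (i in seq(j0 + 1, n))
    eta[i] <- m[i, i - 1] * eta[i - 1] / (lam - m[i, i])
  mu <- numeric(n)
  mu[j0] <- 1
  if (j0 > 1) for (i in seq(j0 - 1, 1))
    mu[i] <- m[i + 1, i] * mu[i + 1] / (lam - m[i, i])
  list(mu = mu, eta = eta)
}

# Normalise a left/right eigenvector pair: eta to unit Euclidean norm with a
# positive anchor entry, mu so that crossprod(mu, eta) = 1. Any consistent
# choice leaves mu' B eta invariant; this one is reproducible.
normalizePair <- function(mu, eta, anchor = which.max(abs(eta))) {
  eta <- eta / sqrt(sum(eta^2))
  if (eta[anchor] < 0) eta <- -eta
  s <- sum(mu * eta)
  if (abs(s) < 1e-300)
    stop("left and right eigenvectors are numerically orthogonal; dominant eigenvalue ill-conditioned")
  list(mu = mu / s, eta = eta)
}

#' Dominant-eigenvalue summary of a projection matrix
#'
#' Returns the eigenvalue of largest real part with its left and right
#' eigenvectors normalised to `crossprod(mu, eta) = 1`, the spectral gap and
#' a simplicity flag. For the triangular resident variants (`A0`, `A0_asym`)
#' the eigenvalues are the diagonal entries, so the dominant eigenvalue is
#' taken as `max(diag)` exactly and the eigenvectors come from the analytic
#' triangular recursions; for the mutant variants LAPACK (`eigen`) is used on
#' the matrix and its transpose. Essential non-negativity makes the dominant
#' eigenvalue real; an imaginary part above `1e-10` is treated as an internal
#' error.
#'
#' @param m a [ProjectionMatrix-class] object.
#' @param tol relative tolerance below which two eigenvalues are considered
#'   tied (degenerate dominant eigenvalue).
#' @param requireSimple error on a degenerate dominant eigenvalue (default);
#'   if `FALSE`, returns a summary with `simple = FALSE` and `NA`
#'   eigenvectors instead.
#' @return a [SpectralSummary-class] object.
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' dominantSpectrum(buildA0(hp))
#' @export
dominantSpectrum <- function(m, tol = simplicityTol(), requireSimple = TRUE) {
  stopifnot(is(m, "ProjectionMatrix"))
  a <- m@entries
  n <- nrow(a)
  triangular <- m@tag %in% c("A0", "A0_asym")
  if (triangular) {
    evals <- diag(a)
    lam <- max(evals)
    j0 <- which.max(evals[seq_len(n - 1)])
  } else {
    ev <- eigen(a, only.values = TRUE)$values
    lam_c <- ev[which.max(Re(ev))]
    if (abs(Im(lam_c)) >= 1e-10)
      stop("internal error: dominant eigenvalue has imaginary part ",
           format(Im(lam_c)),
           " — essential non-negativity should make it real")
    lam <- Re(lam_c)
    evals <- ev
    j0 <- NA_integer_
  }
  scale <- max(1, abs(lam))
  dists <- abs(evals - lam)
  # gap: nearest eigenvalue distinct from lam
  distinct <- sort(Re(dists))
  distinct <- distinct[distinct > tol * scale]
  gap <- if (length(distinct)) distinct[1] else 0
  ties <- sum(Re(dists) <= tol * scale) - 1
  simple <- ties == 0 && gap > 0
  if (!simple) {
    if (requireSimple)
      stop("degenerate dominant eigenvalue: ", ties + 1,
           " eigenvalues within tolerance of ", format(lam))
    return(new("SpectralSummary", lam = lam, mu = rep(NA_real_, n),
               eta = rep(NA_real_, n), j0 = as.integer(j0), gap = gap,
               simple = FALSE))
  }
  if (triangular) {
    jlam <- which.min(abs(diag(a) - lam))
    vecs <- triangularEigenvectors(a, jlam)
    pair <- normalizePair(vecs$mu, vecs$eta, anchor = jlam)
  } else {
    er <- eigen(a)
    el <- eigen(t(a))
    kr <- which.min(abs(er$values - lam))
    kl <- which.min(abs(el$values - lam))
    eta <- er$vectors[, kr]
    mu <- el$vectors[, kl]
    if (max(abs(Im(eta))) > 1e-8 || max(abs(Im(mu))) > 1e-8)
      stop("internal error: dominant eigenvectors are not real")
    pair <- normalizePair(Re(mu), Re(eta))
  }
  new("SpectralSummary", lam = lam, mu = pair$mu, eta = pair$eta,
      j0 = as.integer(j0), gap = gap, simple = TRUE)
}

#' Leading compartment and resident growth rate
#'
#' The resident's dominant eigenvalue is `max(r[i]*(p[i]-q[i]))` (the
#' projection matrix is triangular and the terminal entry `-d` is negative),
#' attained at the leading compartment `j0`. Errors when the maximum is tied
#' within tolerance (degenerate eigenvalue) or negative (shrinking resident;
#' the model restricts attention to expanding or homeostatic residents).
#'
#' @param params a [HierarchyParams-class] object.
#' @param tol relative simplicity tolerance.
#' @return list with elements `j0` (integer) and `lambda0` (numeric).
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' leadingCompartment(hp)  # j0 = 3, lambda0 = 0.42
#' @export
leadingCompartment <- function(params, tol = simplicityTol()) {
  stopifnot(is(params, "HierarchyParams"))
  eff <- effectiveSelfRenewal(params)
  lam0 <- max(eff)
  if (lam0 < 0)
    stop("resident population is shrinking (max effective self-renewal rate ",
         format(lam0), " < 0); the selection analysis assumes lambda0 >= 0")
  ties <- which(abs(eff - lam0) <= tol * max(1, abs(lam0)))
  if (length(ties) > 1)
    stop("leading compartment is not unique: compartments ",
         paste(ties, collapse = ", "),
         " tie for the maximum effective self-renewal rate")
  list(j0 = which.max(eff), lambda0 = lam0)
}

#' Gamma ratio entering the closed-form selection gradients
#'
#' `Gamma[j,k,l] = 2*r[j]*q[j] / (r[k]*(p[k]-q[k]) - r[l]*(p[l]-q[l]))`:
#' the differentiation influx of compartment `j` measured against the
#' difference between the effective self-renewal rates of compartments `k`
#' and `l`. Whenever the dominant eigenvalue is simple and `k = j0`, every
#' Gamma term entering the gradients is strictly positive.
#'
#' @param params a [HierarchyParams-class] object.
#' @param j,k,l compartment indices in `1..n-1`.
#' @return numeric scalar.
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' gammaTerm(hp, 2, 3, 2)  # 0.28 / 0.30
#' @export
gammaTerm <- function(params, j, k, l) {
  stopifnot(is(params, "HierarchyParams"))
  nd <- params@n - 1
  if (any(c(j, k, l) < 1) || any(c(j, k, l) > nd))
    stop("indices must lie in 1..n-1")
  eff <- effectiveSelfRenewal(params)
  den <- eff[k] - eff[l]
  if (abs(den) < 1e-14 * max(1, abs(eff[k])))
    stop(sprintf(
      "zero denominator in Gamma[%d,%d,%d]: compartments %d and %d have equal effective self-renewal rates",
      j, k, l, k, l))
  2 * params@r[j] * params@q[j] / den
}
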