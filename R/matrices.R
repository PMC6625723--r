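# Dense construction: n is small (typically 4), so no sparse representation.

emptyMatrix <- function(n) {
  m <- matrix(0, n, n, dimnames = list(paste0("c", seq_len(n)),
                                       paste0("c", seq_len(n))))
  m
}

#' Build the resident projection matrix
#'
#' The resident generator is lower triangular: diagonal entries are the
#' effective self-renewal rates `r[i]*(p[i]-q[i])` for the dividing
#' compartments and `-d` for the terminal compartment; subdiagonal entries
#' `(i+1, i) = 2*r[i]*q[i]` carry the differentiation influx.
#'
#' @param params a valid [HierarchyParams-class] object.
#' @return a [ProjectionMatrix-class] with tag `"A0"`.
#' @examples
#' hp <- hierarchyParams(3, r = c(1, 1), p = c(0.6, 0.4), d = 1)
#' as.matrix(buildA0(hp))
#' @export
buildA0 <- function(params) {
  stopifnot(is(params, "HierarchyParams"))
  n <- params@n
  m <- emptyMatrix(n)
  diag(m) <- c(params@r * (params@p - params@q), -params@d)
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- 2 * params@r * params@q
  new("ProjectionMatrix", entries = m, tag = "A0",
      paramsHash = paramsHash(params))
}

#' Build the stepwise-mutant projection matrix
#'
#' Relative to the resident matrix, each dividing non-stem compartment
#' `i = 2..n-1` acquires a de-differentiation outflow to the adjacent
#' upstream compartment: superdiagonal entries `(i-1, i) = rho`, a diagonal
#' reduction of `kappa*rho` and a subdiagonal reduction of `(1-kappa)*rho`
#' (the redistribution of the probability cost between self-renewal and
#' differentiation). The stem-cell row and the influx `(2,1)` are unchanged:
#' stem cells never de-differentiate.
#'
#' @param params a valid [HierarchyParams-class] object.
#' @param dediff a [DedifferentiationSpec-class] with mode `"stepwise"`.
#' @return a [ProjectionMatrix-class] with tag `"AS"`.
#' @examples
#' hp <- hierarchyParams(4, r = c(0.99, 0.44, 0.3),
#'                       p = c(0.8, 0.55, 0.6), d = 0.05)
#' as.matrix(buildAS(hp, dediffSpec("stepwise", rho = 0.01, kappa = 0.5)))
#' @export
buildAS <- function(params, dediff) {
  stopifnot(is(params, "HierarchyParams"), is(dediff, "DedifferentiationSpec"))
  if (dediff@mode != "stepwise")
    stop("buildAS requires mode = 'stepwise'")
  n <- params@n
  rho <- dediff@rho; kappa <- dediff@kappa
  m <- as.matrix(buildA0(params))
  m[cbind(seq_len(n - 2), seq_len(n - 2) + 1)] <- rho
  i <- seq(2, n - 1)
  m[cbind(i, i)] <- m[cbind(i, i)] - kappa * rho
  sub <- m[cbind(i + 1, i)] - (1 - kappa) * rho
  if (any(sub < 0))
    stop(sprintf(
      "invalid probability redistribution: effective influx 2*r[%d]*q[%d] - (1-kappa)*rho = %.6g is negative",
      i[which(sub < 0)[1]], i[which(sub < 0)[1]], min(sub)))
  m[cbind(i + 1, i)] <- sub
  new("ProjectionMatrix", entries = m, tag = "AS",
      paramsHash = paramsHash(params))
}

#' Build the jumpwise-mutant projection matrix
#'
#' Relative to the resident matrix, only the last dividing compartment
#' `n-1` de-differentiates, and it does so directly into the stem-cell
#' compartment: a single extra entry `(1, n-1) = rho`, a diagonal reduction
#' of `kappa*rho` at `(n-1, n-1)` and a reduction of `(1-kappa)*rho` at
#' `(n, n-1)`.
#'
#' @inheritParams buildAS
#' @param dediff a [DedifferentiationSpec-class] with mode `"jumpwise"`.
#' @return a [ProjectionMatrix-class] with tag `"AJ"`.
#' @export
buildAJ <- function(params, dediff) {
  stopifnot(is(params, "HierarchyParams"), is(dediff, "DedifferentiationSpec"))
  if (dediff@mode != "jumpwise")
    stop("buildAJ requires mode = 'jumpwise'")
  n <- params@n
  rho <- dediff@rho; kappa <- dediff@kappa
  m <- as.matrix(buildA0(params))
  m[1, n - 1] <- m[1, n - 1] + rho
  m[n - 1, n - 1] <- m[n - 1, n - 1] - kappa * rho
  sub <- m[n, n - 1] - (1 - kappa) * rho
  if (sub < 0)
    stop(sprintf(
      "invalid probability redistribution: effective influx 2*r[%d]*q[%d] - (1-kappa)*rho = %.6g is negative",
      n - 1, n - 1, sub))
  m[n, n - 1] <- sub
  new("ProjectionMatrix", entries = m, tag = "AJ",
      paramsHash = paramsHash(params))
}

#' Build a projection matrix for either de-differentiation mode
#'
#' Dispatch wrapper over [buildAS()] and [buildAJ()] on the mode of `dediff`.
#'
#' @inheritParams buildAS
#' @return a [ProjectionMatrix-class].
#' @export
buildMutantMatrix <- function(params, dediff) {
  if (dediff@mode == "stepwise") buildAS(params, dediff)
  else buildAJ(params, dediff)
}

#' Build the resident matrix with asymmetric division
#'
#' With asymmetric division probability `s[i]` (one daughter in compartment
#' `i`, one in `i+1`; closure `p + q + s = 1`), the effective self-renewal
#' rates are unchanged while the differentiation influx shifts from
#' `2*r*q` to `2*r*q + r*s`. The matrix stays lower triangular, so its
#' dominant eigenvalue equals that of the symmetric resident with the same
#' diagonal — the equivalence this variant exists to demonstrate.
#'
#' @param params a [HierarchyParams-class] object (only with `s = 0`, since
#'   residents close as `p + q = 1`), or a plain list with elements
#'   `n, r, p, q, d` whose probabilities satisfy `p + q + s = 1` together
#'   with `ext`.
#' @param ext an [AsymmetricExtension-class] object.
#' @return a [ProjectionMatrix-class] with tag `"A0_asym"`.
#' @examples
#' buildA0Asymmetric(list(n = 3, r = c(1, 1), p = c(0.5, 0.3),
#'                        q = c(0.3, 0.5), d = 1),
#'                   asymmetricExtension(c(0.2, 0.2)))
#' @export
buildA0Asymmetric <- function(params, ext) {
  stopifnot(is(ext, "AsymmetricExtension"))
  if (is(params, "HierarchyParams")) {
    n <- params@n; r <- params@r; p <- params@p; q <- params@q; d <- params@d
  } else if (is.list(params)) {
    n <- as.integer(params$n); r <- params$r; p <- params$p; q <- params$q
    d <- params$d
    if (is.null(q)) stop("q must be given explicitly for the asymmetric variant")
    if (n < 3 || length(r) != n - 1 || any(r <= 0) || d <= 0 ||
        any(p < 0) || any(p > 1) || any(q < 0) || any(q > 1))
      stop("invalid asymmetric parameter list")
  } else stop("params must be a HierarchyParams object or a list")
  if (length(ext@s) != n - 1)
    stop("s must have length n - 1")
  if (any(abs(p + q + ext@s - 1) > 1e-12))
    stop("asymmetric closure violated: p + q + s must equal 1 in every dividing compartment")
  m <- emptyMatrix(n)
  diag(m) <- c(r * (p - q), -d)
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- 2 * r * q + r * ext@s
  new("ProjectionMatrix", entries = m, tag = "A0_asym",
      paramsHash = hashValues(n, r, p, q, d))
}

# Constant derivative dA/drho of the affine family A(rho) = A0 + rho * B for
# the given mode and redistributing factor; used by the perturbation gradient.
dAdRho <- function(n, mode, kappa) {
  b <- matrix(0, n, n)
  if (mode == "stepwise") {
    b[cbind(seq_len(n - 2), seq_len(n - 2) + 1)] <- 1
    i <- seq(2, n - 1)
    b[cbind(i, i)] <- -kappa
    b[cbind(i + 1, i)] <- -(1 - kappa)
  } else {
    b[1, n - 1] <- 1
    b[n - 1, n - 1] <- -kappa
    b[n, n - 1] <- -(1 - kappa)
  }
  b
}
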