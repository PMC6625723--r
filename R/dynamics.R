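#' Deterministic compartment trajectory
#'
#' Compartment counts `N_i(t)` of the linear dynamics `dN/dt = A N` at a set
#' of requested times, plus the total population size `M(t) = sum_i N_i(t)`.
#'
#' @slot times increasing numeric vector of sample times.
#' @slot counts numeric matrix (time x n) of non-negative counts.
#' @slot total numeric vector, row sums of `counts`.
#'
#' @seealso [propagate()], [asymptoticGrowthRate()]
#' @export
setClass("Trajectory",
  slots = c(times = "numeric", counts = "matrix", total = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@counts) != length(object@times))
    msg <- c(msg, "counts must have one row per time")
  if (length(object@total) != length(object@times))
    msg <- c(msg, "total must have one entry per time")
  if (length(msg) == 0) TRUE else msg
})

#' @rdname Trajectory-class
#' @param x a [Trajectory-class] object.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname Trajectory-class
#' @export
setMethod("sampleTimes", "Trajectory", function(x) x@times)

#' @rdname Trajectory-class
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' @rdname Trajectory-class
#' @export
setMethod("countsMatrix", "Trajectory", function(x) x@counts)

#' @rdname Trajectory-class
#' @export
setGeneric("totalSize", function(x) standardGeneric("totalSize"))

#' @rdname Trajectory-class
#' @export
setMethod("totalSize", "Trajectory", function(x) x@total)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d times on [%g, %g], %d compartments\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@counts)))
})

#' Default propagation horizon
#'
#' `max(50, 10/gap)`: long enough that the spectral gap has suppressed the
#' subdominant modes over the tail of the window.
#'
#' @param gap spectral gap of the generator.
#' @return numeric horizon.
#' @export
propagationHorizon <- function(gap) {
  if (!is.finite(gap) || gap <= 0) return(50)
  max(50, 10 / gap)
}

#' Propagate compartment counts under a projection matrix
#'
#' Evaluates `N(t) = expm(t*A) %*% N0` at each requested time. The system is
#' linear with constant coefficients, so matrix-exponential action (not
#' generic time stepping) reproduces the solution to near machine precision
#' and keeps integrator tolerances out of eigenvalue-agreement checks.
#' The essentially non-negative generator preserves the non-negative orthant,
#' so counts stay non-negative for non-negative initial states.
#'
#' @param m a [ProjectionMatrix-class] object.
#' @param N0 non-negative initial counts, not all zero, length `n`.
#' @param times strictly increasing sample times starting at `>= 0`.
#' @return a [Trajectory-class] object.
#' @examples
#' hp <- hierarchyParams(4, r = c(0.3, 0.4, 0.6),
#'                       p = c(0.5, 0.65, 0.85), d = 0.05)
#' tr <- propagate(buildA0(hp), rep(1, 4), seq(0, 10, by = 1))
#' totalSize(tr)
#' @export
propagate <- function(m, N0, times) {
  stopifnot(is(m, "ProjectionMatrix"))
  a <- m@entries
  n <- nrow(a)
  if (length(N0) != n)
    stop("N0 must have length n = ", n)
  if (any(!is.finite(N0)) || any(N0 < 0))
    stop("initial counts must be non-negative")
  if (all(N0 == 0))
    stop("initial counts must not all be zero")
  if (length(times) < 1 || any(times < 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and non-negative")
  counts <- matrix(0, length(times), n,
                   dimnames = list(NULL, paste0("c", seq_len(n))))
  for (ti in seq_along(times)) {
    counts[ti, ] <- if (times[ti] == 0) N0
      else as.numeric(Matrix::expm(times[ti] * a) %*% N0)
  }
  # clip tiny negative round-off; the exact flow is orthant-preserving
  counts[counts < 0 & counts > -1e-12 * max(abs(counts))] <- 0
  new("Trajectory", times = as.numeric(times), counts = counts,
      total = rowSums(counts))
}

#' Asymptotic growth rate from a trajectory tail
#'
#' Least-squares slope of `log(M(t))` over the final `tailFraction` of the
#' time window. For large times the total size grows like
#' `M(0) * exp(lambda * t)`, so the tail slope estimates the dominant
#' eigenvalue once the spectral gap has suppressed the subdominant modes
#' (residual of order `exp(-gap * t_tail_start)`; the caller controls the
#' horizon, see [propagationHorizon()]).
#'
#' @param traj a [Trajectory-class] object.
#' @param tailFraction fraction of the time window (from the end) used for
#'   the fit, in `(0, 1)`.
#' @return numeric slope (per unit time).
#' @export
asymptoticGrowthRate <- function(traj, tailFraction = 0.25) {
  stopifnot(is(traj, "Trajectory"))
  if (tailFraction <= 0 || tailFraction >= 1)
    stop("tailFraction must lie in (0, 1)")
  tmax <- max(traj@times)
  tmin <- min(traj@times)
  cut <- tmax - tailFraction * (tmax - tmin)
  sel <- traj@times >= cut
  if (sum(sel) < 2)
    stop("tail window contains fewer than two samples")
  m <- traj@total[sel]
  if (any(m <= 0))
    stop("total population is non-positive in the tail; cannot take logarithm")
  tt <- traj@times[sel]
  unname(coef(lm(log(m) ~ tt))[2])
}
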