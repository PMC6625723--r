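# Lenient fixture resolver: start from the registry entry, fill free
# parameters with their defaults, then apply overrides (which, unlike
# bindFixture, may also re-set fixed entries such as rho or d — needed for
# scans and the CLI --set flag). Returns a plain value list; validity is the
# caller's concern so that invalid grid points can be reported, not thrown.
resolveFixture <- function(name, overrides = list()) {
  entry <- namedFixture(name)
  fixed <- entry$fixed
  vals <- list(n = fixed$n, r = fixed$r, p = fixed$p, d = fixed$d,
               rho = fixed$rho, kappa = fixed$kappa, mode = entry$mode)
  for (i in seq_len(nrow(entry$free))) {
    nm <- entry$free$param[i]
    vals <- applyOverride(vals, nm, entry$free$default[i])
  }
  for (nm in names(overrides))
    vals <- applyOverride(vals, nm, overrides[[nm]])
  vals$q <- 1 - vals$p
  vals
}

applyOverride <- function(vals, nm, value) {
  if (grepl("^[rpq][0-9]+$", nm)) {
    idx <- as.integer(substring(nm, 2))
    if (idx < 1 || idx > vals$n - 1)
      stop("index out of range in parameter name ", nm)
    slot <- substring(nm, 1, 1)
    if (slot == "q") vals$p[idx] <- 1 - value
    else vals[[slot]][idx] <- value
  } else if (nm %in% c("kappa", "rho", "d", "mode")) {
    vals[[nm]] <- value
  } else {
    stop("unknown parameter name '", nm, "'")
  }
  vals
}

valuesToModel <- function(vals) {
  params <- hierarchyParams(vals$n, r = vals$r, p = vals$p, d = vals$d)
  dediff <- dediffSpec(vals$mode, rho = vals$rho, kappa = vals$kappa)
  list(params = params, dediff = dediff)
}

#' Specify a parameter scan
#'
#' Describes a one- or two-axis sweep over a fixture's parameters, the
#' de-differentiation mode, and which gradient quantities to tabulate —
#' the machinery behind the figure-style sweeps.
#'
#' @param fixture fixture name (see [fixtureNames()]).
#' @param axes named list of one or two numeric grids; names are parameter
#'   names (`p1..`, `q1..`, `r1..`, `kappa`, `rho`, `d`).
#' @param outputs subset of `c("closed_form", "perturbation", "exact",
#'   "kappa_critical")`.
#' @param mode optional mode override.
#' @param values named list of non-axis overrides applied to every grid
#'   point.
#' @return a list of class `"hierDediffScanSpec"`.
#' @export
scanSpec <- function(fixture, axes,
                     outputs = c("closed_form", "exact"),
                     mode = NULL, values = list()) {
  outputs <- match.arg(outputs,
    c("closed_form", "perturbation", "exact", "kappa_critical"),
    several.ok = TRUE)
  if (length(axes) < 1 || length(axes) > 2 || is.null(names(axes)) ||
      any(names(axes) == ""))
    stop("axes must be a named list of one or two numeric grids")
  structure(list(fixture = fixture, axes = axes, outputs = outputs,
                 mode = mode, values = values),
            class = "hierDediffScanSpec")
}

#' Run a parameter scan
#'
#' Evaluates the requested quantities on the full grid. Grid points that
#' break model assumptions (invalid parameters, degenerate or negative
#' dominant eigenvalue) are retained with a reason code rather than dropped,
#' so the output table always has one row per grid point. Deterministic:
#' repeated runs give identical tables.
#'
#' @param spec a [scanSpec()] object.
#' @return data.frame with the axis columns, `lambda0`, `j0`, one column per
#'   requested output, `valid` and `reason`.
#' @examples
#' sc <- scanGrid(scanSpec("fig6a", axes = list(kappa = seq(0, 1, 0.25)),
#'                         values = list(r1 = 0.3)))
#' sc[, c("kappa", "closed_form")]
#' @export
scanGrid <- function(spec) {
  stopifnot(inherits(spec, "hierDediffScanSpec"))
  grid <- expand.grid(spec$axes, KEEP.OUT.ATTRS = FALSE)
  out <- grid
  out$lambda0 <- NA_real_
  out$j0 <- NA_integer_
  for (o in spec$outputs) out[[o]] <- NA_real_
  out$valid <- FALSE
  out$reason <- ""
  for (i in seq_len(nrow(grid))) {
    overrides <- c(as.list(grid[i, , drop = FALSE]), spec$values)
    row <- tryCatch({
      vals <- resolveFixture(spec$fixture, overrides)
      if (!is.null(spec$mode)) vals$mode <- spec$mode
      viol <- validateModel(list(n = vals$n, r = vals$r, p = vals$p,
                                 q = vals$q, d = vals$d))
      if (length(viol))
        list(reason = paste(viol, collapse = "; "))
      else {
        model <- valuesToModel(vals)
        lead <- leadingCompartment(model$params)
        vcols <- list(lambda0 = lead$lambda0, j0 = lead$j0, valid = TRUE)
        for (o in spec$outputs) {
          vcols[[o]] <- switch(o,
            closed_form = deltaLambda(gradientClosed(model$params,
                                                     model$dediff)),
            perturbation = deltaLambda(gradientPerturbation(model$params,
                                                            model$dediff)),
            exact = deltaLambda(gradientExact(model$params, model$dediff)),
            kappa_critical = {
              ck <- criticalKappa(model$params, vals$mode)
              if (ck$status == "critical") ck$kappaCritical else NA_real_
            })
        }
        vcols
      }
    }, error = function(e) list(reason = conditionMessage(e)))
    for (nm in names(row))
      if (nm %in% names(out)) out[i, nm] <- row[[nm]]
    if (!is.null(row$reason)) out$reason[i] <- row$reason
  }
  out
}

#' Trace the stepwise invasion boundary in (p2, kappa)
#'
#' For each `p2` in the grid, computes the critical redistributing factor at
#' which the stepwise selection gradient vanishes (leading compartment 2
#' required and checked per point) and back-substitutes it into the closed
#' form. Points whose crossing falls outside `[0,1]` are reported as having
#' no boundary in range rather than dropped.
#'
#' @param p2Grid numeric grid of self-renewal probabilities for
#'   compartment 2.
#' @param fixture fixture providing the remaining parameters.
#' @param values named overrides applied to every point.
#' @return data.frame with columns `p2`, `j0`, `kappaStar`, `residual`
#'   (closed-form gradient at `kappaStar`), `inRange` and `reason`.
#' @examples
#' boundaryCurve(c(0.8, 0.9), fixture = "fig4")
#' @export
boundaryCurve <- function(p2Grid, fixture = "fig4", values = list()) {
  out <- data.frame(p2 = p2Grid, j0 = NA_integer_, kappaStar = NA_real_,
                    residual = NA_real_, inRange = FALSE, reason = "")
  for (i in seq_along(p2Grid)) {
    res <- tryCatch({
      vals <- resolveFixture(fixture, c(list(p2 = p2Grid[i]), values))
      vals$mode <- "stepwise"
      model <- valuesToModel(vals)
      lead <- leadingCompartment(model$params)
      if (lead$j0 != 2)
        list(j0 = lead$j0,
             reason = sprintf("leading compartment is %d, not 2", lead$j0))
      else {
        ck <- criticalKappa(model$params, "stepwise")
        if (ck$status != "critical")
          list(j0 = lead$j0, reason = paste0("no boundary in range (",
                                             ck$status, ")"))
        else {
          resid <- deltaLambda(gradientStepwiseClosed(model$params,
                                                      ck$kappaCritical))
          list(j0 = lead$j0, kappaStar = ck$kappaCritical,
               residual = resid, inRange = TRUE)
        }
      }
    }, error = function(e) list(reason = conditionMessage(e)))
    for (nm in names(res)) out[i, nm] <- res[[nm]]
  }
  out
}
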