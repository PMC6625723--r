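# Registry of the named four-compartment parameter sets used by the figure
# analyses. Each entry records the canonical fixed values verbatim (NA marks a
# value the figure varies or never states), which parameters are free, a
# plausible range for each free parameter, and a default binding used when a
# single representative point is needed. Ranges marked stated = FALSE are
# package choices, not source values; r2 in fig5a/fig5b/fig5d and r1 in fig5c
# have no canonical value (the dominant eigenvalue does not depend on them at
# those homeostatic/leading configurations, so none was ever fixed), and
# their defaults are package choices as well.

freeSpec <- function(param, lo, hi, stated, default) {
  data.frame(param = param, lo = lo, hi = hi, stated = stated,
             default = default, stringsAsFactors = FALSE)
}

fixtureRegistry <- list(
  fig2a = list(
    mode = "stepwise",
    fixed = list(n = 4, d = 0.05, rho = 0.001, kappa = 0.1,
                 r = c(0.99, NA, 0.3), p = c(NA, 0.55, 0.6)),
    free = rbind(freeSpec("p1", 0.55, 1.0, TRUE, 0.775),
                 freeSpec("r2", 0.01, 0.99, FALSE, 0.5)),
    note = "expanding, leading compartment 1"),
  fig2b = list(
    mode = "stepwise",
    fixed = list(n = 4, d = 0.05, rho = 0.001, kappa = 0.1,
                 r = c(0.99, NA, 0.3), p = c(0.5, NA, 0)),
    free = rbind(freeSpec("p2", 0, 0.3, TRUE, 0.15),
                 freeSpec("r2", 0.01, 0.99, FALSE, 0.5)),
    note = "homeostasis, leading compartment 1"),
  fig3a = list(
    mode = "stepwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = NA,
                 r = c(NA, 0.44, 0.17), p = c(0.5, 0.95, 0.55)),
    free = rbind(freeSpec("r1", 0.01, 0.99, FALSE, 0.5),
                 freeSpec("kappa", 0, 1, TRUE, 0.5)),
    note = "expanding, leading compartment 2"),
  fig3b = list(
    mode = "stepwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = NA,
                 r = c(0.99, NA, 0.8), p = c(0.001, 0.5, 0.001)),
    free = rbind(freeSpec("r2", 0.01, 0.99, FALSE, 0.5),
                 freeSpec("kappa", 0, 1, TRUE, 0.5)),
    note = "homeostasis, leading compartment 2"),
  fig4 = list(
    mode = "stepwise",
    fixed = list(n = 4, d = 0.005, rho = 0.01, kappa = NA,
                 r = c(0.0885, 0.4145, 0.5555), p = c(0.4723, NA, 0.0727)),
    free = rbind(freeSpec("p2", 0.5, 1.0, FALSE, 0.75),
                 freeSpec("kappa", 0, 1, TRUE, 0.5)),
    note = "expanding, leading compartment 2; invasion boundary in (p2, kappa)"),
  fig5a = list(
    mode = "jumpwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = 0.1,
                 r = c(0.2, NA, 0.3), p = c(NA, 0.55, 0.6)),
    free = rbind(freeSpec("p1", 0.65, 1.0, FALSE, 0.85),
                 freeSpec("r2", 0.01, 0.99, FALSE, 0.3)),
    note = "expanding, leading compartment 1; r2 has no canonical value"),
  fig5b = list(
    mode = "jumpwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = 0.1,
                 r = c(0.2, NA, 0.3), p = c(0.55, NA, 0.6)),
    free = rbind(freeSpec("p2", 0.6, 1.0, FALSE, 0.8),
                 freeSpec("r2", 0.01, 0.99, FALSE, 0.4)),
    note = "expanding, leading compartment 2; r2 has no canonical value"),
  fig5c = list(
    mode = "jumpwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = 0.1,
                 r = c(NA, 0.4, 0.6), p = c(0.5, NA, 0.1)),
    free = rbind(freeSpec("p2", 0.01, 0.49, FALSE, 0.25),
                 freeSpec("r1", 0.01, 0.99, FALSE, 0.5)),
    note = "homeostasis, leading compartment 1; r1 has no canonical value"),
  fig5d = list(
    mode = "jumpwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = 0.1,
                 r = c(0.4, NA, 0.6), p = c(NA, 0.5, 0.1)),
    free = rbind(freeSpec("p1", 0.01, 0.49, FALSE, 0.25),
                 freeSpec("r2", 0.01, 0.99, FALSE, 0.5)),
    note = "homeostasis, leading compartment 2; r2 has no canonical value"),
  fig6a = list(
    mode = "jumpwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = NA,
                 r = c(NA, 0.4, 0.6), p = c(0.5, 0.65, 0.85)),
    free = rbind(freeSpec("r1", 0.01, 0.6, FALSE, 0.3),
                 freeSpec("kappa", 0, 1, TRUE, 0.5)),
    note = "expanding, leading compartment 3; critical r1 near 0.45"),
  fig6b = list(
    mode = "jumpwise",
    fixed = list(n = 4, d = 0.05, rho = 0.01, kappa = NA,
                 r = c(0.8, 0.7, 0.2), p = c(0.01, NA, 0.5)),
    free = rbind(freeSpec("p2", 0.01, 0.49, FALSE, 0.25),
                 freeSpec("kappa", 0, 1, TRUE, 0.5)),
    note = "homeostasis, leading compartment 3")
)

#' Names of the registered figure fixtures
#'
#' @return character vector of fixture names.
#' @export
fixtureNames <- function() names(fixtureRegistry)

#' Look up a named figure fixture
#'
#' Returns the registry entry for one of the four-compartment parameter sets
#' used in the figure analyses: the fixed values, the de-differentiation mode
#' the figure studies, and a table of the free parameters the figure varies
#' (with their ranges, whether the range is part of the fixture's canonical
#' definition, and the default binding used by [bindFixture()]).
#'
#' @param name one of [fixtureNames()].
#' @return a list with elements `name`, `mode`, `fixed` (list with `n`, `d`,
#'   `rho`, `kappa`, `r`, `p`; `NA` marks free/unstated values), `free`
#'   (data.frame) and `note`.
#' @examples
#' namedFixture("fig6a")
#' @export
namedFixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(fixtureRegistry))
    stop("unknown fixture '", paste(name, collapse = ","), "'; see fixtureNames()")
  c(list(name = name), fixtureRegistry[[name]])
}

#' Bind a fixture's free parameters to concrete values
#'
#' Builds a validated [HierarchyParams-class] and [DedifferentiationSpec-class]
#' pair from a registry entry, binding each free parameter either to a value
#' supplied in `values` or to its registry default.
#'
#' @param name fixture name, see [fixtureNames()].
#' @param values named list/vector of bindings for free parameters (names as
#'   in the fixture's `free` table, e.g. `r1`, `p2`, `kappa`); unsupplied free
#'   parameters take their registry defaults.
#' @param mode override the fixture's de-differentiation mode.
#' @return list with elements `params` ([HierarchyParams-class]), `dediff`
#'   ([DedifferentiationSpec-class]) and `values` (the resolved full
#'   parameter list).
#' @examples
#' fx <- bindFixture("fig6a", values = list(r1 = 0.3, kappa = 1))
#' effectiveSelfRenewal(fx$params)
#' @export
bindFixture <- function(name, values = list(), mode = NULL) {
  entry <- namedFixture(name)
  fixed <- entry$fixed
  r <- fixed$r; p <- fixed$p; kappa <- fixed$kappa
  resolved <- list()
  for (i in seq_len(nrow(entry$free))) {
    nm <- entry$free$param[i]
    val <- if (!is.null(values[[nm]])) values[[nm]] else entry$free$default[i]
    resolved[[nm]] <- val
  }
  extra <- setdiff(names(values), entry$free$param)
  if (length(extra))
    stop("not free parameters of ", name, ": ", paste(extra, collapse = ", "))
  for (nm in names(resolved)) {
    if (nm == "kappa") kappa <- resolved[[nm]]
    else if (grepl("^r[0-9]+$", nm)) r[as.integer(substring(nm, 2))] <- resolved[[nm]]
    else if (grepl("^p[0-9]+$", nm)) p[as.integer(substring(nm, 2))] <- resolved[[nm]]
    else stop("unhandled free parameter ", nm)
  }
  if (anyNA(r) || anyNA(p) || is.na(kappa))
    stop("unbound free parameters remain for fixture ", name)
  params <- hierarchyParams(n = fixed$n, r = r, p = p, d = fixed$d)
  spec <- dediffSpec(if (is.null(mode)) entry$mode else mode,
                     rho = fixed$rho, kappa = kappa)
  list(params = params, dediff = spec,
       values = list(n = fixed$n, r = r, p = p, q = 1 - p, d = fixed$d,
                     rho = fixed$rho, kappa = kappa,
                     mode = if (is.null(mode)) entry$mode else mode))
}
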