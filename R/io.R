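#' Read a model configuration file
#'
#' Flat YAML or JSON document with keys `n`, `r` (list), `p` (list), `q`
#' (list, optional — defaults to `1 - p`), `d`, and optionally `rho`,
#' `kappa`, `mode` describing a de-differentiation spec. The format is
#' chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path file path.
#' @return list with elements `params` ([HierarchyParams-class]) and
#'   `dediff` ([DedifferentiationSpec-class] or `NULL` when the document has
#'   no de-differentiation keys).
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    d <- yaml::read_yaml(path)
    # YAML 1.1 resolves a bare key `n` to boolean FALSE; undo that
    names(d)[names(d) == "FALSE"] <- "n"
    d
  } else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
  need <- c("n", "r", "p", "d")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("config is missing keys: ", paste(miss, collapse = ", "))
  q <- if (is.null(doc$q)) 1 - unlist(doc$p) else unlist(doc$q)
  params <- hierarchyParams(doc$n, r = unlist(doc$r), p = unlist(doc$p),
                            q = q, d = doc$d)
  dediff <- NULL
  if (!is.null(doc$rho) || !is.null(doc$mode) || !is.null(doc$kappa)) {
    if (is.null(doc$rho) || is.null(doc$mode) || is.null(doc$kappa))
      stop("a de-differentiation spec needs all of mode, rho, kappa")
    dediff <- dediffSpec(doc$mode, rho = doc$rho, kappa = doc$kappa)
  }
  list(params = params, dediff = dediff)
}

# Comment-header block recorded at the top of every output CSV.
csvHeader <- function(meta = list()) {
  base <- c(package = paste0("hierDediff ",
                             as.character(utils::packageVersion("hierDediff"))))
  meta <- c(base, unlist(meta))
  sprintf("# %s: %s", names(meta), as.character(meta))
}

#' Write a results table as annotated CSV
#'
#' Comma-separated, `.` decimal, 12 significant digits, with a leading block
#' of `#` comment lines recording the package version and any metadata
#' (fixture name, resolved parameters, seed) — enough precision to verify
#' 1e-9-level agreements from the file alone.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param meta named character/numeric vector or list of metadata lines.
#' @return `path`, invisibly.
#' @export
writeResultsCSV <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csvHeader(meta), con)
  fmt <- df
  for (nm in names(fmt))
    if (is.numeric(fmt[[nm]])) fmt[[nm]] <- signif(fmt[[nm]], 12)
  write.table(fmt, con, sep = ",", dec = ".", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a projection matrix as CSV
#'
#' Row-major dump with a header row of compartment labels `c1..cn` and a
#' comment block recording tag and parameter hash.
#'
#' @param m a [ProjectionMatrix-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMatrixCSV <- function(m, path) {
  stopifnot(is(m, "ProjectionMatrix"))
  df <- as.data.frame(as.matrix(m))
  writeResultsCSV(df, path,
                  meta = list(tag = m@tag, params = m@paramsHash))
}

#' Read back an annotated results CSV
#'
#' @param path file written by [writeResultsCSV()].
#' @return data.frame (comment lines skipped).
#' @export
readResultsCSV <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
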