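test_that("a kappa scan on the jumpwise fixture is the expected affine line", {
  sp <- scanSpec("fig6a", axes = list(kappa = seq(0, 1, by = 0.1)),
                 outputs = c("closed_form", "exact"),
                 values = list(r1 = 0.3))
  tab <- scanGrid(sp)
  expect_true(all(tab$valid))
  expect_equal(tab$closed_form, 2 / 3 - tab$kappa, tolerance = 1e-12)
  expect_true(all(abs(tab$exact - tab$closed_form) <= 10 * 0.01))
  expect_equal(tab$lambda0, rep(0.42, 11))
  expect_equal(tab$j0, rep(3L, 11))
})

test_that("stepwise selection is positive across the fig2a-style (p1, r2) plane", {
  sp <- scanSpec("fig2a",
                 axes = list(p1 = seq(0.58, 0.98, by = 0.08),
                             r2 = seq(0.1, 0.9, by = 0.2)),
                 outputs = "closed_form")
  tab <- scanGrid(sp)
  expect_true(all(tab$valid))
  expect_true(all(tab$closed_form > 0))
})

test_that("grid points that break assumptions are flagged, not dropped", {
  # r3 = 0.12/0.7 ties compartments 2 and 3; p2 = 1.2 is no probability
  sp <- scanSpec("fig6a", axes = list(r3 = c(0.12 / 0.7, 0.6)),
                 outputs = "closed_form", values = list(r1 = 0.3))
  tab <- scanGrid(sp)
  expect_identical(nrow(tab), 2L)
  expect_false(tab$valid[1])
  expect_match(tab$reason[1], "degenerate|not unique")
  expect_true(tab$valid[2])

  sp2 <- scanSpec("fig6a", axes = list(p2 = c(0.65, 1.2)),
                  outputs = "closed_form")
  tab2 <- scanGrid(sp2)
  expect_false(tab2$valid[2])
  expect_match(tab2$reason[2], "outside \\[0, 1\\]")
})

test_that("scans are deterministic and the CSV round-trips at full precision", {
  sp <- scanSpec("fig6a", axes = list(kappa = seq(0, 1, by = 0.25)),
                 outputs = c("closed_form", "perturbation"),
                 values = list(r1 = 0.3))
  tab <- scanGrid(sp)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeResultsCSV(tab, f1, meta = list(fixture = "fig6a", seed = 1))
  writeResultsCSV(scanGrid(sp), f2, meta = list(fixture = "fig6a", seed = 1))
  expect_identical(readLines(f1), readLines(f2))
  head <- readLines(f1)
  expect_match(head[1], "^# package: hierDediff")
  expect_true(any(grepl("^# seed: 1", head)))
  back <- readResultsCSV(f1)
  expect_equal(back$closed_form, tab$closed_form, tolerance = 1e-11)
  unlink(c(f1, f2))
})

test_that("the fig4 boundary is traced with exact back-substitution", {
  grid <- seq(0.75, 0.95, by = 0.05)
  tab <- boundaryCurve(grid, fixture = "fig4")
  expect_true(all(tab$j0 == 2))
  expect_true(all(tab$inRange))
  expect_true(all(abs(tab$residual) < 1e-10))
  expect_true(all(diff(tab$kappaStar) <= 0))  # kappa* decreases with p2
  expect_equal(tab$kappaStar[abs(tab$p2 - 0.9) < 1e-9], 0.3804,
               tolerance = 1e-4)
})

test_that("boundary points without a crossing in [0,1] are reported as such", {
  # small p2 keeps the Gamma sum above 1: always positive, no boundary
  tab <- boundaryCurve(c(0.55, 0.9), fixture = "fig4")
  expect_false(tab$inRange[1])
  expect_match(tab$reason[1], "no boundary in range")
  expect_true(tab$inRange[2])
})

test_that("model configuration files round-trip through YAML and JSON", {
  cfg <- list(n = 4, r = c(0.3, 0.4, 0.6), p = c(0.5, 0.65, 0.85), d = 0.05,
              rho = 0.01, kappa = 1, mode = "jumpwise")
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  my <- readModelConfig(fy)
  expect_equal(divisionRates(my$params), c(0.3, 0.4, 0.6))
  expect_equal(diffProb(my$params), 1 - c(0.5, 0.65, 0.85))
  expect_identical(dediffMode(my$dediff), "jumpwise")

  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  mj <- readModelConfig(fj)
  expect_equal(selfRenewalProb(mj$params), selfRenewalProb(my$params))
  expect_equal(redistributingFactor(mj$dediff), 1)

  shipped <- readModelConfig(system.file("extdata", "example-config.yaml",
                                         package = "hierDediff"))
  expect_equal(leadingCompartment(shipped$params)$lambda0, 0.42)

  expect_error(readModelConfig(tempfile(fileext = ".yaml")), "not found")
  cfg$rho <- NULL; cfg$kappa <- NULL
  yaml::write_yaml(cfg, fy)
  expect_error(readModelConfig(fy), "all of mode")
  unlink(c(fy, fj))
})

test_that("the CLI lists fixtures, validates, and reports thresholds and gradients", {
  expect_identical(runCLI("fixtures"), 0L)
  out <- capture.output(runCLI("fixtures"))
  expect_length(out, 11)

  expect_output(code <- runCLI(c("validate", "--fixture", "fig6a")), "ok")
  expect_identical(code, 0L)

  out <- capture.output(code <- runCLI(c(
    "rate-threshold", "--fixture", "fig6a", "--mode", "jumpwise",
    "--kappa", "1", "--rate", "1", "--bracket", "0.01", "0.6")))
  expect_identical(code, 0L)
  expect_identical(out, "0.450000")

  out <- capture.output(code <- runCLI(c(
    "gradient", "--fixture", "fig6a", "--set", "r1=0.3", "--mode", "jumpwise",
    "--kappa", "1", "--method", "all")))
  expect_identical(code, 0L)
  vals <- as.numeric(sub(".*=", "", out))
  expect_length(vals, 3)
  expect_true(all(abs(vals - (-1 / 3)) < 0.02))
  expect_delta_equal(vals[1], vals[2], 1e-9)
})

test_that("the CLI writes matrix and scan CSVs and signals usage errors", {
  f <- tempfile(fileext = ".csv")
  code <- runCLI(c("matrix", "--fixture", "fig6a", "--matrix", "A0",
                   "--out", f, "-q"))
  expect_identical(code, 0L)
  m <- readResultsCSV(f)
  expect_equal(m$c3[3], 0.42)

  f2 <- tempfile(fileext = ".csv")
  code <- runCLI(c("scan", "--fixture", "fig6a", "--axis", "kappa=0:1:5",
                   "--set", "r1=0.3", "--out", f2, "-q", "--seed", "3"))
  expect_identical(code, 0L)
  tab <- readResultsCSV(f2)
  expect_equal(tab$closed_form, 2 / 3 - seq(0, 1, 0.25), tolerance = 1e-10)
  expect_true(any(grepl("^# seed: 3", readLines(f2))))

  expect_identical(suppressMessages(runCLI("frobnicate")), 2L)
  expect_identical(suppressMessages(runCLI(c("gradient", "--bogus"))), 2L)
  expect_identical(suppressMessages(
    runCLI(c("validate", "--fixture", "fig3b", "--set", "kappa=0.9"))), 2L)
  unlink(c(f, f2))
})

test_that("simulate reports the tail growth rate consistent with the spectrum", {
  out <- capture.output(code <- runCLI(c(
    "simulate", "--fixture", "fig6a", "--set", "r1=0.3", "--matrix", "A0",
    "-q")))
  expect_identical(code, 0L)
  vals <- setNames(sub(".*=", "", out), sub("=.*", "", out))
  expect_equal(as.numeric(vals["lambda"]), 0.42)
  expect_delta_equal(as.numeric(vals["tail_growth_rate"]), 0.42, 1e-3)
})
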