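rawProjection <- function(entries, tag = "A0") {
  new("ProjectionMatrix", entries = entries, tag = tag, paramsHash = "raw")
}

triDiag <- function(diagonal, sub) {
  n <- length(diagonal)
  m <- matrix(0, n, n)
  diag(m) <- diagonal
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- sub
  m
}

test_that("dominant spectrum of a triangular resident is its maximal diagonal entry", {
  m <- rawProjection(triDiag(c(0.2, -0.2, -1), c(0.8, 1.2)))
  sp <- dominantSpectrum(m)
  expect_identical(dominantEigenvalue(sp), 0.2)
  expect_identical(leadingIndex(sp), 1L)
  expect_equal(spectralGap(sp), 0.4)
  expect_true(isSimple(sp))

  fx <- bindFixture("fig6a", values = list(r1 = 0.3))
  sp6 <- dominantSpectrum(buildA0(fx$params))
  expect_identical(dominantEigenvalue(sp6), 0.42)
  expect_identical(leadingIndex(sp6), 3L)
})

test_that("a tied maximum is reported as a degenerate dominant eigenvalue", {
  m <- rawProjection(triDiag(c(0.3, 0.3, -1), c(0.4, 0.4)))
  expect_error(dominantSpectrum(m), "degenerate")
  sp <- dominantSpectrum(m, requireSimple = FALSE)
  expect_false(isSimple(sp))
  expect_true(all(is.na(leftEigenvector(sp))))
})

test_that("eigenvectors satisfy the eigen-relations and the mu'eta = 1 normalization", {
  cases <- c(lapply(randomCases(12, seedOffset = 300), function(cs)
               buildA0(cs$params)),
             lapply(randomCases(6, seedOffset = 320), function(cs)
               buildMutantMatrix(cs$params,
                 dediffSpec(if (cs$j0 == 1) "jumpwise" else "stepwise",
                            0.01, 0.5))))
  for (m in cases) {
    sp <- dominantSpectrum(m)
    a <- as.matrix(m)
    lam <- dominantEigenvalue(sp)
    mu <- leftEigenvector(sp); eta <- rightEigenvector(sp)
    scale <- max(1, abs(lam))
    expect_lt(max(abs(a %*% eta - lam * eta)) / scale, 1e-10)
    expect_lt(max(abs(crossprod(mu, a) - lam * mu)) / scale, 1e-10)
    expect_equal(sum(mu * eta), 1, tolerance = 1e-12)
  }
})

test_that("leadingCompartment matches the effective self-renewal maximum and rejects edge cases", {
  fx <- bindFixture("fig2a", values = list(p1 = 0.8, r2 = 0.3))
  lead <- leadingCompartment(fx$params)
  expect_identical(lead$j0, 1L)
  expect_equal(lead$lambda0, 0.594)

  hp <- randomParams(17, "homeostatic", j0Target = 2)
  lead2 <- leadingCompartment(hp)
  expect_identical(lead2$j0, 2L)
  expect_identical(lead2$lambda0, 0)

  # shrinking and tied residents cannot be constructed; probe via validateModel
  expect_match(validateModel(list(n = 4, r = c(1, 1, 1),
                                  p = c(0.2, 0.3, 0.1), d = 0.05)),
               "shrinking")
})

test_that("gammaTerm evaluates the closed-form ratio and flags degenerate pairs", {
  fx <- bindFixture("fig6a", values = list(r1 = 0.3))
  expect_equal(gammaTerm(fx$params, 2, 3, 2), 0.28 / 0.30)
  expect_equal(gammaTerm(fx$params, 1, 3, 1), 0.3 / 0.42)

  # at homeostasis with j0 = 2, Gamma[1,2,1] = 2 q1 / (q1 - p1) independent of r1
  hp <- hierarchyParams(4, r = c(0.7, 0.5, 0.9), p = c(0.2, 0.5, 0.1),
                        d = 0.1)
  expect_equal(gammaTerm(hp, 1, 2, 1), 2 * 0.8 / 0.6)
  expect_gt(gammaTerm(hp, 1, 2, 1), 1)

  expect_error(gammaTerm(fx$params, 1, 2, 2), "zero denominator")
  expect_error(gammaTerm(fx$params, 1, 2, 5), "1..n-1")
})

test_that("closed-form stepwise gradient follows the three leading-compartment cases", {
  # j0 = 1: Gamma[1,1,2], kappa-independent
  fx <- bindFixture("fig2a", values = list(p1 = 0.8, r2 = 0.3))
  res <- gradientStepwiseClosed(fx$params, kappa = 0.1)
  expect_equal(deltaLambda(res), 2 * 0.99 * 0.2 / (0.594 - 0.03))
  expect_equal(deltaLambda(res), 0.70213, tolerance = 1e-5)
  expect_identical(deltaLambda(gradientStepwiseClosed(fx$params, kappa = 1)),
                   deltaLambda(res))
  expect_identical(gammaTerms(res)[, c("j", "k", "l")],
                   data.frame(j = 1L, k = 1L, l = 2L))

  # 1 < j0 < n-1: Gamma[j0-1,j0,j0-1] + Gamma[j0,j0,j0+1] - kappa
  fx4 <- bindFixture("fig4", values = list(p2 = 0.9, kappa = 0))
  res4 <- gradientStepwiseClosed(fx4$params, kappa = 0)
  expect_equal(deltaLambda(res4), 0.38038, tolerance = 1e-5)
  expect_equal(gammaTerms(res4)$value, c(0.27757, 0.10281), tolerance = 1e-4)

  # j0 = n-1: Gamma[n-2,n-1,n-2] - kappa
  fx6 <- bindFixture("fig6a", values = list(r1 = 0.3))
  res6 <- gradientStepwiseClosed(fx6$params, kappa = 1)
  expect_equal(deltaLambda(res6), 0.28 / 0.30 - 1)
})

test_that("closed-form jumpwise gradient is the Gamma product with the kappa case at j0 = n-1", {
  fx <- bindFixture("fig6a", values = list(r1 = 0.3))
  res <- gradientJumpwiseClosed(fx$params, kappa = 1)
  expect_equal(deltaLambda(res), (0.3 / 0.42) * (0.28 / 0.30) - 1)
  expect_equal(deltaLambda(res), -1 / 3, tolerance = 1e-12)

  # at the printed threshold rate the gradient vanishes
  fx45 <- bindFixture("fig6a", values = list(r1 = 0.45))
  expect_equal(deltaLambda(gradientJumpwiseClosed(fx45$params, kappa = 1)), 0,
               tolerance = 1e-12)

  # j0 < n-1: kappa-independent product
  fx5 <- bindFixture("fig5b")
  r0 <- deltaLambda(gradientJumpwiseClosed(fx5$params, kappa = 0))
  r1 <- deltaLambda(gradientJumpwiseClosed(fx5$params, kappa = 1))
  expect_identical(r0, r1)
  expect_gt(r0, 0)
})

test_that("perturbation gradient agrees with the closed form to 1e-9", {
  for (fx in allFixturesBound()) {
    closed <- gradientClosed(fx$params, fx$dediff)
    pert <- gradientPerturbation(fx$params, fx$dediff)
    expect_delta_equal(deltaLambda(closed), deltaLambda(pert), 1e-9)
  }
  fx6 <- bindFixture("fig6a", values = list(r1 = 0.3, kappa = 1))
  expect_equal(deltaLambda(gradientPerturbation(fx6$params, fx6$dediff)),
               -1 / 3, tolerance = 1e-9)
})

test_that("the kappa coefficient of the perturbation gradient is the exact closed-form slope", {
  fx <- bindFixture("fig6a", values = list(r1 = 0.3))
  g0 <- deltaLambda(gradientPerturbation(fx$params,
                                         dediffSpec("jumpwise", 0.01, 0)))
  g1 <- deltaLambda(gradientPerturbation(fx$params,
                                         dediffSpec("jumpwise", 0.01, 1)))
  expect_equal(g0 - g1, 1, tolerance = 1e-10)
})

test_that("exact finite-rho gradient approaches the closed form as rho shrinks", {
  fx <- bindFixture("fig6a", values = list(r1 = 0.3, kappa = 1))
  closed <- deltaLambda(gradientClosed(fx$params, fx$dediff))
  errAt <- function(rho) {
    spec <- dediffSpec("jumpwise", rho = rho, kappa = 1)
    abs(deltaLambda(gradientExact(fx$params, spec)) - closed)
  }
  e1 <- errAt(0.01); e2 <- errAt(0.005)
  expect_lt(e1, 10 * 0.01)
  expect_lt(e2 / e1, 0.65)  # first-order error halves with rho
  expect_gt(e2 / e1, 0.35)

  # extrapolation oracle in the small-rho regime
  rich <- gradientExact(fx$params, dediffSpec("jumpwise", 5e-4, 1),
                        richardson = TRUE)
  expect_delta_equal(deltaLambda(rich), closed, 1e-6)

  expect_error(gradientExact(fx$params, dediffSpec("jumpwise", 0, 1)),
               "rho > 0")
})

test_that("criticalKappa returns the crossing or the one-signed verdicts", {
  fx <- bindFixture("fig6a", values = list(r1 = 0.3))
  ck <- criticalKappa(fx$params, "jumpwise")
  expect_identical(ck$status, "critical")
  expect_equal(ck$kappaCritical, 2 / 3, tolerance = 1e-12)

  fx2 <- bindFixture("fig6a", values = list(r1 = 0.6))
  ck2 <- criticalKappa(fx2$params, "jumpwise")
  expect_identical(ck2$status, "always_positive")
  expect_true(ck2$kappaDependent)

  fx1 <- bindFixture("fig2a")
  ck3 <- criticalKappa(fx1$params, "stepwise")
  expect_identical(ck3$status, "always_positive")
  expect_false(ck3$kappaDependent)
  expect_gt(ck3$gradient, 0)
})

test_that("criticalRate finds the invasion threshold by bisection and guards its assumptions", {
  fx <- bindFixture("fig6a")
  root <- criticalRate(fx$params, "jumpwise", rateIndex = 1,
                       bracket = c(0.01, 0.6))
  expect_equal(root, 0.45, tolerance = 1e-6)
  # closed-form expression for the same threshold
  expect_equal(root, 0.42 / (0.28 / 0.30), tolerance = 1e-6)

  expect_error(criticalRate(fx$params, "jumpwise", 1, c(0.5, 0.6)),
               "does not change sign")
  # scanning r3 across the j0 = 2/3 boundary is rejected
  expect_error(criticalRate(fx$params, "jumpwise", 3, c(0.05, 0.6)),
               "leading compartment changes")
})
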