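# Angle wrapping, the fitting objective, differential evolution and DRAM.

test_that("wrapAngle follows the half-open [-180, 180) convention", {
  expect_identical(wrapAngle(180), -180)
  expect_identical(wrapAngle(-180), -180)
  expect_identical(wrapAngle(-182), 178)
  expect_identical(wrapAngle(0), 0)
  expect_equal(wrapAngle(c(360, -360, 540, 725)), c(0, 0, -180, 5))
  # idempotent
  x <- seq(-1000, 1000, by = 7.3)
  expect_equal(wrapAngle(wrapAngle(x)), wrapAngle(x))
  expect_true(all(wrapAngle(x) >= -180 & wrapAngle(x) < 180))
  expect_error(wrapAngle(NA_real_))
})

test_that("the (theta+180, 180-phi) twin is an exact model degeneracy", {
  m <- smallModel()
  ct <- contrastDefinition("D2O", "D2O")
  for (a in list(c(30, 45), c(-10, 120), c(77, -160))) {
    # identical rotated z coordinates, hence identical profiles
    z1 <- rotateModel(m, a[1], a[2])@coords[, 3]
    z2 <- rotateModel(m, a[1] + 180, 180 - a[2])@coords[, 3]
    expect_equal(z1, z2, tolerance = 1e-12)
    s1 <- sliceTable(assembleProfile(m, adsorptionState(a[1], a[2], 5, 1.5),
                                     ct))$sld
    s2 <- sliceTable(assembleProfile(
      m, adsorptionState(a[1] + 180, 180 - a[2], 5, 1.5), ct))$sld
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("canonicalAngles fixes the degeneracy gauge", {
  ca <- canonicalAngles(-150, 135)
  expect_equal(c(ca$theta, ca$phi), c(30, 45))
  # already canonical: unchanged
  expect_equal(canonicalAngles(30, 45), list(theta = 30, phi = 45))
  # idempotent everywhere, including the self-symmetric boundary
  for (a in list(c(30, 45), c(0, 90), c(10, -90), c(-170, 179))) {
    c1 <- canonicalAngles(a[1], a[2])
    c2 <- canonicalAngles(c1$theta, c1$phi)
    expect_equal(c1, c2)
    expect_true(c1$phi >= -90 && c1$phi <= 90)
  }
})

test_that("fitProblem assembles bounds and nuisance parameters", {
  ex <- recoveryExperiment()
  p <- ex$problem
  expect_equal(names(p@lower), c("theta", "phi", "zPen", "gamma"))
  expect_equal(unname(p@lower), c(-180, -180, 0, 0))
  expect_equal(unname(p@upper[1:2]), c(180, 180))
  # default zPen bound is the bounding-sphere diameter
  cc <- sweep(beadCoords(ex$model), 2, colMeans(beadCoords(ex$model)))
  expect_equal(unname(p@upper[["zPen"]]), 2 * sqrt(max(rowSums(cc^2))))
  pb <- fitProblem(ex$model, ex$contrasts, ex$sim$curves,
                   freeNuisance = "both")
  expect_equal(length(pb@lower), 4 + 2 * 3)
  expect_true(all(c("bg1", "scale3") %in% names(pb@lower)))
})

test_that("the internal objective agrees with the public pipeline", {
  ex <- recoveryExperiment()
  st <- adsorptionState(12, -80, 6, 1.7)
  direct <- sum(vapply(seq_along(ex$contrasts), function(i)
    chiSquared(simulateContrast(ex$model, st, ex$contrasts[[i]]),
               ex$sim$curves[[i]]), 0))
  expect_equal(problemChiSquared(ex$problem, st), direct, tolerance = 1e-10)
})

test_that("the objective rejects out-of-bounds parameters", {
  ex <- recoveryExperiment()
  obj <- rbrnr:::.makeObjective(ex$problem)
  expect_false(is.finite(obj(c(0, 0, -1, 1))))
  expect_false(is.finite(obj(c(0, 0, 5, 100))))
  expect_true(is.finite(obj(c(0, 0, 5, 1))))
})

test_that("bestFit recovers the three-contrast ground truth", {
  ex <- recoveryExperiment()
  fit <- recoveryFit()
  # the fit must match the data at least as well as the generating truth
  obj <- rbrnr:::.makeObjective(ex$problem)
  chi2Truth <- obj(c(30, 45, 10, 2.0))
  expect_lt(fit$chi2, 1.2 * chi2Truth)
  # and recover the generating profile closely (angles are reported in the
  # canonical gauge, phi in [-90, 90))
  sc <- recoveryScore(fit$state, recoveryTruth(), ex$model, ex$contrasts)
  expect_lt(sc$profileRMSFraction, 0.05)
  expect_s4_class(fit$state, "AdsorptionState")
  expect_gte(fit$state@phi, -90)
  expect_lt(fit$state@phi, 90)
  expect_gt(fit$evaluations, 1000)
})

test_that("DRAM reproduces an analytic Gaussian target", {
  lp <- function(p) -0.5 * sum(((p - c(2, -1)) / c(0.5, 1.5))^2)
  ch <- runMCMC(nSteps = 20000, nBurn = 4000, seed = 5, logPost = lp,
                init = c(0, 0), lower = c(-20, -20), upper = c(20, 20))[[1]]
  pb <- postBurn(ch)
  expect_equal(colMeans(pb), c(p1 = 2, p2 = -1), tolerance = 0.12)
  expect_equal(apply(pb, 2, sd), c(p1 = 0.5, p2 = 1.5), tolerance = 0.15)
  expect_gt(acceptanceRate(ch), 0.1)
  expect_lte(acceptanceRate(ch), 1)
})

test_that("MCMC repeats are reproducible and independent", {
  lp <- function(p) -0.5 * sum(p^2)
  a <- runMCMC(nSteps = 2000, nBurn = 500, nRepeats = 2, seed = 9,
               logPost = lp, init = 0, lower = -10, upper = 10)
  b <- runMCMC(nSteps = 2000, nBurn = 500, nRepeats = 2, seed = 9,
               logPost = lp, init = 0, lower = -10, upper = 10)
  expect_identical(a[[1]]@samples, b[[1]]@samples)
  expect_false(identical(a[[1]]@samples, a[[2]]@samples))
  expect_equal(a[[1]]@repeatId, 1)
  expect_equal(a[[2]]@repeatId, 2)
})

test_that("chains respect bounds and keep angles wrapped", {
  lp <- function(p) -0.5 * ((wrapAngle(p[1] - 170) / 20)^2 + (p[2] / 2)^2)
  ch <- runMCMC(nSteps = 5000, nBurn = 1000, seed = 2, logPost = lp,
                init = c(170, 0), lower = c(-180, -8), upper = c(180, 8),
                angleIdx = 1)[[1]]
  sm <- ch@samples
  expect_true(all(sm[, 1] >= -180 & sm[, 1] < 180))
  expect_true(all(sm[, 2] >= -8 & sm[, 2] <= 8))
  # the periodic chain populates both sides of the seam around +-180
  expect_gt(mean(sm[, 1] > 150), 0.05)
  expect_gt(mean(sm[, 1] < -150), 0.02)
})

test_that("combineChains concatenates post-burn segments", {
  lp <- function(p) -0.5 * sum(p^2)
  chains <- runMCMC(nSteps = 1500, nBurn = 300, nRepeats = 3, seed = 4,
                    logPost = lp, init = 0, lower = -10, upper = 10)
  comb <- combineChains(chains)
  expect_equal(nrow(comb@samples), 3 * 1200)
  expect_equal(comb@nBurn, 0)
  expect_equal(comb@provenance$segments$length, rep(1200L, 3))
  bad <- chains[[1]]
  colnames(bad@samples) <- "other"
  expect_error(combineChains(list(chains[[2]], bad)), "inconsistent")
})
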