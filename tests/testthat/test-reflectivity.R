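# Reflectivity: optical matrix method against closed-form oracles, solvent
# presets, smearing, goodness of fit and data I/O.

test_that("a bare interface reproduces the closed-form Fresnel curve", {
  q <- seq(0.005, 0.4, length.out = 500)
  pr <- bareInterfaceProfile(sldSubstrate = 0, sldSolvent = 6.35)
  r <- reflectivityFromProfile(pr, q)
  expect_lt(max(abs(r - fresnelOracle(q, 0, 6.35))), 1e-10)
  # reversed contrast (incident medium denser)
  pr2 <- bareInterfaceProfile(sldSubstrate = 5.65, sldSolvent = 0)
  r2 <- reflectivityFromProfile(pr2, q)
  expect_lt(max(abs(r2 - fresnelOracle(q, 5.65, 0))), 1e-10)
})

test_that("total reflection holds below the critical edge", {
  drho <- 6.35e-6
  qc <- sqrt(16 * pi * drho)
  q <- seq(0.0005, qc * 0.999, length.out = 50)
  pr <- bareInterfaceProfile(0, 6.35)
  expect_equal(reflectivityFromProfile(pr, q), rep(1, 50), tolerance = 1e-12)
  # just above the edge the reflectivity drops
  expect_lt(reflectivityFromProfile(pr, qc * 1.05), 1)
})

test_that("a uniform film reproduces the two-interface Airy formula", {
  q <- seq(0.008, 0.35, length.out = 300)
  pr <- filmProfile(sldSubstrate = 0, sldFilm = 3.2, sldSolvent = 6.0,
                    thickness = 48, nSlices = 40)
  r <- reflectivityFromProfile(pr, q)
  expect_lt(max(abs(r - airyOracle(q, 0, 3.2, 6.0, 48))), 1e-10)
})

test_that("Kiessig fringe spacing matches the film thickness", {
  thickness <- 100
  q <- seq(0.05, 0.35, length.out = 3000)
  pr <- filmProfile(0, 4, 6.35, thickness)
  r <- log(reflectivityFromProfile(pr, q))
  mins <- which(diff(sign(diff(r))) > 0) + 1
  expect_gt(length(mins), 3)
  expect_equal(mean(diff(q[mins])), 2 * pi / thickness, tolerance = 0.02)
})

test_that("subdividing slices does not change the reflectivity", {
  q <- exp(seq(log(0.008), log(0.3), length.out = 60))
  pr1 <- filmProfile(0, 3, 6.35, 50, nSlices = 10)
  pr2 <- filmProfile(0, 3, 6.35, 50, nSlices = 250)
  expect_equal(reflectivityFromProfile(pr1, q),
               reflectivityFromProfile(pr2, q), tolerance = 1e-12)
})

test_that("solvent presets carry consistent SLD and composition", {
  for (nm in c("NRW", "CM4.5", "CMSapphire")) {
    sp <- solventSpec(nm)
    expect_equal(sp$sld, waterSLD(1 - sp$hFraction))
  }
  expect_equal(solventSpec("NRW")$sld, 0)
  expect_equal(solventSpec("CM4.5")$sld, 4.5)
  expect_equal(solventSpec("CMSapphire")$sld, 5.65)
  expect_equal(solventSpec("H2O")$hFraction, 1)
  expect_equal(solventSpec("D2O")$hFraction, 0)
  expect_equal(solventSpec("custom", sld = 2.56)$sld, 2.56)
  expect_error(solventSpec("brine"), "unknown solvent preset")
})

test_that("resolution smearing is the identity at zero width", {
  q <- seq(0.01, 0.3, length.out = 80)
  pr <- filmProfile(0, 3, 6.35, 50)
  expect_equal(reflectivityFromProfile(pr, q, dq = rep(0, 80)),
               reflectivityFromProfile(pr, q))
  # smearing damps the fringes: smeared curve has smaller variance in log
  sm <- reflectivityFromProfile(pr, q, dq = 0.05 * q)
  expect_lt(stats::var(diff(log(sm))), stats::var(diff(log(
    reflectivityFromProfile(pr, q)))))
})

test_that("simulateContrast applies scale and background", {
  m <- smallModel()
  q <- seq(0.01, 0.2, length.out = 30)
  ct0 <- contrastDefinition("D2O", "D2O", q = q)
  ct1 <- contrastDefinition("D2O", "D2O", q = q, background = 1e-6,
                            scale = 1.2)
  st <- adsorptionState(10, 20, 4, 1.5)
  r0 <- simulateContrast(m, st, ct0)@r
  r1 <- simulateContrast(m, st, ct1)@r
  expect_equal(r1, 1.2 * r0 + 1e-6)
  expect_error(simulateContrast(m, st, contrastDefinition("D2O", "D2O")),
               "no q grid")
})

test_that("chiSquared matches a hand computation and its options work", {
  q <- c(0.01, 0.02, 0.03)
  sim <- reflectivityCurve(q, c(1, 0.5, 0.25))
  obs <- reflectivityCurve(q, c(0.9, 0.55, 0.2), dr = c(0.1, 0.05, 0.05))
  expect_equal(chiSquared(sim, obs), 1 + 1 + 1)
  # list form is additive over contrasts
  expect_equal(chiSquared(list(sim, sim), list(obs, obs)), 6)
  expect_gt(chiSquared(sim, obs, logSpace = TRUE), 0)
  # mismatched grids require interpolation
  obs2 <- reflectivityCurve(c(0.015, 0.025), c(0.7, 0.4), dr = c(0.1, 0.1))
  expect_error(chiSquared(sim, obs2), "mismatched q grids")
  expect_equal(chiSquared(sim, obs2, interpolate = TRUE),
               ((0.75 - 0.7) / 0.1)^2 + ((0.375 - 0.4) / 0.1)^2)
  expect_error(chiSquared(sim, reflectivityCurve(q, c(1, 0.5, 0.25))),
               "no uncertainties")
})

test_that("reflectivity files roundtrip through write and read", {
  q <- seq(0.01, 0.1, length.out = 20)
  cv <- reflectivityCurve(q, exp(-40 * q), dr = 0.01 * exp(-40 * q),
                          dq = 0.03 * q, contrastName = "NRW")
  path <- tempfile(fileext = ".dat")
  writeReflectivityFile(cv, path)
  back <- readReflectivityFile(path, "NRW")
  expect_equal(back@q, cv@q, tolerance = 1e-8)
  expect_equal(back@r, cv@r, tolerance = 1e-8)
  expect_equal(back@dr, cv@dr, tolerance = 1e-8)
  expect_equal(back@dq, cv@dq, tolerance = 1e-8)
  expect_error(readReflectivityFile({
    p <- tempfile(); writeLines("0.01 1.0", p); p
  }), "3 columns")
})

test_that("curve validity catches malformed inputs", {
  expect_error(reflectivityCurve(c(0.02, 0.01), c(1, 1)),
               "strictly increasing")
  expect_error(reflectivityCurve(c(-0.01, 0.02), c(1, 1)), "positive")
  expect_error(reflectivityCurve(c(0.01, 0.02), c(1, -1)), ">= 0")
})
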