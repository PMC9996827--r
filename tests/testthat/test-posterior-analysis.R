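# Toroidal KDE, histograms, HPD regions, intervals and bands.

test_that("kdeTorus normalizes and needs enough samples", {
  set.seed(1)
  s <- cbind(rnorm(2000, 20, 15), rnorm(2000, -40, 10))
  d <- kdeTorus(s, gridRes = 2)
  expect_s4_class(d, "OrientationDensity")
  expect_equal(sum(d@density) * d@cellArea, 1, tolerance = 1e-9)
  expect_true(all(d@density >= 0))
  # mode lands near the sample centre
  peak <- which(d@density == max(d@density), arr.ind = TRUE)[1, ]
  expect_lt(abs(wrapAngle(d@theta[peak[1]] - 20)), 10)
  expect_lt(abs(wrapAngle(d@phi[peak[2]] - (-40))), 10)
  expect_error(kdeTorus(s[1:50, ]), "at least 100 samples")
  expect_error(kdeTorus(s, gridRes = 7), "divide 360")
})

test_that("kdeTorus is continuous across the +-180 seam", {
  set.seed(2)
  # mode straddling the seam: mass at theta near +-180
  s <- cbind(wrapAngle(rnorm(4000, 180, 12)), rnorm(4000, 0, 12))
  d <- kdeTorus(s, gridRes = 1)
  m <- length(d@theta)
  phiMid <- which.min(abs(d@phi))
  # density just below +180 and just above -180 must agree closely
  expect_equal(d@density[m, phiMid], d@density[1, phiMid],
               tolerance = 0.05)
  # and the seam cells carry the maximum, not a trough
  expect_gt(d@density[1, phiMid], max(d@density[m / 2, ]))
})

test_that("an explicit wrap-shifted sample gives a shifted density", {
  set.seed(3)
  s <- cbind(rnorm(3000, 10, 20), rnorm(3000, 5, 20))
  d1 <- kdeTorus(s, gridRes = 2, bandwidth = 8)
  d2 <- kdeTorus(cbind(s[, 1] + 90, s[, 2]), gridRes = 2, bandwidth = 8)
  # shifting by a multiple of the grid translates the density exactly
  shift <- 90 / 2
  expect_equal(d2@density, d1@density[((seq_along(d1@theta) - 1 - shift) %%
                                         length(d1@theta)) + 1, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("histogram2d counts every sample once with half-open bins", {
  s <- rbind(c(-180, -180), c(179.99, 179.99), c(0, 0), c(-0.01, 2.5))
  h <- histogram2d(s, binWidth = 5)
  expect_equal(sum(h), 4L)
  expect_equal(dim(h), c(72, 72))
  expect_equal(h[1, 1], 1L)      # -180 falls in the first bin
  expect_equal(h[72, 72], 1L)
})

test_that("HPD regions on a uniform density have area fraction = level", {
  u <- orientationDensityFromFunction(function(t, p) rep(1, length(t)),
                                      gridRes = 1)
  reg <- hpdRegions(u, levels = c(0.25, 0.65, 0.95))
  expect_equal(reg@areas / 360^2, c(0.25, 0.65, 0.95))
})

test_that("HPD regions of a wrapped Gaussian enclose the nominal mass", {
  wg <- function(t, p) {
    f <- 0
    for (k in -2:2) for (j in -2:2)
      f <- f + exp(-0.5 * (((t - 20 + 360 * k) / 25)^2 +
                           ((p + 40 + 360 * j) / 35)^2))
    f
  }
  d <- orientationDensityFromFunction(wg, gridRes = 1)
  reg <- hpdRegions(d)
  expect_equal(reg@enclosedMass, c(0.25, 0.65, 0.95), tolerance = 0.01)
  # nested by construction
  expect_true(all(reg@masks[[3]][reg@masks[[2]]]))
  expect_true(all(reg@masks[[2]][reg@masks[[1]]]))
  # membership: mode inside every level, antipode outside the 25% region
  expect_true(hpdrContains(reg, d, 0.25, 20, -40))
  expect_false(hpdrContains(reg, d, 0.25, -160, 140))
  expect_error(hpdrContains(reg, d, 0.5, 0, 0), "level not present")
})

test_that("univariateInterval reports mean and sd", {
  set.seed(4)
  x <- rnorm(5000, 3, 0.7)
  ui <- univariateInterval(x)
  expect_equal(ui$mean, mean(x))
  expect_equal(ui$sd, sd(x))
  expect_warning(univariateInterval(rep(1, 10)), "zero-width")
  expect_error(univariateInterval(1), "at least 2")
})

test_that("profileBands brackets a linear evaluator's quantiles", {
  set.seed(5)
  n <- 5000
  sm <- cbind(a = rnorm(n), b = rnorm(n))
  ch <- new("MCMCChain", samples = sm, logPost = rep(0, n), nBurn = 0,
            seed = 1, repeatId = 1, acceptanceRate = 0.5,
            provenance = list())
  bands <- profileBands(ch, function(p) c(p[1], p[1] + 10), nDraws = 3000,
                        level = 0.65)
  expect_equal(bands$nUsed, 3000)
  expect_equal(bands$upper - bands$lower, rep(2 * qnorm(0.825), 2),
               tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(bands$lower[2] - bands$lower[1], 10, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(profileBands(ch, identity, nDraws = n), "longer than")
  expect_warning(
    profileBands(ch, function(p) if (p[1] > 1) stop("x") else p[1],
                 nDraws = 200), "dropped")
})

test_that("density CSV export matches the grid", {
  set.seed(6)
  d <- kdeTorus(cbind(rnorm(500, 0, 30), rnorm(500, 0, 30)), gridRes = 10)
  path <- tempfile(fileext = ".csv")
  writeDensityCSV(d, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 36^2)
  expect_equal(sum(back$density) * d@cellArea, 1, tolerance = 1e-9)
})
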