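# Posterior summaries: toroidal KDE, 2D histograms, HPD regions, univariate
# intervals and profile/reflectivity confidence bands.

# Data-driven smoothing bandwidth for circular data (degrees). The sample is
# recentred on its circular mean so the seam does not split the bulk, then a
# Sheather-Jones plug-in is applied (falling back to the normal-reference
# rule, and to half a grid cell for degenerate samples).
.circBandwidth <- function(x, gridRes) {
  rad <- x * pi / 180
  mu <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  y <- wrapAngle(x - mu)
  if (stats::sd(y) < 1e-10) return(gridRes / 2)
  h <- tryCatch(stats::bw.SJ(y), error = function(e) stats::bw.nrd0(y))
  max(h, gridRes / 2)
}

# Periodic Gaussian (heat-kernel) smoothing of a matrix by FFT, bandwidths in
# grid-axis units matching the period 360.
.torusSmooth <- function(counts, bwTheta, bwPhi) {
  m <- nrow(counts); p <- ncol(counts)
  att <- function(n, bw) {
    k <- 0:(n - 1)
    kk <- ifelse(k <= n / 2, k, k - n)
    exp(-0.5 * (2 * pi * kk / 360)^2 * bw^2)
  }
  G <- stats::fft(counts)
  G <- G * outer(att(m, bwTheta), att(p, bwPhi))
  sm <- Re(stats::fft(G, inverse = TRUE)) / (m * p)
  pmax(sm, 0)
}

#' Toroidal kernel density estimate of the orientation posterior
#'
#' Diffusion (heat-kernel) density estimate on the periodic (theta, phi)
#' grid: samples are binned, then smoothed by the heat kernel on the torus
#' via 2D FFT, with per-dimension data-driven bandwidths. Periodicity is
#' intrinsic to the solver, so the density is continuous across the +/-180
#' seams and integrates to 1.
#'
#' @param samples n x 2 matrix (theta, phi) in degrees; n >= 100 (bandwidth
#'   estimation is unreliable below that).
#' @param gridRes grid resolution in degrees (default 1; must divide 360).
#' @param bandwidth optional fixed bandwidths (degrees, length 1 or 2)
#'   overriding the data-driven choice.
#' @return an \code{OrientationDensity}.
#' @export
kdeTorus <- function(samples, gridRes = 1, bandwidth = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 100)
    stop("need at least 100 samples for a stable bandwidth estimate")
  if (360 %% gridRes != 0) stop("gridRes must divide 360")
  m <- as.integer(360 / gridRes)
  th <- wrapAngle(samples[, 1]); ph <- wrapAngle(samples[, 2])
  it <- pmin(floor((th + 180) / gridRes) + 1L, m)
  ip <- pmin(floor((ph + 180) / gridRes) + 1L, m)
  counts <- matrix(0, m, m)
  tb <- table(factor(it, levels = seq_len(m)), factor(ip, levels = seq_len(m)))
  counts[] <- as.numeric(tb)
  if (is.null(bandwidth)) {
    bandwidth <- c(.circBandwidth(th, gridRes), .circBandwidth(ph, gridRes))
  } else {
    bandwidth <- rep_len(bandwidth, 2)
  }
  dens <- .torusSmooth(counts, bandwidth[1], bandwidth[2])
  cellArea <- gridRes^2
  dens <- dens / (sum(dens) * cellArea)
  centres <- -180 + (seq_len(m) - 0.5) * gridRes
  new("OrientationDensity", theta = centres, phi = centres, density = dens,
      cellArea = cellArea, bandwidth = bandwidth)
}

#' Construct an orientation density from an analytic function
#'
#' Evaluates a bivariate density function on the periodic grid and
#' normalizes it; useful for calibration against analytic targets such as
#' wrapped Gaussians.
#'
#' @param f function(theta, phi) returning unnormalized density values
#'   (vectorized over theta for fixed phi).
#' @param gridRes grid resolution in degrees.
#' @return an \code{OrientationDensity}.
#' @export
orientationDensityFromFunction <- function(f, gridRes = 1) {
  m <- as.integer(360 / gridRes)
  centres <- -180 + (seq_len(m) - 0.5) * gridRes
  dens <- outer(centres, centres, f)
  dens <- pmax(dens, 0)
  cellArea <- gridRes^2
  dens <- dens / (sum(dens) * cellArea)
  new("OrientationDensity", theta = centres, phi = centres, density = dens,
      cellArea = cellArea, bandwidth = c(0, 0))
}

#' Periodic 2D histogram of orientation samples
#'
#' Counts on the periodic (theta, phi) lattice with half-open bins starting
#' at -180 (a sample at exactly -180 falls in the first bin).
#'
#' @param samples n x 2 matrix (theta, phi), degrees.
#' @param binWidth bin width in degrees; must divide 360 (default 5).
#' @return matrix of counts with bin-centre dimnames; sums to n.
#' @export
histogram2d <- function(samples, binWidth = 5) {
  if (360 %% binWidth != 0) stop("binWidth must divide 360")
  samples <- as.matrix(samples)
  m <- as.integer(360 / binWidth)
  it <- pmin(floor((wrapAngle(samples[, 1]) + 180) / binWidth) + 1L, m)
  ip <- pmin(floor((wrapAngle(samples[, 2]) + 180) / binWidth) + 1L, m)
  counts <- matrix(0L, m, m)
  tb <- table(factor(it, levels = seq_len(m)), factor(ip, levels = seq_len(m)))
  counts[] <- as.integer(tb)
  centres <- -180 + (seq_len(m) - 0.5) * binWidth
  dimnames(counts) <- list(theta = centres, phi = centres)
  counts
}

#' Highest-posterior-density regions of an orientation density
#'
#' For each probability level, thresholds the density at the smallest value
#' whose super-level set encloses at least that much mass (grid cells are
#' sorted by density, descending, ties broken by cell index for
#' determinism). Regions are nested across levels by construction.
#'
#' @param density an \code{OrientationDensity} (normalized).
#' @param levels probability levels (default 0.25, 0.65, 0.95).
#' @return an \code{HPDRegionSet}.
#' @export
hpdRegions <- function(density, levels = c(0.25, 0.65, 0.95)) {
  stopifnot(is(density, "OrientationDensity"))
  levels <- sort(levels)
  d <- density@density
  mass <- sum(d) * density@cellArea
  if (abs(mass - 1) > 1e-6) stop("density is not normalized")
  ord <- order(d, decreasing = TRUE)   # ties broken by cell index
  cum <- cumsum(d[ord]) * density@cellArea
  masks <- vector("list", length(levels))
  areas <- enclosed <- numeric(length(levels))
  for (i in seq_along(levels)) {
    k <- which(cum >= levels[i] - 1e-12)[1]
    if (is.na(k)) k <- length(ord)
    msk <- matrix(FALSE, nrow(d), ncol(d))
    msk[ord[seq_len(k)]] <- TRUE
    masks[[i]] <- msk
    areas[i] <- k * density@cellArea
    enclosed[i] <- cum[k]
  }
  new("HPDRegionSet", levels = levels, masks = masks, areas = areas,
      enclosedMass = enclosed)
}

#' Does an HPD region contain an orientation?
#'
#' @param regions an \code{HPDRegionSet} built on \code{density}'s grid.
#' @param density the \code{OrientationDensity} the regions came from.
#' @param level which probability level to query.
#' @param theta,phi orientation, degrees.
#' @return logical.
#' @export
hpdrContains <- function(regions, density, level, theta, phi) {
  i <- match(level, regions@levels)
  if (is.na(i)) stop("level not present in the region set")
  gridRes <- sqrt(density@cellArea)
  m <- length(density@theta)
  it <- pmin(floor((wrapAngle(theta) + 180) / gridRes) + 1L, m)
  ip <- pmin(floor((wrapAngle(phi) + 180) / gridRes) + 1L, m)
  regions@masks[[i]][cbind(it, ip)]
}

#' Univariate credible interval as mean +/- standard deviation
#'
#' The univariate parameters (Gamma, penetration depth) are close to
#' Gaussian in the posterior, so their intervals are reported as the sample
#' mean plus/minus the sample standard deviation.
#'
#' @param x numeric samples (>= 2).
#' @return list with \code{mean} and \code{sd}.
#' @export
univariateInterval <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  s <- stats::sd(x)
  if (s == 0) warning("constant chain: zero-width interval")
  list(mean = mean(x), sd = s)
}

#' Pointwise posterior confidence bands for profiles or reflectivity
#'
#' Draws \code{nDraws} states from the post-burn-in chain, evaluates a
#' user-supplied curve for each (an SLD profile or a reflectivity curve on a
#' fixed abscissa), and returns the central band covering the stated level
#' at each abscissa via interpolated percentiles.
#'
#' @param chain an \code{MCMCChain} whose post-burn-in part has more than
#'   \code{nDraws} steps.
#' @param evaluator function(parameter vector) -> numeric curve of fixed
#'   length. A draw on which the evaluator fails is dropped with a warning.
#' @param nDraws number of chain draws (default 3000).
#' @param level central coverage level (default 0.65).
#' @param seed RNG seed for the draw.
#' @return list with \code{lower}, \code{upper} (per-abscissa), \code{level}
#'   and \code{nUsed}.
#' @export
profileBands <- function(chain, evaluator, nDraws = 3000, level = 0.65,
                         seed = 1) {
  pb <- postBurn(chain)
  if (nrow(pb) <= nDraws)
    stop("post-burn-in chain must be longer than nDraws")
  set.seed(seed)
  rows <- sample.int(nrow(pb), nDraws)
  curves <- vector("list", nDraws)
  ok <- logical(nDraws)
  for (i in seq_len(nDraws)) {
    v <- tryCatch(evaluator(pb[rows[i], ]), error = function(e) NULL)
    if (!is.null(v)) { curves[[i]] <- v; ok[i] <- TRUE }
  }
  if (!all(ok))
    warning(sum(!ok), " draw(s) failed evaluation and were dropped")
  if (!any(ok)) stop("evaluator failed on every draw")
  mat <- do.call(rbind, curves[ok])
  lo <- (1 - level) / 2
  qs <- apply(mat, 2, stats::quantile, probs = c(lo, 1 - lo), names = FALSE)
  list(lower = qs[1, ], upper = qs[2, ], level = level, nUsed = sum(ok))
}

#' Export an orientation density as gridded CSV
#'
#' @param density an \code{OrientationDensity}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDensityCSV <- function(density, path) {
  grid <- expand.grid(theta = density@theta, phi = density@phi)
  grid$density <- as.vector(density@density)
  utils::write.table(grid, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
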