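# Best-fit search (differential evolution) and DRAM posterior sampling with
# periodic angular boundaries.

#' Wrap an angle into [-180, 180)
#'
#' Subtracts the integer multiple of 360 placing the angle in range;
#' idempotent. wrap(180) = -180 by the half-open convention. A proposal
#' stepping 3 degrees past -179 lands at +178.
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in [-180, 180).
#' @export
wrapAngle <- function(x) {
  stopifnot(all(is.finite(x)))
  ((x + 180) %% 360) - 180
}

#' Canonical representative of the exact orientation degeneracy
#'
#' In the XY rotation system the slab profile depends on the protein only
#' through the rotated z coordinates, and
#' \code{z(theta, phi) = z(theta + 180, 180 - phi)} holds identically, so
#' every orientation has an exactly equivalent twin. This gauge is fixed by
#' reporting the class member with \code{phi} in [-90, 90); orientations on
#' the self-symmetric boundary (phi = +/-90) are left unchanged.
#'
#' @param theta,phi angles in degrees (vectors allowed).
#' @return list with wrapped, canonicalized \code{theta} and \code{phi}.
#' @export
canonicalAngles <- function(theta, phi) {
  th <- wrapAngle(theta)
  ph <- wrapAngle(phi)
  flip <- (ph < -90 | ph >= 90) & wrapAngle(180 - ph) != ph
  list(theta = ifelse(flip, wrapAngle(th + 180), th),
       phi = ifelse(flip, wrapAngle(180 - ph), ph))
}

#' Assemble a fitting problem
#'
#' Bundles a canonicalized model, the per-contrast datasets, the slicing
#' settings, and the parameter box. The free parameters are theta and phi
#' (periodic), the penetration depth zPen, the surface excess gamma, and
#' optionally per-contrast background and/or scale nuisance parameters.
#' Priors are uniform over the bounds.
#'
#' @param model a canonicalized \code{ProteinModel}.
#' @param contrasts list of \code{ContrastDefinition}.
#' @param data list of \code{ReflectivityCurve} (same order; dr required).
#' @param nSlices slice count for the forward model (default 50).
#' @param exchange labile-H exchange fraction.
#' @param gammaMax upper bound on the surface excess, mg/m^2.
#' @param zPenMax upper bound on penetration; defaults to the model's
#'   bounding-sphere diameter (the largest possible z extent).
#' @param freeNuisance "none" (default), "background", "scale" or "both":
#'   which per-contrast nuisance parameters to fit.
#' @param backgroundMax,scaleRange bounds for free nuisance parameters.
#' @return a \code{FitProblem}.
#' @export
fitProblem <- function(model, contrasts, data, nSlices = 50, exchange = 1,
                       gammaMax = 10, zPenMax = NULL,
                       freeNuisance = c("none", "background", "scale", "both"),
                       backgroundMax = 1e-4, scaleRange = c(0.5, 2)) {
  freeNuisance <- match.arg(freeNuisance)
  if (is.null(zPenMax)) {
    cc <- sweep(model@coords, 2, colMeans(model@coords))
    zPenMax <- 2 * sqrt(max(rowSums(cc^2)))
  }
  lower <- c(theta = -180, phi = -180, zPen = 0, gamma = 0)
  upper <- c(theta = 180, phi = 180, zPen = zPenMax, gamma = gammaMax)
  k <- length(contrasts)
  if (freeNuisance %in% c("background", "both")) {
    lower <- c(lower, stats::setNames(rep(0, k), paste0("bg", seq_len(k))))
    upper <- c(upper, stats::setNames(rep(backgroundMax, k),
                                      paste0("bg", seq_len(k))))
  }
  if (freeNuisance %in% c("scale", "both")) {
    lower <- c(lower, stats::setNames(rep(scaleRange[1], k),
                                      paste0("scale", seq_len(k))))
    upper <- c(upper, stats::setNames(rep(scaleRange[2], k),
                                      paste0("scale", seq_len(k))))
  }
  new("FitProblem", model = model, contrasts = contrasts, data = data,
      nSlices = nSlices, exchange = exchange, lower = lower, upper = upper,
      freeNuisance = freeNuisance)
}

# Build a fast chi-squared objective closing over precomputed arrays.
# par = (theta, phi, zPen, gamma[, bg_k...][, scale_k...]); returns Inf for
# out-of-bounds or unphysically packed states.
.makeObjective <- function(problem) {
  model <- problem@model
  tab <- residueTable()
  V <- tab$V[match(model@kind, tab$code)]
  sumV <- sum(V)
  coords <- model@coords
  nS <- as.integer(problem@nSlices)
  dProt <- proteinDensity(model@mwt / 1000)
  K <- length(problem@contrasts)
  bMat <- vapply(problem@contrasts, function(ct)
    residueEffectiveB(model@kind, ct@hFraction, problem@exchange),
    numeric(nrow(coords)))
  solv <- vapply(problem@contrasts, function(ct) ct@solventSLD, 0) * 1e-6
  subs <- vapply(problem@contrasts, function(ct) ct@substrateSLD, 0) * 1e-6
  scl0 <- vapply(problem@contrasts, function(ct) ct@scale, 0)
  bg0 <- vapply(problem@contrasts, function(ct) ct@background, 0)
  dqq <- vapply(problem@contrasts, function(ct) ct@dqOverQ, 0)
  qs <- lapply(problem@data, function(d) d@q)
  robs <- lapply(problem@data, function(d) d@r)
  drs <- lapply(problem@data, function(d) {
    if (!length(d@dr)) stop("observed curves need uncertainties (dr)")
    d@dr
  })
  lower <- problem@lower; upper <- problem@upper
  nuis <- problem@freeNuisance
  mode <- "XY"

  function(par) {
    zp <- par[3]; g <- par[4]
    if (zp < lower[3] || zp > upper[3] || g < lower[4] || g > upper[4])
      return(Inf)
    bg <- bg0; scl <- scl0
    if (nuis %in% c("background", "both")) bg <- par[5:(4 + K)]
    if (nuis == "scale") scl <- par[5:(4 + K)]
    if (nuis == "both") scl <- par[(5 + K):(4 + 2 * K)]
    if (any(bg < 0) || any(scl <= 0)) return(Inf)

    rc <- coords %*% t(rotationMatrix(par[1], par[2], mode))
    z <- rc[, 3]
    zmin <- min(z); zmax <- max(z)
    if (zmax - zmin < 1e-9) { zmin <- zmin - 1; zmax <- zmax + 1 }
    zExt <- zmax - zmin
    d <- zExt / nS
    idx <- pmin(floor((z - zmin) / d) + 1L, nS)
    agg <- rowsum(cbind(V, bMat), idx)
    at <- as.integer(rownames(agg))
    vs <- numeric(nS); vs[at] <- agg[, 1]
    occ <- 10 * g / (dProt * zExt) * vs * nS / sumV
    if (any(occ > 1 + 1e-9)) return(Inf)
    occ <- pmin(occ, 1)
    zi <- zmin + zp
    zHigh <- zmin + seq_len(nS) * d
    B <- pmin(1, pmax(0, (zHigh - zi) / d))

    chi2 <- 0
    for (k in seq_len(K)) {
      bs <- numeric(nS); bs[at] <- agg[, 1 + k]
      sldProt <- ifelse(vs > 0, bs / vs, 0)          # absolute A^-2
      bulk <- B * solv[k] + (1 - B) * subs[k]
      sld <- occ * sldProt + (1 - occ) * bulk
      q <- qs[[k]]
      if (dqq[k] > 0) {
        nodes <- seq(-3, 3, length.out = 21)
        w <- exp(-nodes^2 / 2); w <- w / sum(w)
        r <- numeric(length(q))
        for (j in seq_along(nodes))
          r <- r + w[j] * abeles_kernel(pmax(q + nodes[j] * dqq[k] * q, 1e-6),
                                        subs[k], sld, rep(d, nS), solv[k])
      } else {
        r <- abeles_kernel(q, subs[k], sld, rep(d, nS), solv[k])
      }
      chi2 <- chi2 + sum(((scl[k] * r + bg[k] - robs[[k]]) / drs[[k]])^2)
    }
    chi2
  }
}

#' Chi-squared of an adsorption state against a problem's data
#'
#' @param problem a \code{FitProblem}.
#' @param state an \code{AdsorptionState}.
#' @return chi-squared.
#' @export
problemChiSquared <- function(problem, state) {
  obj <- .makeObjective(problem)
  obj(c(state@theta, state@phi, state@zPen, state@gamma))
}

# One rand/1/bin differential-evolution run over the bounded box, angles
# wrapped periodically. Returns the best member, its cost and the
# evaluation count.
.deRun <- function(obj, lower, upper, angleIdx, seed, popSize, maxGen,
                   f, cr) {
  d <- length(lower)
  set.seed(seed)
  pop <- t(replicate(popSize, lower + stats::runif(d) * (upper - lower)))
  cost <- apply(pop, 1, obj)
  nev <- popSize
  if (!any(is.finite(cost)))
    stop("no valid state found at initialization: the whole sampled box is ",
         "unphysically packed; lower gammaMax or check the model")
  rest <- setdiff(seq_len(d), angleIdx)
  for (gen in seq_len(maxGen)) {
    for (i in seq_len(popSize)) {
      r <- sample(seq_len(popSize)[-i], 3)
      v <- pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
      jr <- sample.int(d, 1)
      mask <- stats::runif(d) < cr
      mask[jr] <- TRUE
      trial <- ifelse(mask, v, pop[i, ])
      trial[angleIdx] <- wrapAngle(trial[angleIdx])
      trial[rest] <- pmin(pmax(trial[rest], lower[rest]), upper[rest])
      ct <- obj(trial); nev <- nev + 1
      if (is.finite(ct) && (ct <= cost[i] || !is.finite(cost[i]))) {
        pop[i, ] <- trial; cost[i] <- ct
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], chi2 = cost[best], evaluations = nev)
}

#' Global best-fit search by differential evolution
#'
#' Stochastic global minimization of chi-squared over the bounded parameter
#' box, with the two angles treated periodically (mutant vectors are wrapped,
#' not clipped). Runs \code{nStarts} independent rand/1/bin differential
#' evolution populations and keeps the best. The chi-squared surface is
#' typically multimodal in the orientation angles while the nuisance
#' parameters (penetration, surface excess) are well determined, so the
#' search then rescreens a coarse angle lattice at the refined nuisance
#' values and polishes the best few candidates with Nelder-Mead before a
#' final high-precision polish. The returned orientation is reduced to the
#' canonical representative of the exact forward-model degeneracy (see
#' \code{\link{canonicalAngles}}). Deterministic given the seed.
#'
#' @param problem a \code{FitProblem}.
#' @param seed integer RNG seed.
#' @param popSize population size per start (default 30).
#' @param maxGen number of generations per start (default 250).
#' @param f mutation weight; cr crossover probability.
#' @param polish run the angle-lattice rescreen and Nelder-Mead refinement.
#' @param nStarts independent differential-evolution restarts (default 2).
#' @return list with \code{state} (an \code{AdsorptionState}), \code{par},
#'   \code{chi2} and \code{evaluations}.
#' @export
bestFit <- function(problem, seed = 1, popSize = 30, maxGen = 250, f = 0.8,
                    cr = 0.9, polish = TRUE, nStarts = 2) {
  stopifnot(nStarts >= 1)
  obj <- .makeObjective(problem)
  lower <- problem@lower; upper <- problem@upper
  d <- length(lower)
  angleIdx <- 1:2
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, nStarts)
  runs <- lapply(subSeeds, function(s)
    .deRun(obj, lower, upper, angleIdx, s, popSize, maxGen, f, cr))
  nev <- sum(vapply(runs, `[[`, 0, "evaluations"))
  best <- runs[[which.min(vapply(runs, `[[`, 0, "chi2"))]]
  par <- best$par; chi2 <- best$chi2
  if (polish) {
    fnP <- function(p) {
      p[angleIdx] <- wrapAngle(p[angleIdx])
      v <- obj(p)
      if (!is.finite(v)) 1e30 else v
    }
    # orientation-lattice multistart: for each coarse (theta, phi) pair,
    # screen a short zPen scan at the refined surface excess and keep the
    # best depth, then polish the most promising candidates. The phi range
    # is halved because of the exact (theta, phi) -> (theta + 180, 180 -
    # phi) degeneracy (see canonicalAngles).
    lattice <- as.matrix(expand.grid(theta = seq(-165, 180, by = 15),
                                     phi = seq(-90, 90, by = 15)))
    zGrid <- unique(c(seq(0, min(30, upper[3]), by = 5), par[3]))
    nuisance <- matrix(par[-(1:3)], nrow(lattice), d - 3, byrow = TRUE)
    cand <- matrix(NA_real_, nrow(lattice), d)
    latCost <- rep(Inf, nrow(lattice))
    for (i in seq_len(nrow(lattice))) {
      zc <- vapply(zGrid, function(z)
        obj(c(lattice[i, ], z, nuisance[i, ])), 0)
      nev <- nev + length(zGrid)
      k <- which.min(zc)
      cand[i, ] <- c(lattice[i, ], zGrid[k], nuisance[i, ])
      latCost[i] <- zc[k]
    }
    ord <- order(latCost)
    ord <- ord[is.finite(latCost[ord])]
    starts <- rbind(par, cand[utils::head(ord, 8), , drop = FALSE])
    for (i in seq_len(nrow(starts))) {
      op <- stats::optim(starts[i, ], fnP, method = "Nelder-Mead",
                         control = list(maxit = 300, reltol = 1e-8))
      nev <- nev + op$counts[1]
      if (op$value < chi2) {
        par <- op$par
        chi2 <- op$value
      }
    }
    op <- stats::optim(par, fnP, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    nev <- nev + op$counts[1]
    if (op$value < chi2) {
      par <- op$par
      chi2 <- op$value
    }
    par[angleIdx] <- wrapAngle(par[angleIdx])
  }
  ca <- canonicalAngles(par[1], par[2])
  par[1] <- ca$theta; par[2] <- ca$phi
  names(par) <- names(lower)
  state <- adsorptionState(par[1], par[2], par[3], par[4])
  list(state = state, par = par, chi2 = unname(chi2), evaluations = nev)
}

# Fold a value into [lo, hi] by reflection at the bounds.
.reflect <- function(v, lo, hi) {
  w <- hi - lo
  r <- (v - lo) %% (2 * w)
  lo + pmin(r, 2 * w - r)
}

# One DRAM chain. logPost must be finite at init.
.dramChain <- function(logPost, init, nSteps, nBurn, seed, lower, upper,
                       angleIdx, periodic, cov0, adaptInterval, drScale,
                       repeatId) {
  d <- length(init)
  set.seed(seed)
  fix <- function(y) {
    if (length(angleIdx)) {
      y[angleIdx] <- if (periodic) wrapAngle(y[angleIdx])
                     else .reflect(y[angleIdx], -180, 180)
    }
    rest <- setdiff(seq_len(d), angleIdx)
    if (length(rest))
      y[rest] <- .reflect(y[rest], lower[rest], upper[rest])
    y
  }
  wdiff <- function(a, b) {
    dd <- a - b
    if (length(angleIdx) && periodic) dd[angleIdx] <- wrapAngle(dd[angleIdx])
    dd
  }
  C <- cov0
  U <- chol(C)
  Ci <- chol2inv(U)
  lq <- function(a, b) { dd <- wdiff(a, b); -0.5 * sum((Ci %*% dd) * dd) }

  x <- fix(init)
  lp <- logPost(x)
  if (!is.finite(lp))
    stop("log-posterior is not finite at the initial state; start from a ",
         "bestFit() result")
  samples <- matrix(NA_real_, nSteps, d)
  lps <- numeric(nSteps)
  nacc <- 0L
  sdScale <- 2.38^2 / d
  for (s in seq_len(nSteps)) {
    y1 <- fix(x + drop(stats::rnorm(d) %*% U))
    lp1 <- logPost(y1)
    if (is.finite(lp1) && log(stats::runif(1)) < lp1 - lp) {
      x <- y1; lp <- lp1; nacc <- nacc + 1L
    } else {
      # delayed rejection: one narrower second-stage try
      y2 <- fix(x + drScale * drop(stats::rnorm(d) %*% U))
      lp2 <- logPost(y2)
      if (is.finite(lp2) && lp1 < lp2) {
        a1rev <- min(1, exp(if (is.finite(lp1)) lp1 - lp2 else -Inf))
        a1fwd <- min(1, exp(if (is.finite(lp1)) lp1 - lp else -Inf))
        lnum <- lp2 + lq(y2, y1) + log1p(-a1rev)
        lden <- lp + lq(x, y1) + log1p(-a1fwd)
        if (log(stats::runif(1)) < lnum - lden) {
          x <- y2; lp <- lp2; nacc <- nacc + 1L
        }
      }
    }
    samples[s, ] <- x
    lps[s] <- lp
    if (s %% adaptInterval == 0L && s >= adaptInterval) {
      Ch <- stats::cov(samples[seq_len(s), , drop = FALSE])
      Cn <- sdScale * Ch + diag(1e-10, d)
      Un <- tryCatch(chol(Cn), error = function(e) NULL)
      if (!is.null(Un)) { C <- Cn; U <- Un; Ci <- chol2inv(U) }
    }
  }
  colnames(samples) <- names(lower)
  rate <- nacc / nSteps
  new("MCMCChain", samples = samples, logPost = lps, nBurn = nBurn,
      seed = seed, repeatId = repeatId,
      acceptanceRate = min(max(rate, 1e-12), 1), provenance = list())
}

#' Sample the posterior by delayed-rejection adaptive Metropolis (DRAM)
#'
#' Samples the posterior proportional to exp(-chi2/2) under uniform priors
#' over the problem's bounds. The angle coordinates are periodic: proposals
#' wrap across the +/-180 seam, which greatly improves mixing when a
#' posterior mode abuts the boundary. zPen and gamma proposals are reflected
#' at their bounds. The proposal covariance is adapted at a fixed epoch from
#' the chain history (adaptive Metropolis), and each first-stage rejection
#' triggers one narrower delayed-rejection stage with the proper DR
#' acceptance ratio. Independent repeats differ only by seeds derived
#' deterministically from the master seed.
#'
#' @param problem a \code{FitProblem}, or NULL when \code{logPost} is given.
#' @param nSteps steps per repeat; \code{nBurn} burn-in steps (nSteps >
#'   nBurn). The study-scale defaults in the package configuration are 2e6
#'   steps / 2e5 burn-in for compact antibody fragments; use far fewer for
#'   testing.
#' @param nRepeats number of independent repeats.
#' @param seed master seed; expands deterministically to per-repeat seeds.
#' @param init initial parameter vector (defaults to a \code{bestFit} run).
#' @param cov0 initial proposal covariance (default: diagonal, (range/50)^2).
#' @param adaptInterval adaptation epoch in steps.
#' @param drScale second-stage proposal shrink factor.
#' @param periodic treat angles periodically (TRUE; FALSE reflects them at
#'   +/-180 instead, provided for mixing diagnostics).
#' @param logPost optional log-density function replacing the chi-squared
#'   posterior (for analytic targets); requires \code{lower}, \code{upper}.
#' @param lower,upper,angleIdx parameter box and periodic-coordinate indices
#'   when \code{logPost} is supplied.
#' @return list of \code{MCMCChain}, one per repeat.
#' @export
runMCMC <- function(problem = NULL, nSteps = 50000, nBurn = 5000,
                    nRepeats = 1, seed = 1, init = NULL, cov0 = NULL,
                    adaptInterval = 1000, drScale = 0.2, periodic = TRUE,
                    logPost = NULL, lower = NULL, upper = NULL,
                    angleIdx = NULL) {
  stopifnot(nSteps > nBurn)
  if (is.null(logPost)) {
    stopifnot(is(problem, "FitProblem"))
    obj <- .makeObjective(problem)
    logPost <- function(p) -obj(p) / 2
    lower <- problem@lower; upper <- problem@upper
    if (is.null(angleIdx)) angleIdx <- 1:2
    if (is.null(init)) init <- bestFit(problem, seed = seed)$par
  } else {
    stopifnot(!is.null(lower), !is.null(upper), !is.null(init))
    if (is.null(angleIdx)) angleIdx <- integer()
  }
  if (is.null(names(lower))) names(lower) <- paste0("p", seq_along(lower))
  if (is.null(cov0))
    cov0 <- diag(((upper - lower) / 50)^2, length(lower))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nRepeats)
  lapply(seq_len(nRepeats), function(i)
    .dramChain(logPost, init, nSteps, nBurn, seeds[i], lower, upper,
               angleIdx, periodic, cov0, adaptInterval, drScale, i))
}

#' Concatenate MCMC chains
#'
#' Concatenates the post-burn-in steps of several chains over the same
#' parameter space into one chain (burn-in 0), recording the provenance of
#' each segment. Intended for multimodal posteriors whose modes do not mix,
#' where separate chains are started in each mode and added together.
#'
#' @param chains list of \code{MCMCChain} sharing parameter names.
#' @return a combined \code{MCMCChain}.
#' @export
combineChains <- function(chains) {
  stopifnot(length(chains) >= 1,
            all(vapply(chains, is, TRUE, "MCMCChain")))
  pn <- colnames(chains[[1]]@samples)
  for (ch in chains)
    if (!identical(colnames(ch@samples), pn))
      stop("chains have inconsistent parameter spaces")
  sm <- do.call(rbind, lapply(chains, postBurn))
  lp <- unlist(lapply(chains, function(ch)
    ch@logPost[(ch@nBurn + 1L):length(ch@logPost)]))
  lens <- vapply(chains, function(ch) nrow(postBurn(ch)), 0L)
  new("MCMCChain", samples = sm, logPost = lp, nBurn = 0,
      seed = chains[[1]]@seed, repeatId = NA_real_,
      acceptanceRate = sum(vapply(chains, function(ch)
        ch@acceptanceRate * nrow(ch@samples), 0)) /
        sum(vapply(chains, function(ch) nrow(ch@samples), 0)),
      provenance = list(segments = data.frame(
        repeatId = vapply(chains, function(ch) ch@repeatId, 0),
        seed = vapply(chains, function(ch) ch@seed, 0),
        length = lens)))
}
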