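# Synthetic bead proteins and noisy multi-contrast reflectivity datasets
# with known ground truth, so the whole pipeline is testable end to end.

# Typical amino-acid frequencies (Swiss-Prot-like) for random compositions.
.aaFrequencies <- c(
  ALA = 0.083, ARG = 0.055, ASN = 0.041, ASP = 0.054, CYS = 0.014,
  GLN = 0.039, GLU = 0.067, GLY = 0.071, HIS = 0.023, ILE = 0.059,
  LEU = 0.097, LYS = 0.058, MET = 0.024, PHE = 0.039, PRO = 0.047,
  SER = 0.066, THR = 0.054, TRP = 0.011, TYR = 0.029, VAL = 0.069)

# Is a point inside the shape template? Templates are sized in Angstrom.
.insideShape <- function(shape, p, extents) {
  half <- extents / 2
  switch(shape,
    sphere = ,
    ellipsoid = sum((p / half)^2) <= 1,
    cylinder = (p[2] / half[2])^2 <= 1 &&
      (p[1] / half[1])^2 + (p[3] / half[3])^2 <= 1,
    yshape = {
      # three ellipsoidal lobes: an Fc-like stem and two Fab-like arms
      # tilted +/-45 degrees, an mAb-like Y with approximate 2-fold symmetry
      inLobe <- function(centre, tilt) {
        q <- p - centre
        a <- tilt * pi / 180
        q2 <- c(cos(a) * q[1] - sin(a) * q[2],
                sin(a) * q[1] + cos(a) * q[2], q[3])
        sum((q2 / c(20, 34, 17))^2) <= 1
      }
      inLobe(c(0, -36, 0), 0) || inLobe(c(-34, 30, 0), -45) ||
        inLobe(c(34, 30, 0), 45)
    },
    stop("unknown shape: ", shape))
}

.shapeBox <- function(shape, extents) {
  if (shape == "yshape") cbind(c(-56, -72, -18), c(56, 66, 18))
  else cbind(-extents / 2, extents / 2)
}

#' Generate a synthetic bead protein
#'
#' Beads are placed by rejection sampling inside the requested shape with a
#' minimum separation, assigned residue kinds drawn from a composition
#' distribution (so the Gamma/volume bookkeeping is exercised with realistic
#' residue volumes), and the model is canonicalized. Deterministic given the
#' seed. The "yshape" is an mAb-like body of three ellipsoidal lobes with
#' approximate 2-fold symmetry, broken by the random composition.
#'
#' @param shape "yshape", "ellipsoid", "cylinder" or "sphere".
#' @param nBeads number of residues (>= 10; default 300).
#' @param extents full axis extents (x, y, z) in Angstrom; default 80 x 100
#'   x 60 for the simple shapes. For "yshape" the built-in mAb-like lobe
#'   geometry (span about 112 x 138 x 36 A) is used as-is when extents is
#'   NULL, or rescaled to the requested extents otherwise.
#' @param seed RNG seed.
#' @param minSep minimum bead separation, Angstrom.
#' @param composition named probability vector over residue codes (defaults
#'   to typical protein frequencies).
#' @param name model label.
#' @return a canonicalized \code{ProteinModel}.
#' @export
makeBeadProtein <- function(shape = c("yshape", "ellipsoid", "cylinder",
                                      "sphere"),
                            nBeads = 300, extents = NULL,
                            seed = 1, minSep = 3.5, composition = NULL,
                            name = NULL) {
  shape <- match.arg(shape)
  rescaleY <- shape == "yshape" && !is.null(extents)
  if (is.null(extents)) extents <- c(80, 100, 60)
  stopifnot(nBeads >= 10, all(extents > 0))
  if (is.null(composition)) composition <- .aaFrequencies
  set.seed(seed)
  box <- .shapeBox(shape, extents)
  pts <- matrix(NA_real_, nBeads, 3)
  got <- 0L
  tries <- 0L
  maxTries <- 2000L * nBeads
  minSep2 <- minSep^2
  while (got < nBeads) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("infeasible bead density: placed ", got, " of ", nBeads,
           " beads at separation ", minSep)
    p <- stats::runif(3, box[, 1], box[, 2])
    if (!.insideShape(shape, p, extents)) next
    if (got > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)
      if (min(d2) < minSep2) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  if (rescaleY) {
    tpl <- .shapeBox("yshape", extents)
    pts <- sweep(pts, 2, extents / (tpl[, 2] - tpl[, 1]), `*`)
  }
  kinds <- sample(names(composition), nBeads, replace = TRUE,
                  prob = composition)
  model <- proteinModel(pts, kinds,
                        name = if (is.null(name)) paste0("synthetic-", shape)
                               else name)
  canonicalizeOrientation(model)
}

# Geometric q grid mirroring typical air/water measurement ranges.
.defaultQGrid <- function(qMin = 0.0063, qMax = 0.32, n = 101)
  exp(seq(log(qMin), log(qMax), length.out = n))

#' Default synthetic contrast set
#'
#' Three air-substrate contrasts: null-reflecting water, solvent matched to
#' the protein (falling back to CM4.5 when no model is given), and D2O. Oil
#' variants swap the substrate SLD to 5.65e-6 A^-2 (hexadecane matched to
#' sapphire).
#'
#' @param model optional \code{ProteinModel} used to compute the
#'   contrast-match solvent.
#' @param substrate "air" or "oil".
#' @param q momentum-transfer grid (default geometric over 0.0063-0.32).
#' @return list of three \code{ContrastDefinition}.
#' @export
syntheticContrasts <- function(model = NULL, substrate = c("air", "oil"),
                               q = .defaultQGrid()) {
  substrate <- match.arg(substrate)
  subSLD <- if (substrate == "air") 0 else 5.65
  cm <- if (is.null(model)) solventSpec("CM4.5")
        else solventSpec("CMProtein", sld = matchPoint(model)$sld)
  list(contrastDefinition("NRW", solventSpec("NRW"), subSLD, q),
       contrastDefinition("CMProtein", cm, subSLD, q),
       contrastDefinition("D2O", solventSpec("D2O"), subSLD, q))
}

#' Simulate a noisy multi-contrast experiment from a known truth
#'
#' For each contrast the noiseless forward curve is computed and perturbed
#' multiplicatively, r -> r * (1 + sigmaRel * eps) with eps ~ N(0, 1); the
#' reported uncertainty is dr = sqrt((sigmaRel * r)^2 + floor^2), where the
#' additive floor mimics the counting-statistics background limit at high q.
#' sigmaRel = 0 returns the noiseless curve exactly. Deterministic per seed.
#'
#' @param model a canonicalized \code{ProteinModel}.
#' @param state the ground-truth \code{AdsorptionState}.
#' @param contrasts list of \code{ContrastDefinition} with q grids.
#' @param sigmaRel relative noise level (default 0.01).
#' @param floor additive reflectivity floor for dr (default 1e-7).
#' @param seed RNG seed.
#' @param nSlices slice count for the forward model.
#' @param dir optional output directory: writes one 4-column data file per
#'   contrast plus a YAML manifest recording the truth.
#' @return list with \code{curves} (list of \code{ReflectivityCurve}),
#'   \code{truth}, \code{contrasts} and \code{manifest}.
#' @export
simulateExperiment <- function(model, state, contrasts, sigmaRel = 0.01,
                               floor = 1e-7, seed = 1, nSlices = 50,
                               dir = NULL) {
  stopifnot(sigmaRel >= 0)
  set.seed(seed)
  curves <- vector("list", length(contrasts))
  for (i in seq_along(contrasts)) {
    ct <- contrasts[[i]]
    r0 <- simulateContrast(model, state, ct, nSlices)@r
    rn <- pmax(r0 * (1 + sigmaRel * stats::rnorm(length(r0))), 0)
    dr <- sqrt((sigmaRel * r0)^2 + floor^2)
    curves[[i]] <- reflectivityCurve(ct@q, rn, dr, contrastName = ct@name)
  }
  manifest <- list(
    truth = list(theta = state@theta, phi = state@phi, zPen = state@zPen,
                 gamma = state@gamma, mode = state@mode),
    noise = list(sigmaRel = sigmaRel, floor = floor),
    seed = seed, nSlices = nSlices,
    contrasts = lapply(contrasts, function(ct)
      list(name = ct@name, solventSLD = ct@solventSLD,
           hFraction = ct@hFraction, substrateSLD = ct@substrateSLD,
           qMin = min(ct@q), qMax = max(ct@q), nQ = length(ct@q))))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(curves))
      writeReflectivityFile(curves[[i]], file.path(
        dir, paste0(contrasts[[i]]@name, ".dat")))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  list(curves = curves, truth = state, contrasts = contrasts,
       manifest = manifest)
}

# SLD profile of a state evaluated on a fixed z grid (piecewise constant,
# bounding media outside the box).
.profileOnGrid <- function(model, state, contrast, zGrid, nSlices = 50) {
  pr <- assembleProfile(model, state, contrast, nSlices)
  s <- sliceTable(pr)
  breaks <- c(s$zLow, s$zHigh[nrow(s)])
  sf <- stats::stepfun(breaks, c(pr@sldSubstrate, s$sld, pr@sldSolvent))
  sf(zGrid)
}

#' Parameter-recovery score of a fitted state against the truth
#'
#' Angular errors are geodesic on the torus (at most 180 degrees);
#' penetration and surface excess are absolute errors. The profile-space RMS
#' SLD difference is evaluated on a common z grid across all contrasts and
#' scored as the minimum over the fitted state and its 180-degree symmetric
#' image (theta + 180, phi + 180), which produces the z-reversed, physically
#' near-equivalent layer.
#'
#' @param fitted,truth \code{AdsorptionState}s over the same space.
#' @param model the \code{ProteinModel} both states refer to.
#' @param contrasts list of \code{ContrastDefinition}.
#' @param nSlices slice count; \code{nZ} grid points for the profile RMS.
#' @return list with angular/absolute errors, \code{profileRMS} (1e-6 A^-2)
#'   and \code{profileRMSFraction} (RMS over the truth profile's dynamic
#'   range).
#' @export
recoveryScore <- function(fitted, truth, model, contrasts, nSlices = 50,
                          nZ = 201) {
  geo <- function(a, b) abs(wrapAngle(a - b))
  # common z grid covering both states' boxes
  span <- function(st) {
    z <- rotateModel(model, st@theta, st@phi, st@mode)@coords[, 3]
    range(z)
  }
  r1 <- span(fitted); r2 <- span(truth)
  zGrid <- seq(min(r1[1], r2[1]) - 5, max(r1[2], r2[2]) + 5,
               length.out = nZ)
  rmsFor <- function(st) {
    tot <- 0
    for (ct in contrasts) {
      a <- .profileOnGrid(model, st, ct, zGrid, nSlices)
      b <- .profileOnGrid(model, truth, ct, zGrid, nSlices)
      tot <- tot + mean((a - b)^2)
    }
    sqrt(tot / length(contrasts))
  }
  flipped <- adsorptionState(fitted@theta + 180, fitted@phi + 180,
                             fitted@zPen, fitted@gamma, fitted@mode)
  rms <- min(rmsFor(fitted), rmsFor(flipped))
  dyn <- range(unlist(lapply(contrasts, function(ct)
    .profileOnGrid(model, truth, ct, zGrid, nSlices))))
  list(thetaError = geo(fitted@theta, truth@theta),
       phiError = geo(fitted@phi, truth@phi),
       zPenError = abs(fitted@zPen - truth@zPen),
       gammaError = abs(fitted@gamma - truth@gamma),
       profileRMS = rms,
       profileRMSFraction = rms / diff(dyn))
}
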