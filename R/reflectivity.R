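# Specular reflectivity from a slab profile, contrast definitions, data I/O
# and goodness of fit.

# Named solvent presets: target SLD in 1e-6 A^-2 (NULL = pure endpoint).
.solventPresets <- list(
  H2O = list(sld = NULL, d2o = 0),
  D2O = list(sld = NULL, d2o = 1),
  NRW = list(sld = 0, d2o = NA),
  CM4.5 = list(sld = 4.5, d2o = NA),
  CMSapphire = list(sld = 5.65, d2o = NA))

#' Solvent specification
#'
#' Builds a solvent from a preset name ("H2O", "D2O", "NRW", "CM4.5",
#' "CMSapphire") or from a target SLD; the D2O fraction is solved from the
#' linear H2O/D2O mix so the composition and SLD are always consistent.
#'
#' @param name preset name, or a label when \code{sld} is given.
#' @param sld target SLD in 1e-6 A^-2 (overrides the preset lookup).
#' @return list with \code{name}, \code{sld} and \code{hFraction} (the H2O
#'   volume fraction).
#' @export
solventSpec <- function(name, sld = NULL) {
  if (is.null(sld)) {
    p <- .solventPresets[[name]]
    if (is.null(p)) stop("unknown solvent preset: ", name)
    f <- if (is.na(p$d2o)) d2oFractionForSLD(p$sld) else p$d2o
  } else {
    f <- d2oFractionForSLD(sld)
  }
  list(name = name, sld = unname(waterSLD(f)), hFraction = unname(1 - f))
}

#' Define an isotopic contrast
#'
#' @param name contrast label.
#' @param solvent a \code{solventSpec()} result or preset name.
#' @param substrateSLD SLD of the non-aqueous phase, 1e-6 A^-2 (0 for air,
#'   5.65 for hexadecane matched to sapphire).
#' @param q measurement grid (A^-1), strictly increasing.
#' @param dqOverQ fractional resolution width (1 sigma; 0 disables smearing).
#' @param background additive reflectivity background.
#' @param scale multiplicative scale.
#' @return a \code{ContrastDefinition}.
#' @export
contrastDefinition <- function(name, solvent, substrateSLD = 0, q = numeric(),
                               dqOverQ = 0, background = 0, scale = 1) {
  if (is.character(solvent)) solvent <- solventSpec(solvent)
  new("ContrastDefinition", name = name, solventName = solvent$name,
      solventSLD = solvent$sld, hFraction = solvent$hFraction,
      substrateSLD = substrateSLD, q = q, dqOverQ = dqOverQ,
      background = background, scale = scale)
}

#' Construct a reflectivity curve
#'
#' @param q momentum transfer grid (A^-1).
#' @param r reflectivity values.
#' @param dr optional 1-sigma uncertainties.
#' @param dq optional resolution widths.
#' @param contrastName label.
#' @return a \code{ReflectivityCurve}.
#' @export
reflectivityCurve <- function(q, r, dr = numeric(), dq = numeric(),
                              contrastName = "") {
  new("ReflectivityCurve", q = as.numeric(q), r = as.numeric(r),
      dr = as.numeric(dr), dq = as.numeric(dq), contrastName = contrastName)
}

#' Reflectivity of a slab profile by the optical matrix method
#'
#' Parratt/Abeles recursion over the profile's slices, with the substrate as
#' the (semi-infinite) incident medium below and the solvent as the backing
#' above. Optional Gaussian q-resolution smearing with per-point width dq
#' (1 sigma).
#'
#' @param profile a \code{SlabProfile}.
#' @param q momentum transfer grid (A^-1), strictly increasing, > 0.
#' @param dq optional per-point resolution width (1 sigma, A^-1).
#' @return reflectivity values in [0, 1].
#' @export
reflectivityFromProfile <- function(profile, q, dq = NULL) {
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("q grid must be positive and strictly increasing")
  s <- sliceTable(profile)
  calc <- function(qv) abeles_kernel(qv, profile@sldSubstrate * 1e-6,
                                     s$sld * 1e-6, s$d, profile@sldSolvent * 1e-6)
  if (is.null(dq) || !length(dq) || all(dq == 0)) return(calc(q))
  dq <- rep_len(dq, length(q))
  nodes <- seq(-3, 3, length.out = 21)
  w <- exp(-nodes^2 / 2); w <- w / sum(w)
  r <- numeric(length(q))
  for (j in seq_along(nodes))
    r <- r + w[j] * calc(pmax(q + nodes[j] * dq, 1e-6))
  r
}

#' Simulate the reflectivity of an adsorption state under one contrast
#'
#' Assembles the SLD profile for the state and contrast, runs the optical
#' matrix method on the contrast's q grid, and applies the contrast's scale
#' and background.
#'
#' @param model a canonicalized \code{ProteinModel}.
#' @param state an \code{AdsorptionState}.
#' @param contrast a \code{ContrastDefinition} with a non-empty q grid.
#' @param nSlices slice count.
#' @param exchange labile-H exchange fraction.
#' @return a \code{ReflectivityCurve} (noiseless; dr empty).
#' @export
simulateContrast <- function(model, state, contrast, nSlices = 50,
                             exchange = 1) {
  if (!length(contrast@q)) stop("contrast has no q grid")
  profile <- assembleProfile(model, state, contrast, nSlices, exchange)
  dq <- if (contrast@dqOverQ > 0) contrast@dqOverQ * contrast@q else NULL
  r <- contrast@scale * reflectivityFromProfile(profile, contrast@q, dq) +
    contrast@background
  reflectivityCurve(contrast@q, r, contrastName = contrast@name)
}

#' Chi-squared between simulated and observed curves
#'
#' Sum over contrasts and points of ((r_model - r_obs) / dr)^2; additive
#' over contrasts. Grids must match unless \code{interpolate = TRUE}, in
#' which case the model curve is linearly interpolated onto the data grid.
#'
#' @param simulated a \code{ReflectivityCurve} or list of them.
#' @param observed matching \code{ReflectivityCurve}(s) with dr > 0.
#' @param interpolate allow linear interpolation onto the observed grid.
#' @param logSpace compute residuals on log10(r) instead of r.
#' @return chi-squared (dimensionless).
#' @export
chiSquared <- function(simulated, observed, interpolate = FALSE,
                       logSpace = FALSE) {
  if (is(simulated, "ReflectivityCurve")) simulated <- list(simulated)
  if (is(observed, "ReflectivityCurve")) observed <- list(observed)
  stopifnot(length(simulated) == length(observed))
  tot <- 0
  for (i in seq_along(simulated)) {
    sim <- simulated[[i]]; obs <- observed[[i]]
    if (!length(obs@dr)) stop("observed curve has no uncertainties")
    rs <- if (!isTRUE(all.equal(sim@q, obs@q))) {
      if (!interpolate) stop("mismatched q grids (set interpolate = TRUE)")
      stats::approx(sim@q, sim@r, xout = obs@q, rule = 2)$y
    } else sim@r
    if (logSpace) {
      keep <- rs > 0 & obs@r > 0
      res <- (log10(rs[keep]) - log10(obs@r[keep])) /
        (obs@dr[keep] / (obs@r[keep] * log(10)))
    } else {
      res <- (rs - obs@r) / obs@dr
    }
    tot <- tot + sum(res^2)
  }
  tot
}

#' Read a columnar reflectivity data file
#'
#' Whitespace-delimited (q, r, dr[, dq]) columns; lines starting with '#'
#' (including ORSO .ort header blocks) are skipped.
#'
#' @param path data file.
#' @param contrastName label for the curve.
#' @return a \code{ReflectivityCurve}.
#' @export
readReflectivityFile <- function(path, contrastName = basename(path)) {
  dat <- utils::read.table(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 3L) stop("expected at least 3 columns (q, r, dr)")
  reflectivityCurve(dat[[1]], pmax(dat[[2]], 0), dat[[3]],
                    if (ncol(dat) >= 4L) dat[[4]] else numeric(),
                    contrastName = contrastName)
}

#' Write a reflectivity curve as columnar text
#'
#' Four columns (q, r, dr, dq); missing dr/dq are written as 0.
#'
#' @param curve a \code{ReflectivityCurve}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeReflectivityFile <- function(curve, path) {
  n <- length(curve@q)
  dat <- data.frame(q = curve@q, r = curve@r,
                    dr = if (length(curve@dr)) curve@dr else rep(0, n),
                    dq = if (length(curve@dq)) curve@dq else rep(0, n))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s", curve@contrastName), con)
  writeLines("# q(1/A) R dR dQ", con)
  utils::write.table(format(dat, digits = 10, trim = TRUE, scientific = TRUE),
                     con, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
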