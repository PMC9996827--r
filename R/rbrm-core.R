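# Rigid-body rotation, slicing, and assembly of the hydrated SLD profile.
#
# Coordinate convention: +z points from the substrate (air or oil) into the
# aqueous solvent. The interface plane sits at z = min_z(protein) + z_pen,
# so a penetration depth of 0 leaves the whole protein in the solvent.

.deg2rad <- pi / 180

#' Construct an adsorption state
#'
#' @param theta rotation about x, degrees (wrapped into [-180, 180)).
#' @param phi rotation about y, degrees (wrapped).
#' @param zPen penetration depth, Angstrom, >= 0.
#' @param gamma surface excess, mg/m^2, >= 0.
#' @param mode rotation order, "XY" (default) or "ZY".
#' @param background,scale per-contrast nuisance parameters.
#' @return an \code{AdsorptionState}.
#' @export
adsorptionState <- function(theta, phi, zPen, gamma, mode = "XY",
                            background = 0, scale = 1) {
  new("AdsorptionState", theta = wrapAngle(theta), phi = wrapAngle(phi),
      mode = mode, zPen = zPen, gamma = gamma,
      background = background, scale = scale)
}

#' Rigid rotation matrix for a two-angle orientation
#'
#' Active, right-handed rotations. In the "XY" system the body is rotated by
#' theta about the x axis and then by phi about the y axis, so the composite
#' matrix is \code{Ry(phi) \%*\% Rx(theta)}. The alternative "ZY" system
#' rotates first about z, then about y.
#'
#' @param theta,phi angles in degrees.
#' @param mode "XY" (default) or "ZY".
#' @return orthonormal 3 x 3 matrix with determinant +1.
#' @export
rotationMatrix <- function(theta, phi, mode = c("XY", "ZY")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(theta), is.finite(phi))
  t <- theta * .deg2rad; p <- phi * .deg2rad
  ry <- matrix(c(cos(p), 0, sin(p), 0, 1, 0, -sin(p), 0, cos(p)), 3, 3,
               byrow = TRUE)
  first <- if (mode == "XY") {
    matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
           byrow = TRUE)
  } else {
    matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  ry %*% first
}

#' Rotate a protein model
#'
#' @param model a \code{ProteinModel}.
#' @param theta,phi angles in degrees.
#' @param mode rotation order.
#' @return the rotated \code{ProteinModel}.
#' @export
rotateModel <- function(model, theta, phi, mode = "XY") {
  out <- model
  out@coords <- model@coords %*% t(rotationMatrix(theta, phi, mode))
  out
}

# z-bounds of the slicing box, padded when the extent degenerates.
.zBox <- function(z) {
  zmin <- min(z); zmax <- max(z)
  if (zmax - zmin < 1e-9) { zmin <- zmin - 1; zmax <- zmax + 1 }
  c(zmin, zmax)
}

#' Slice a (rotated) protein into per-slice volume and SLD
#'
#' The box spanning the protein's z extent is divided into \code{nSlices}
#' slices of equal thickness; each residue is binned wholly into the slice
#' containing its bead position (half-open intervals, top slice closed).
#' Per slice, the protein volume is the sum of residue volumes and the
#' protein SLD is the summed effective scattering length over that volume
#' (0 for empty slices). Total protein volume is conserved exactly.
#'
#' @param model a rotated \code{ProteinModel}.
#' @param nSlices number of slices (default 50).
#' @param hFraction solvent H2O volume fraction.
#' @param exchange labile-H exchange fraction.
#' @return data.frame with columns zLow, zHigh, vProt, sldProt; the box
#'   bounds are attached as attribute \code{"zRange"}.
#' @export
sliceProtein <- function(model, nSlices = 50, hFraction, exchange = 1) {
  stopifnot(is(model, "ProteinModel"), nSlices >= 2)
  tab <- residueTable()
  V <- tab$V[match(model@kind, tab$code)]
  b <- residueEffectiveB(model@kind, hFraction, exchange)
  z <- model@coords[, 3]
  zr <- .zBox(z)
  d <- (zr[2] - zr[1]) / nSlices
  idx <- pmin(floor((z - zr[1]) / d) + 1L, nSlices)
  agg <- rowsum(cbind(V, b), idx)
  vs <- bs <- numeric(nSlices)
  at <- as.integer(rownames(agg))
  vs[at] <- agg[, 1]; bs[at] <- agg[, 2]
  sld <- ifelse(vs > 0, bs / vs * 1e6, 0)
  out <- data.frame(zLow = zr[1] + (seq_len(nSlices) - 1) * d,
                    zHigh = zr[1] + seq_len(nSlices) * d,
                    vProt = vs, sldProt = sld)
  attr(out, "zRange") <- zr
  out
}

#' Bulk SLD of a slice relative to the interface plane
#'
#' Slices entirely above the interface (solvent side) take the solvent SLD;
#' slices entirely below take the substrate SLD; the straddling slice mixes
#' the two by the solvent-side fraction B of its z extent.
#'
#' @param zLow,zHigh slice bounds (vectors allowed), zHigh > zLow.
#' @param zInterface interface plane position, Angstrom.
#' @param sldSolvent,sldSubstrate bounding SLDs, 1e-6 A^-2.
#' @return bulk SLD per slice, 1e-6 A^-2.
#' @export
bulkSLD <- function(zLow, zHigh, zInterface, sldSolvent, sldSubstrate) {
  if (any(zHigh <= zLow)) stop("inverted slice bounds")
  B <- pmin(1, pmax(0, (zHigh - zInterface) / (zHigh - zLow)))
  B * sldSolvent + (1 - B) * sldSubstrate
}

#' Total protein volume fraction from the surface excess
#'
#' Converts Gamma (mg/m^2) into the volume fraction of protein in a layer of
#' the given extent: \code{rho_total = 10 * Gamma / (D_prot * extent)} with
#' Gamma in mg/m^2, density in g/cm^3 and extent in Angstrom (the factor 10
#' collects the unit conversions). Linear in Gamma.
#'
#' @param gamma surface excess, mg/m^2.
#' @param dProt protein mass density, g/cm^3, > 0.
#' @param layerExtent z extent of the layer box, Angstrom, > 0.
#' @return dimensionless volume fraction.
#' @export
rhoTotalFromGamma <- function(gamma, dProt, layerExtent) {
  if (dProt <= 0 || layerExtent <= 0)
    stop("density and layer extent must be positive")
  if (gamma < 0) stop("gamma must be >= 0")
  10 * gamma / (dProt * layerExtent)
}

#' Assemble the hydrated SLD profile for one contrast
#'
#' Rotates the model by the state's orientation, slices it, and fills each
#' slice with protein and bulk: the per-slice protein occupancy is
#' \code{rho_norm * rho_slice}, where \code{rho_slice} is the protein volume
#' fraction of the slice within the box and \code{rho_norm = rho_total /
#' rho_box} renormalizes the arbitrary box to the Gamma-implied layer volume
#' fraction. rho_norm above 1 is allowed (proteins packed more densely than
#' one per box) but per-slice occupancy above 1 is an error. The per-slice
#' SLD mixes the protein and bulk values by occupancy; bulk is substrate
#' below the interface plane and solvent above it.
#'
#' @param model a canonicalized \code{ProteinModel}.
#' @param state an \code{AdsorptionState}.
#' @param contrast a \code{ContrastDefinition}.
#' @param nSlices slice count (default 50).
#' @param exchange labile-H exchange fraction.
#' @return a \code{SlabProfile}.
#' @export
assembleProfile <- function(model, state, contrast, nSlices = 50,
                            exchange = 1) {
  stopifnot(is(model, "ProteinModel"), is(state, "AdsorptionState"),
            is(contrast, "ContrastDefinition"))
  rot <- rotateModel(model, state@theta, state@phi, state@mode)
  sl <- sliceProtein(rot, nSlices, contrast@hFraction, exchange)
  zr <- attr(sl, "zRange")
  d <- sl$zHigh[1] - sl$zLow[1]
  zExtent <- zr[2] - zr[1]

  ext <- apply(rot@coords[, 1:2, drop = FALSE], 2,
               function(v) diff(range(v)))
  aBox <- (ext[1] + 4) * (ext[2] + 4)  # 2 A pad per side
  vBox <- aBox * zExtent

  rhoSlice <- sl$vProt / (aBox * d)
  rhoBox <- sum(sl$vProt) / vBox
  dProt <- proteinDensity(model@mwt / 1000)
  rhoTotal <- rhoTotalFromGamma(state@gamma, dProt, zExtent)
  rhoNorm <- rhoTotal / rhoBox
  occ <- rhoNorm * rhoSlice
  if (any(occ > 1 + 1e-9)) {
    bad <- which.max(occ)
    stop(sprintf(
      "unphysical packing in slice %d (occupancy %.3f): Gamma too high for this orientation",
      bad, occ[bad]))
  }
  occ <- pmin(occ, 1)

  zInterface <- zr[1] + state@zPen
  bulk <- bulkSLD(sl$zLow, sl$zHigh, zInterface,
                  contrast@solventSLD, contrast@substrateSLD)
  sld <- occ * sl$sldProt + (1 - occ) * bulk

  new("SlabProfile",
      slices = data.frame(zLow = sl$zLow, zHigh = sl$zHigh, d = d,
                          vProt = sl$vProt, sldProt = sl$sldProt,
                          rhoSlice = rhoSlice, occupancy = occ,
                          bulk = bulk, sld = sld),
      sldSolvent = contrast@solventSLD, sldSubstrate = contrast@substrateSLD,
      rhoBox = rhoBox, rhoNorm = rhoNorm, rhoTotal = rhoTotal,
      aBox = unname(aBox), zInterface = zInterface)
}

#' Fraction of residues past the interface
#'
#' The penetrated fraction P_f estimates how much of the protein sits on the
#' substrate side of the interface plane, counted as the proportion of
#' residue beads with z below \code{min_z + zPen}. A bead exactly on the
#' plane counts as solvent-side; when zPen reaches or exceeds the protein's
#' z extent the whole protein has passed (P_f = 1).
#'
#' @param model a \code{ProteinModel} (already rotated, or supply angles).
#' @param zPen penetration depth, Angstrom, >= 0.
#' @param theta,phi optional orientation applied before counting.
#' @param mode rotation order.
#' @return P_f in [0, 1].
#' @export
penetratedFraction <- function(model, zPen, theta = 0, phi = 0, mode = "XY") {
  stopifnot(zPen >= 0)
  if (theta != 0 || phi != 0) model <- rotateModel(model, theta, phi, mode)
  z <- model@coords[, 3]
  ext <- max(z) - min(z)
  if (zPen >= ext) return(1)
  mean(z < min(z) + zPen)
}

#' Export a slab profile as columnar text
#'
#' Writes (z mid-plane, total SLD, protein volume fraction) per slice for
#' plotting; tab-separated with a comment header.
#'
#' @param profile a \code{SlabProfile}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeProfile <- function(profile, path) {
  s <- sliceTable(profile)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# z(A)\tSLD(1e-6 A^-2)\tprotein_volume_fraction",
               sprintf("# substrate SLD %.4f, solvent SLD %.4f",
                       profile@sldSubstrate, profile@sldSolvent)), con)
  utils::write.table(
    data.frame(z = (s$zLow + s$zHigh) / 2, sld = s$sld, phi = s$occupancy),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
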