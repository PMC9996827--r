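# Generics, accessors and show methods.

#' Bead coordinates of a protein model
#' @param x a \code{ProteinModel}.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))

#' @rdname beadCoords
setMethod("beadCoords", "ProteinModel", function(x) x@coords)

#' Residue kinds of a protein model
#' @param x a \code{ProteinModel}.
#' @return character vector of 3-letter codes.
#' @export
setGeneric("residueKinds", function(x) standardGeneric("residueKinds"))

#' @rdname residueKinds
setMethod("residueKinds", "ProteinModel", function(x) x@kind)

#' Number of beads (residues)
#' @param x a \code{ProteinModel}.
#' @return integer count.
#' @export
setGeneric("beadCount", function(x) standardGeneric("beadCount"))

#' @rdname beadCount
setMethod("beadCount", "ProteinModel", function(x) nrow(x@coords))

#' Molecular weight (Da)
#' @param x a \code{ProteinModel}.
#' @return numeric, Da.
#' @export
setGeneric("molecularWeight", function(x) standardGeneric("molecularWeight"))

#' @rdname molecularWeight
setMethod("molecularWeight", "ProteinModel", function(x) x@mwt)

#' Summed residue volume (A^3)
#' @param x a \code{ProteinModel}.
#' @return numeric, A^3.
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))

#' @rdname totalVolume
setMethod("totalVolume", "ProteinModel", function(x) {
  tab <- residueTable()
  sum(tab$V[match(x@kind, tab$code)])
})

#' Slice table of a SlabProfile
#' @param x a \code{SlabProfile}.
#' @return data.frame of per-slice quantities.
#' @export
setGeneric("sliceTable", function(x) standardGeneric("sliceTable"))

#' @rdname sliceTable
setMethod("sliceTable", "SlabProfile", function(x) x@slices)

#' Post-burn-in samples of an MCMC chain
#' @param x an \code{MCMCChain}.
#' @return step x parameter matrix with the burn-in removed.
#' @export
setGeneric("postBurn", function(x) standardGeneric("postBurn"))

#' @rdname postBurn
setMethod("postBurn", "MCMCChain", function(x) {
  x@samples[(x@nBurn + 1L):nrow(x@samples), , drop = FALSE]
})

#' Acceptance rate of an MCMC chain
#' @param x an \code{MCMCChain}.
#' @return numeric in (0, 1).
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))

#' @rdname acceptanceRate
setMethod("acceptanceRate", "MCMCChain", function(x) x@acceptanceRate)

setMethod("show", "ProteinModel", function(object) {
  cat("ProteinModel '", object@name, "': ", nrow(object@coords),
      " residue beads, ", length(unique(object@chain)), " chain(s), MW ",
      format(object@mwt, big.mark = ","), " Da\n", sep = "")
  ext <- apply(object@coords, 2, function(v) diff(range(v)))
  cat(sprintf("  extents (x, y, z): %.1f x %.1f x %.1f A\n",
              ext[1], ext[2], ext[3]))
})

setMethod("show", "AdsorptionState", function(object) {
  cat(sprintf(
    "AdsorptionState (%s): theta = %.2f deg, phi = %.2f deg, z_pen = %.2f A, Gamma = %.3f mg/m^2\n",
    object@mode, object@theta, object@phi, object@zPen, object@gamma))
})

setMethod("show", "SlabProfile", function(object) {
  s <- object@slices
  cat(sprintf(
    "SlabProfile: %d slices of %.2f A; substrate SLD %.2f | solvent SLD %.2f (1e-6 A^-2)\n",
    nrow(s), s$d[1], object@sldSubstrate, object@sldSolvent))
  cat(sprintf("  rho_box = %.4f, rho_total = %.4f, rho_norm = %.4f\n",
              object@rhoBox, object@rhoTotal, object@rhoNorm))
})

setMethod("show", "ReflectivityCurve", function(object) {
  cat(sprintf("ReflectivityCurve '%s': %d points, q in [%.4g, %.4g] A^-1%s\n",
              object@contrastName, length(object@q), min(object@q),
              max(object@q),
              if (length(object@dr)) " (with uncertainties)" else ""))
})

setMethod("show", "MCMCChain", function(object) {
  cat(sprintf(
    "MCMCChain: %d steps (%d burn-in), %d parameters, acceptance %.3f\n",
    nrow(object@samples), as.integer(object@nBurn), ncol(object@samples),
    object@acceptanceRate))
})

setMethod("show", "OrientationDensity", function(object) {
  cat(sprintf(
    "OrientationDensity: %d x %d grid (%.2f deg cells), bandwidths %.2f/%.2f deg\n",
    length(object@theta), length(object@phi), sqrt(object@cellArea),
    object@bandwidth[1], object@bandwidth[2]))
})

setMethod("show", "HPDRegionSet", function(object) {
  cat("HPDRegionSet:\n")
  for (i in seq_along(object@levels))
    cat(sprintf("  %.0f%%: area %.0f deg^2 (mass %.4f)\n",
                100 * object@levels[i], object@areas[i],
                object@enclosedMass[i]))
})

setMethod("show", "FootprintResult", function(object) {
  cat(sprintf(
    "FootprintResult: APM convex %.0f A^2, concave %.0f A^2, from Gamma %.0f A^2 (coverage %.2f)\n",
    object@apmConvex, object@apmConcave, object@apmGamma, object@coverage))
})
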