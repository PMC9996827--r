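# Central S4 containers. Coordinates are in Angstrom throughout; SLD values
# are quoted in units of 1e-6 A^-2 (the convention of the reflectometry
# literature); scattering lengths are in Angstrom; Gamma in mg/m^2.

#' Residue-level bead model of a protein
#'
#' One bead per amino-acid residue, positioned at the residue's heavy-atom
#' centroid (or C-alpha, depending on how it was built). Bead kinds index the
#' residue scattering-parameter table shipped with the package.
#'
#' @slot coords n x 3 numeric matrix of bead positions (Angstrom).
#' @slot kind character vector of 3-letter residue codes.
#' @slot chain character vector of chain identifiers.
#' @slot resno integer vector of residue ordinals.
#' @slot name label for the model.
#' @slot mwt molecular weight in Da; consistent with the summed residue
#'   masses to within 5 percent (water-loss bookkeeping tolerance).
#' @exportClass ProteinModel
setClass("ProteinModel",
  slots = c(coords = "matrix", kind = "character", chain = "character",
            resno = "integer", name = "character", mwt = "numeric"),
  validity = function(object) {
    n <- nrow(object@coords)
    if (n < 1L) return("model must contain at least one bead")
    if (ncol(object@coords) != 3L) return("coords must be n x 3")
    if (!all(is.finite(object@coords))) return("non-finite coordinates")
    if (length(object@kind) != n) return("kind length != bead count")
    if (length(object@chain) != n) return("chain length != bead count")
    tab <- residueTable()
    bad <- setdiff(unique(object@kind), tab$code)
    if (length(bad))
      return(paste("unknown residue kind(s):", paste(bad, collapse = ", ")))
    if (length(object@mwt) != 1L || !is.finite(object@mwt) || object@mwt <= 0)
      return("mwt must be a single positive number")
    msum <- sum(tab$mass[match(object@kind, tab$code)]) +
      18.02 * length(unique(object@chain))
    if (abs(object@mwt - msum) > 0.05 * msum)
      return("mwt inconsistent with summed residue masses (> 5%)")
    TRUE
  })

#' Rigid-body adsorption state
#'
#' The fitted object: two Euler angles (degrees, wrapped to [-180, 180)),
#' the penetration depth of the protein past the solvent/substrate interface,
#' the surface excess Gamma, and per-contrast nuisance scale/background.
#'
#' @slot theta rotation about x, degrees in [-180, 180).
#' @slot phi rotation about y, degrees in [-180, 180).
#' @slot mode rotation order, "XY" (theta about x then phi about y) or "ZY".
#' @slot zPen penetration depth, Angstrom, >= 0.
#' @slot gamma surface excess, mg/m^2, >= 0.
#' @slot background per-contrast additive reflectivity background.
#' @slot scale per-contrast multiplicative scale.
#' @exportClass AdsorptionState
setClass("AdsorptionState",
  slots = c(theta = "numeric", phi = "numeric", mode = "character",
            zPen = "numeric", gamma = "numeric",
            background = "numeric", scale = "numeric"),
  validity = function(object) {
    if (object@theta < -180 || object@theta >= 180) return("theta outside [-180, 180)")
    if (object@phi < -180 || object@phi >= 180) return("phi outside [-180, 180)")
    if (!object@mode %in% c("XY", "ZY")) return("mode must be 'XY' or 'ZY'")
    if (object@zPen < 0) return("zPen must be >= 0")
    if (object@gamma < 0) return("gamma must be >= 0")
    if (any(object@scale <= 0)) return("scale must be > 0")
    if (any(object@background < 0)) return("background must be >= 0")
    TRUE
  })

#' Sliced SLD profile of an adsorbed protein layer
#'
#' Ordered equal-thickness slices along z (substrate below, solvent above),
#' with per-slice protein volume, protein SLD, occupancy and total SLD, plus
#' the bounding semi-infinite media. Slices are ordered by increasing z.
#'
#' @slot slices data.frame with columns zLow, zHigh, d, vProt, sldProt,
#'   rhoSlice, occupancy, bulk, sld.
#' @slot sldSolvent,sldSubstrate bounding-media SLDs (1e-6 A^-2).
#' @slot rhoBox,rhoNorm,rhoTotal layer volume-fraction bookkeeping.
#' @slot aBox box cross-sectional area (A^2); zInterface interface plane (A).
#' @exportClass SlabProfile
setClass("SlabProfile",
  slots = c(slices = "data.frame", sldSolvent = "numeric",
            sldSubstrate = "numeric", rhoBox = "numeric", rhoNorm = "numeric",
            rhoTotal = "numeric", aBox = "numeric", zInterface = "numeric"),
  validity = function(object) {
    s <- object@slices
    need <- c("zLow", "zHigh", "d", "vProt", "sldProt", "rhoSlice",
              "occupancy", "bulk", "sld")
    if (!all(need %in% names(s))) return("slices missing columns")
    if (nrow(s) < 2L) return("need at least 2 slices")
    if (any(diff(s$zLow) <= 0)) return("slices not ordered by z")
    if (max(abs(s$d - s$d[1])) > 1e-9 * s$d[1]) return("unequal slice thickness")
    if (any(s$rhoSlice < -1e-12 | s$rhoSlice > 1 + 1e-12))
      return("rhoSlice outside [0, 1]")
    if (any(s$occupancy < -1e-12 | s$occupancy > 1 + 1e-9))
      return("occupancy outside [0, 1]")
    TRUE
  })

#' A specular reflectivity curve for one isotopic contrast
#'
#' @slot q momentum transfer, A^-1, strictly increasing and positive.
#' @slot r reflectivity (dimensionless, >= 0).
#' @slot dr 1-sigma uncertainty (empty for noiseless simulated curves).
#' @slot dq optional resolution width (1 sigma), empty if absent.
#' @slot contrastName label.
#' @exportClass ReflectivityCurve
setClass("ReflectivityCurve",
  slots = c(q = "numeric", r = "numeric", dr = "numeric", dq = "numeric",
            contrastName = "character"),
  validity = function(object) {
    if (length(object@q) < 1L) return("empty q grid")
    if (any(object@q <= 0)) return("q must be positive")
    if (any(diff(object@q) <= 0)) return("q must be strictly increasing")
    if (length(object@r) != length(object@q)) return("r length != q length")
    if (any(object@r < 0)) return("r must be >= 0")
    if (length(object@dr) && (length(object@dr) != length(object@q) ||
        any(object@dr <= 0))) return("dr must be positive where present")
    if (length(object@dq) && length(object@dq) != length(object@q))
      return("dq length != q length")
    TRUE
  })

#' Definition of one isotopic contrast
#'
#' @slot name label (e.g. "NRW", "D2O").
#' @slot solventName,solventSLD,hFraction the aqueous phase: SLD (1e-6 A^-2)
#'   and H2O volume fraction.
#' @slot substrateSLD SLD of the non-aqueous phase (air = 0; oil matched to
#'   sapphire = 5.65).
#' @slot q measurement grid (A^-1); dqOverQ fractional resolution width.
#' @slot background additive reflectivity background; scale multiplier.
#' @exportClass ContrastDefinition
setClass("ContrastDefinition",
  slots = c(name = "character", solventName = "character",
            solventSLD = "numeric", hFraction = "numeric",
            substrateSLD = "numeric", q = "numeric", dqOverQ = "numeric",
            background = "numeric", scale = "numeric"),
  validity = function(object) {
    if (object@hFraction < 0 || object@hFraction > 1)
      return("hFraction outside [0, 1]")
    if (object@scale <= 0) return("scale must be > 0")
    if (object@background < 0) return("background must be >= 0")
    if (length(object@q) && (any(object@q <= 0) || any(diff(object@q) <= 0)))
      return("q must be positive and strictly increasing")
    TRUE
  })

#' Fitting problem: model + datasets + bounds
#'
#' @slot model ProteinModel (canonicalized).
#' @slot contrasts list of ContrastDefinition.
#' @slot data list of ReflectivityCurve (same order as contrasts).
#' @slot nSlices slice count for the SLD profile.
#' @slot exchange global labile-H exchange fraction.
#' @slot lower,upper named parameter bounds (theta, phi, zPen, gamma, ...).
#' @slot freeNuisance "none", "background", "scale" or "both".
#' @exportClass FitProblem
setClass("FitProblem",
  slots = c(model = "ProteinModel", contrasts = "list", data = "list",
            nSlices = "numeric", exchange = "numeric",
            lower = "numeric", upper = "numeric", freeNuisance = "character"),
  validity = function(object) {
    if (length(object@contrasts) < 1L) return("need at least one dataset")
    if (length(object@contrasts) != length(object@data))
      return("contrasts and data lengths differ")
    if (!all(vapply(object@contrasts, is, TRUE, "ContrastDefinition")))
      return("contrasts must be ContrastDefinition objects")
    if (!all(vapply(object@data, is, TRUE, "ReflectivityCurve")))
      return("data must be ReflectivityCurve objects")
    if (length(object@lower) != length(object@upper))
      return("bounds lengths differ")
    if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
      return("bounds must be finite")
    if (any(object@upper <= object@lower)) return("upper <= lower bound")
    TRUE
  })

#' An MCMC chain over the adsorption-state space
#'
#' @slot samples step x parameter matrix (accepted-state record; angles are
#'   stored wrapped to [-180, 180)).
#' @slot logPost log-posterior at each step.
#' @slot nBurn burn-in step count.
#' @slot seed RNG seed used for this chain.
#' @slot repeatId which independent repeat this is (NA for combined chains).
#' @slot acceptanceRate fraction of proposals accepted, in (0, 1).
#' @slot provenance list of metadata (segment record for combined chains).
#' @exportClass MCMCChain
setClass("MCMCChain",
  slots = c(samples = "matrix", logPost = "numeric", nBurn = "numeric",
            seed = "numeric", repeatId = "numeric",
            acceptanceRate = "numeric", provenance = "list"),
  validity = function(object) {
    if (nrow(object@samples) < 1L) return("empty chain")
    if (length(object@logPost) != nrow(object@samples))
      return("logPost length != step count")
    if (object@nBurn < 0 || object@nBurn >= nrow(object@samples))
      return("post-burn-in length must be positive")
    if (object@acceptanceRate <= 0 || object@acceptanceRate > 1)
      return("acceptance rate must lie in (0, 1]")
    if (is.null(colnames(object@samples))) return("samples need column names")
    TRUE
  })

#' Orientation probability density on the (theta, phi) torus
#'
#' @slot theta,phi grid-cell centres, degrees over [-180, 180).
#' @slot density matrix (theta rows x phi columns), integrates to 1.
#' @slot cellArea grid-cell area, deg^2.
#' @slot bandwidth smoothing bandwidths used (degrees, per dimension).
#' @exportClass OrientationDensity
setClass("OrientationDensity",
  slots = c(theta = "numeric", phi = "numeric", density = "matrix",
            cellArea = "numeric", bandwidth = "numeric"),
  validity = function(object) {
    if (nrow(object@density) != length(object@theta) ||
        ncol(object@density) != length(object@phi))
      return("density dimensions do not match grids")
    if (any(object@density < -1e-12)) return("negative density")
    mass <- sum(object@density) * object@cellArea
    if (abs(mass - 1) > 1e-6) return("density does not integrate to 1")
    TRUE
  })

#' Nested highest-posterior-density regions on the orientation torus
#'
#' @slot levels probability levels (ascending).
#' @slot masks list of logical matrices (one per level, nested).
#' @slot areas enclosed area per level, deg^2.
#' @slot enclosedMass probability mass actually enclosed per level.
#' @exportClass HPDRegionSet
setClass("HPDRegionSet",
  slots = c(levels = "numeric", masks = "list", areas = "numeric",
            enclosedMass = "numeric"),
  validity = function(object) {
    k <- length(object@levels)
    if (length(object@masks) != k || length(object@areas) != k)
      return("levels/masks/areas lengths differ")
    if (is.unsorted(object@levels)) return("levels must be ascending")
    if (k > 1L) for (i in 2:k)
      if (any(object@masks[[i - 1L]] & !object@masks[[i]]))
        return("regions not nested across levels")
    TRUE
  })

#' Molecular footprint summary for one orientation
#'
#' @slot apmConvex convex-hull area per molecule, A^2.
#' @slot apmConcave concave (alpha-shape) area per molecule, A^2.
#' @slot apmGamma area per molecule implied by the surface excess, A^2.
#' @slot coverage apmConvex / apmGamma (dimensionless).
#' @exportClass FootprintResult
setClass("FootprintResult",
  slots = c(apmConvex = "numeric", apmConcave = "numeric",
            apmGamma = "numeric", coverage = "numeric"),
  validity = function(object) {
    if (object@apmConcave > object@apmConvex * (1 + 1e-9))
      return("concave footprint exceeds convex footprint")
    if (any(c(object@apmConvex, object@apmConcave, object@apmGamma,
              object@coverage) <= 0)) return("areas must be positive")
    TRUE
  })
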