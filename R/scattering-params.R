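# Residue and solvent neutron scattering parameters.
#
# Scattering lengths are carried in Angstrom (1 fm = 1e-5 A); SLDs are
# quoted in 1e-6 A^-2; volumes in A^3.

# Element coherent scattering lengths, Angstrom.
.elementB <- c(H = -3.739e-5, D = 6.671e-5, C = 6.6460e-5, N = 9.36e-5,
               O = 5.803e-5, S = 2.804e-5)

.AVOGADRO <- 6.02214076e23

# Pure-water molecular masses (Da) and mass densities at 20 C (g/cm^3);
# the densities reproduce the standard quoted pure-water SLD endpoints.
.waterConst <- list(mH2O = 18.0153, mD2O = 20.0276,
                    rhoH2O = 0.998, rhoD2O = 1.105)

#' Physical constants used by the package
#'
#' Element coherent neutron scattering lengths (Angstrom), Avogadro's
#' constant, and the pure-water masses/densities behind the solvent SLD
#' endpoints.
#'
#' @return named list with elements \code{b} (named numeric, Angstrom),
#'   \code{NA_const} (mol^-1) and \code{water}.
#' @examples
#' physicalConstants()$b[["H"]]  # negative; deuterium is positive
#' @export
physicalConstants <- function() {
  list(b = .elementB, NA_const = .AVOGADRO, water = .waterConst)
}

#' Residue scattering-parameter table
#'
#' Loads (and caches) the residue table shipped with the package: for each
#' of the 20 standard amino-acid residues, the summed coherent scattering
#' length with all labile hydrogens protiated (\code{b_h}) and fully
#' exchanged to deuterium (\code{b_d}), both in Angstrom; the consensus
#' residue volume \code{V} (A^3); the count of exchangeable hydrogens
#' \code{n_labile}; and the average residue mass (Da). The table is generated
#' from atomic compositions and element scattering lengths; its header
#' documents the provenance and the labile-H convention.
#'
#' @return data.frame with columns code, nC, nH, nN, nO, nS, n_labile, V,
#'   mass, b_h, b_d.
#' @export
residueTable <- function() {
  if (is.null(.rbrnr_env$residueTable)) {
    path <- system.file("extdata", "residue_params.tsv", package = "rbrnr")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(tab$V > 0), all(tab$b_d >= tab$b_h), all(tab$n_labile >= 0))
    .rbrnr_env$residueTable <- tab
  }
  .rbrnr_env$residueTable
}

#' Effective residue scattering length in a mixed solvent
#'
#' Labile hydrogens equilibrate with the solvent, so the residue scattering
#' length interpolates linearly between the fully protiated value (in pure
#' H2O) and the fully exchanged value (in pure D2O):
#' \code{b = H * b_h + (1 - H) * b_d}, where \code{H} is the H2O volume
#' fraction of the aqueous phase. An optional global exchange fraction
#' scales how much of the labile population actually exchanges.
#'
#' @param kind character vector of 3-letter residue codes.
#' @param hFraction H2O volume fraction of the solvent, in [0, 1].
#' @param exchange fraction of labile hydrogens that exchange (default 1,
#'   i.e. full exchange).
#' @return numeric vector of scattering lengths, Angstrom.
#' @export
residueEffectiveB <- function(kind, hFraction, exchange = 1) {
  if (!is.numeric(hFraction) || length(hFraction) != 1L ||
      !is.finite(hFraction) || hFraction < 0 || hFraction > 1)
    stop("hFraction must be a single value in [0, 1]")
  if (exchange < 0 || exchange > 1) stop("exchange must be in [0, 1]")
  tab <- residueTable()
  i <- match(kind, tab$code)
  if (anyNA(i)) stop("unknown residue kind(s): ",
                     paste(unique(kind[is.na(i)]), collapse = ", "))
  bd <- tab$b_h[i] + exchange * (tab$b_d[i] - tab$b_h[i])
  hFraction * tab$b_h[i] + (1 - hFraction) * bd
}

# Pure-water SLD endpoints in 1e-6 A^-2, from molecular scattering lengths
# and mass densities.
.waterEndpoints <- function() {
  b <- .elementB; w <- .waterConst
  vH2O <- w$mH2O / (w$rhoH2O * .AVOGADRO) * 1e24  # A^3 per molecule
  vD2O <- w$mD2O / (w$rhoD2O * .AVOGADRO) * 1e24
  c(h2o = (2 * b[["H"]] + b[["O"]]) / vH2O * 1e6,
    d2o = (2 * b[["D"]] + b[["O"]]) / vD2O * 1e6)
}

#' SLD of an H2O/D2O mixture
#'
#' Linear volume-fraction mix of the pure-water endpoint SLDs (computed from
#' molecular scattering lengths and the 20 C mass densities; approximately
#' -0.56 and 6.35 in 1e-6 A^-2).
#'
#' @param d2oVolumeFraction D2O volume fraction, in [0, 1].
#' @return SLD in 1e-6 A^-2.
#' @examples
#' waterSLD(1)   # pure D2O, ~6.35
#' waterSLD(0)   # pure H2O, ~-0.56
#' @export
waterSLD <- function(d2oVolumeFraction) {
  if (any(!is.finite(d2oVolumeFraction)) ||
      any(d2oVolumeFraction < 0 | d2oVolumeFraction > 1))
    stop("d2oVolumeFraction must lie in [0, 1]")
  ep <- .waterEndpoints()
  (1 - d2oVolumeFraction) * ep[["h2o"]] + d2oVolumeFraction * ep[["d2o"]]
}

#' D2O fraction giving a target water SLD
#'
#' Inverts the linear H2O/D2O mix; e.g. the null-reflecting-water (NRW)
#' composition solves \code{waterSLD(f) = 0} at f of about 0.081.
#'
#' @param sld target SLD, 1e-6 A^-2, within the pure-water range.
#' @return D2O volume fraction in [0, 1].
#' @export
d2oFractionForSLD <- function(sld) {
  ep <- .waterEndpoints()
  f <- (sld - ep[["h2o"]]) / (ep[["d2o"]] - ep[["h2o"]])
  if (any(f < -1e-9 | f > 1 + 1e-9))
    stop("target SLD outside the pure-water range [",
         round(ep[["h2o"]], 2), ", ", round(ep[["d2o"]], 2), "]")
  pmin(1, pmax(0, f))
}

#' Molecular-weight-dependent protein mass density
#'
#' Empirical exponential-decay form: density decreases with molecular weight
#' towards an asymptote of 1.410 g/cm^3,
#' \code{D(M) = 1.410 + 0.145 * exp(-M / 13)} with M in kDa
#' (Fischer, Polikarpov and Craievich, Protein Sci. 2004).
#'
#' @param mwKDa molecular weight in kDa, > 0.
#' @return mass density, g/cm^3.
#' @export
proteinDensity <- function(mwKDa) {
  if (any(!is.finite(mwKDa)) || any(mwKDa <= 0))
    stop("molecular weight must be positive")
  1.410 + 0.145 * exp(-mwKDa / 13)
}

#' Mean SLD of a protein model
#'
#' Sum of effective residue scattering lengths over the summed residue
#' volumes, for a given solvent H2O fraction.
#'
#' @param model a \code{ProteinModel}.
#' @param hFraction H2O volume fraction of the solvent, in [0, 1].
#' @param exchange labile-H exchange fraction (default 1).
#' @return mean SLD in 1e-6 A^-2.
#' @export
proteinMeanSLD <- function(model, hFraction, exchange = 1) {
  stopifnot(is(model, "ProteinModel"))
  if (beadCount(model) < 1L) stop("empty model")
  b <- residueEffectiveB(residueKinds(model), hFraction, exchange)
  sum(b) / totalVolume(model) * 1e6
}

#' Contrast match point of a protein
#'
#' Solves for the D2O fraction at which the solvent SLD equals the protein's
#' mean SLD (the labile-H exchange makes the protein SLD itself depend on the
#' solvent composition, so the match point is the fixed point of the pair).
#'
#' @param model a \code{ProteinModel}.
#' @param exchange labile-H exchange fraction (default 1).
#' @return list with \code{d2oFraction} and \code{sld} (1e-6 A^-2).
#' @export
matchPoint <- function(model, exchange = 1) {
  g <- function(f) waterSLD(f) - proteinMeanSLD(model, 1 - f, exchange)
  if (g(0) > 0 || g(1) < 0)
    stop("protein mean SLD outside the pure-water range; no match point")
  f <- stats::uniroot(g, c(0, 1), tol = 1e-10)$root
  list(d2oFraction = f, sld = waterSLD(f))
}
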