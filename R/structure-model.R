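# Structure input/output and the canonical initial orientation.

# Common nonstandard-residue aliases used when policy = "nearest".
.residueAliases <- c(MSE = "MET", SEC = "CYS", HSD = "HIS", HSE = "HIS",
                     HSP = "HIS", HID = "HIS", HIE = "HIS", HIP = "HIS",
                     CYX = "CYS", ASH = "ASP", GLH = "GLU", LYN = "LYS",
                     ARN = "ARG")

#' Construct a protein bead model
#'
#' @param coords n x 3 matrix of bead positions (Angstrom).
#' @param kind character vector of 3-letter residue codes.
#' @param chain chain labels (recycled if length 1).
#' @param resno residue ordinals (default sequential).
#' @param name model label.
#' @param mwt molecular weight in Da; defaults to the summed residue masses
#'   plus one water per chain.
#' @return a \code{ProteinModel}.
#' @export
proteinModel <- function(coords, kind, chain = "A", resno = NULL,
                         name = "protein", mwt = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  chain <- rep_len(as.character(chain), n)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(mwt)) {
    tab <- residueTable()
    mwt <- sum(tab$mass[match(kind, tab$code)]) +
      18.02 * length(unique(chain))
  }
  new("ProteinModel", coords = coords, kind = as.character(kind),
      chain = chain, resno = as.integer(resno), name = name, mwt = mwt)
}

#' Read a PDB structure into a residue bead model
#'
#' Each amino-acid residue becomes one bead at its heavy-atom centroid
#' (or C-alpha). Hydrogens are ignored, only the first altloc is used, only
#' model 1 of multi-model files is read, and HETATM records are skipped.
#'
#' @param path PDB file.
#' @param policy what to do with residue codes absent from the parameter
#'   table: \code{"error"} (default; silent substitution would corrupt the
#'   SLD) or \code{"nearest"} (map common variants such as MSE to their
#'   standard parent, error for anything else).
#' @param representative \code{"centroid"} (heavy-atom centroid, default) or
#'   \code{"CA"}.
#' @param name model label (defaults to the file name).
#' @return a \code{ProteinModel}.
#' @export
readStructure <- function(path, policy = c("error", "nearest"),
                          representative = c("centroid", "CA"),
                          name = NULL) {
  policy <- match.arg(policy)
  representative <- match.arg(representative)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elesy <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                 substr(trimws(at$elety), 1, 1), at$elesy)))
  at <- at[elesy != "H" & elesy != "D", , drop = FALSE]
  if (representative == "CA")
    at <- at[trimws(at$elety) == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop("no amino-acid residues found in ", path)

  kinds <- toupper(trimws(at$resid))
  tab <- residueTable()
  unknown <- setdiff(unique(kinds), tab$code)
  if (length(unknown)) {
    if (policy == "nearest") {
      mapped <- .residueAliases[unknown]
      if (anyNA(mapped))
        stop("unknown residue code(s) with no standard parent: ",
             paste(unknown[is.na(mapped)], collapse = ", "))
      kinds[kinds %in% unknown] <- .residueAliases[kinds[kinds %in% unknown]]
    } else {
      stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
           " (set policy = 'nearest' to map common variants)")
    }
  }

  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  key <- factor(key, levels = unique(key))   # preserve file order
  xyz <- cbind(
    tapply(at$x, key, mean), tapply(at$y, key, mean), tapply(at$z, key, mean))
  first <- !duplicated(key)
  proteinModel(coords = unname(xyz), kind = kinds[first],
               chain = at$chain[first], resno = at$resno[first],
               name = if (is.null(name)) basename(path) else name)
}

#' Write a bead model as a pseudo-atom PDB file
#'
#' One CA pseudo-atom per bead; \code{readStructure} on the output recovers
#' the bead positions to the PDB coordinate precision (1e-3 A).
#'
#' @param model a \code{ProteinModel}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStructure <- function(model, path) {
  stopifnot(is(model, "ProteinModel"))
  n <- beadCount(model)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model@coords)),
                   type = rep("ATOM", n), resno = model@resno,
                   resid = model@kind, chain = model@chain,
                   elety = rep("CA", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Canonicalize the orientation of a bead model
#'
#' Defines the (theta = 0, phi = 0) reference: the bead cloud is centred at
#' the origin and its principal axes (eigenvectors of the coordinate
#' covariance, sorted by decreasing extent) are aligned with major -> y,
#' semi-major -> x, minor -> z. Axis signs are fixed deterministically: the
#' bead with the largest |y| gets y > 0, then the bead with the largest |x|
#' gets x > 0; the z axis completes a right-handed frame, so the transform is
#' a proper rigid rotation (pairwise distances are preserved).
#'
#' @param model a \code{ProteinModel} with at least 3 non-collinear beads.
#' @param tol relative tolerance for the collinearity check.
#' @return the canonicalized \code{ProteinModel}.
#' @export
canonicalizeOrientation <- function(model, tol = 1e-9) {
  stopifnot(is(model, "ProteinModel"))
  cc <- sweep(model@coords, 2, colMeans(model@coords))
  if (nrow(cc) < 3L) stop("need at least 3 beads")
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] <= tol * max(ev$values[1], 1))
    stop("degenerate (collinear) bead cloud")
  v1 <- ev$vectors[, 1]  # major -> y
  v2 <- ev$vectors[, 2]  # semi-major -> x
  y <- drop(cc %*% v1)
  if (y[which.max(abs(y))] < 0) v1 <- -v1
  x <- drop(cc %*% v2)
  if (x[which.max(abs(x))] < 0) v2 <- -v2
  v3 <- c(v2[2] * v1[3] - v2[3] * v1[2],   # x-axis cross y-axis -> z-axis
          v2[3] * v1[1] - v2[1] * v1[3],
          v2[1] * v1[2] - v2[2] * v1[1])
  rot <- rbind(v2, v1, v3)                 # rows = new x, y, z axes
  out <- model
  out@coords <- cc %*% t(rot)
  dimnames(out@coords) <- NULL
  out
}
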