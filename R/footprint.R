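# Molecular footprint: convex and concave (alpha-shape) area per molecule
# of the xy-projected residues, and the APM implied by the surface excess.

.polyArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1]))) / 2
}

.projectXY <- function(model, theta = 0, phi = 0, mode = "XY") {
  if (is.matrix(model)) return(model[, 1:2, drop = FALSE])
  stopifnot(is(model, "ProteinModel"))
  if (theta != 0 || phi != 0) model <- rotateModel(model, theta, phi, mode)
  model@coords[, 1:2, drop = FALSE]
}

.checkNonCollinear <- function(xy) {
  cc <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(crossprod(cc), symmetric = TRUE, only.values = TRUE)$values
  if (nrow(xy) < 3 || ev[2] <= 1e-9 * max(ev[1], 1))
    stop("projected beads are collinear; footprint area undefined")
}

#' Convex footprint area of an oriented protein
#'
#' Area of the 2D convex hull of the xy-projected residue beads: the
#' smallest convex polygon around all residues in the interface plane.
#'
#' @param model a \code{ProteinModel} (or an n x 2 matrix of projected
#'   points).
#' @param theta,phi optional orientation applied before projecting.
#' @param mode rotation order.
#' @return hull area, A^2.
#' @export
convexFootprint <- function(model, theta = 0, phi = 0, mode = "XY") {
  xy <- .projectXY(model, theta, phi, mode)
  .checkNonCollinear(xy)
  h <- grDevices::chull(xy)
  .polyArea(xy[h, , drop = FALSE])
}

# Bowyer-Watson Delaunay triangulation with a deterministic sub-Angstrom
# jitter to break cocircular degeneracies (lattice-like inputs). Returns the
# triangle vertex indices, circumradii and areas.
.delaunay <- function(pts) {
  n <- nrow(pts)
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  jx <- (((seq_len(n) * 2654435761) %% 97) / 97 - 0.5) * span * 1e-9
  jy <- (((seq_len(n) * 40503) %% 89) / 89 - 0.5) * span * 1e-9
  P <- pts + cbind(jx, jy)
  cx <- mean(range(P[, 1])); cy <- mean(range(P[, 2]))
  R <- span * 20
  P <- rbind(P, c(cx - 2 * R, cy - R), c(cx + 2 * R, cy - R),
             c(cx, cy + 2 * R))
  circ <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c <- P[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    a2 <- a[1]^2 + a[2]^2; b2 <- b[1]^2 + b[2]^2; c2 <- c[1]^2 + c[2]^2
    ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
    c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
  }
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  ccs <- matrix(circ(tris[1, ]), 1, 3)
  for (i in seq_len(n)) {
    px <- P[i, 1]; py <- P[i, 2]
    bad <- (px - ccs[, 1])^2 + (py - ccs[, 2])^2 <= ccs[, 3]
    badTris <- tris[bad, , drop = FALSE]
    edges <- rbind(badTris[, c(1, 2)], badTris[, c(2, 3)],
                   badTris[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    boundary <- edges[keep, , drop = FALSE]
    newTris <- cbind(boundary, i)
    tris <- rbind(tris[!bad, , drop = FALSE], newTris)
    newCC <- t(apply(newTris, 1, circ))
    ccs <- rbind(ccs[!bad, , drop = FALSE], newCC)
  }
  real <- apply(tris, 1, function(t) all(t <= n))
  tris <- tris[real, , drop = FALSE]
  ccs <- ccs[real, , drop = FALSE]
  areas <- apply(tris, 1, function(t) .polyArea(P[t, , drop = FALSE]))
  list(triangles = tris, circumradius = sqrt(ccs[, 3]), area = areas)
}

# Connected components of a triangle set under shared edges (union-find).
.triComponents <- function(tris) {
  nt <- nrow(tris)
  parent <- seq_len(nt)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- rbind(cbind(tris[, 1], tris[, 2], seq_len(nt)),
                 cbind(tris[, 2], tris[, 3], seq_len(nt)),
                 cbind(tris[, 3], tris[, 1], seq_len(nt)))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  for (grp in split(edges[, 3], key)) {
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (g in grp[-1]) parent[find(g)] <- r
    }
  }
  length(unique(vapply(seq_len(nt), find, 0L)))
}

#' Concave (alpha-shape) footprint area of an oriented protein
#'
#' Area enclosed by the alpha-shape of the xy-projected beads: the union of
#' Delaunay triangles whose circumradius is at most alpha. Converges to the
#' convex-hull area as alpha grows; never exceeds it. The default alpha is
#' 1.5 times the critical probe radius: the smallest circumradius threshold
#' at which the alpha shape is a single connected component containing
#' every projected bead. This adapts to the bead spacing and cannot
#' fragment, while staying close to the tightest concave outline.
#'
#' @param model a \code{ProteinModel} (or an n x 2 matrix).
#' @param alpha probe radius, Angstrom (> 0); NULL for the default.
#' @param theta,phi optional orientation applied before projecting.
#' @param mode rotation order.
#' @return enclosed area, A^2.
#' @export
concaveFootprint <- function(model, alpha = NULL, theta = 0, phi = 0,
                             mode = "XY") {
  xy <- .projectXY(model, theta, phi, mode)
  .checkNonCollinear(xy)
  dt <- .delaunay(xy)
  if (is.null(alpha)) {
    # critical alpha: smallest circumradius threshold whose triangle set is
    # one component covering all beads (the full Delaunay always is)
    connected <- function(r) {
      keep <- dt$circumradius <= r
      if (!any(keep)) return(FALSE)
      tri <- dt$triangles[keep, , drop = FALSE]
      length(unique(as.vector(tri))) == nrow(xy) &&
        .triComponents(tri) == 1L
    }
    rs <- sort(unique(dt$circumradius))
    lo <- 1L; hi <- length(rs)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (connected(rs[mid])) hi <- mid else lo <- mid + 1L
    }
    alpha <- 1.5 * rs[lo]
  }
  if (alpha <= 0) stop("alpha must be positive")
  keep <- dt$circumradius <= alpha
  if (!any(keep))
    stop("alpha too small: the shape fragments into ", nrow(xy),
         " isolated points")
  nComp <- .triComponents(dt$triangles[keep, , drop = FALSE])
  if (nComp > 1)
    stop("alpha too small: the shape fragments into ", nComp, " components")
  sum(dt$area[keep])
}

#' Area per molecule implied by the surface excess
#'
#' APM = MWT / (N_A * Gamma), converted to A^2 per molecule: the interfacial
#' area each adsorbed molecule occupies if the layer is a uniform monolayer
#' at surface excess Gamma. Inversely proportional to Gamma.
#'
#' @param mwt molecular weight, Da.
#' @param gamma surface excess, mg/m^2, > 0.
#' @return area per molecule, A^2.
#' @export
apmFromGamma <- function(mwt, gamma) {
  if (mwt <= 0) stop("molecular weight must be positive")
  if (gamma <= 0) stop("gamma must be positive (APM diverges at zero)")
  mwt / (.AVOGADRO * gamma * 1e-3) * 1e20
}

#' Footprint summary for one adsorption state
#'
#' @param model a canonicalized \code{ProteinModel}.
#' @param theta,phi orientation, degrees.
#' @param gamma surface excess, mg/m^2.
#' @param alpha alpha-shape probe radius (NULL for the default).
#' @param mode rotation order.
#' @return a \code{FootprintResult} (coverage = apmConvex / apmGamma).
#' @export
footprintSummary <- function(model, theta, phi, gamma, alpha = NULL,
                             mode = "XY") {
  conv <- convexFootprint(model, theta, phi, mode)
  conc <- concaveFootprint(model, alpha, theta, phi, mode)
  apg <- apmFromGamma(molecularWeight(model), gamma)
  new("FootprintResult", apmConvex = conv, apmConcave = min(conc, conv),
      apmGamma = apg, coverage = conv / apg)
}

#' Footprint sweep over an orientation grid
#'
#' @param model a canonicalized \code{ProteinModel}.
#' @param thetaSeq,phiSeq angle grids, degrees.
#' @param concave also compute the alpha-shape area (slower).
#' @param alpha probe radius for the concave boundary.
#' @param mode rotation order.
#' @return data.frame with theta, phi, apmConvex (and apmConcave).
#' @export
footprintSweep <- function(model, thetaSeq, phiSeq, concave = FALSE,
                           alpha = NULL, mode = "XY") {
  grid <- expand.grid(theta = thetaSeq, phi = phiSeq)
  grid$apmConvex <- mapply(function(t, p)
    convexFootprint(model, t, p, mode), grid$theta, grid$phi)
  if (concave)
    grid$apmConcave <- mapply(function(t, p)
      concaveFootprint(model, alpha, t, p, mode), grid$theta, grid$phi)
  grid
}
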