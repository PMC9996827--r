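# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# Small cheap model for unit tests.
smallModel <- function() fixture("smallModel", function()
  makeBeadProtein("ellipsoid", nBeads = 80, seed = 42))

# The Y-shaped 300-bead model used by the end-to-end recovery tests.
yModel <- function() fixture("yModel", function()
  makeBeadProtein("yshape", nBeads = 300, seed = 7))

# Regular lattice of identical residues (analytically tractable slicing).
glyLattice <- function(nx = 4, ny = 5, nz = 3, a = 5) {
  g <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny),
                             z = seq_len(nz))) * a
  proteinModel(g, rep("GLY", nrow(g)))
}

# Ground truth and noisy synthetic experiment shared by the acceptance
# recovery and contrast-variation tests.
recoveryTruth <- function() adsorptionState(30, 45, 10, 2.0)

recoveryExperiment <- function() fixture("recoveryExperiment", function() {
  model <- yModel()
  contrasts <- syntheticContrasts(model)
  sim <- simulateExperiment(model, recoveryTruth(), contrasts,
                            sigmaRel = 0.01, seed = 11)
  list(model = model, contrasts = contrasts, sim = sim,
       problem = fitProblem(model, contrasts, sim$curves))
})

recoveryFit <- function() fixture("recoveryFit", function()
  bestFit(recoveryExperiment()$problem, seed = 1))

# Independent Fresnel closed form for a single sharp interface, incident
# medium SLD rhoIn, backing rhoOut (both in 1e-6 A^-2).
fresnelOracle <- function(q, rhoIn, rhoOut) {
  k0 <- as.complex(q / 2)
  k1 <- sqrt(k0^2 - 4 * pi * (rhoOut - rhoIn) * 1e-6 + 0i)
  pmin(Mod((k0 - k1) / (k0 + k1))^2, 1)
}

# Independent two-interface (single uniform film) closed form.
airyOracle <- function(q, rhoIn, rhoFilm, rhoOut, thickness) {
  k0 <- as.complex(q / 2)
  k1 <- sqrt(k0^2 - 4 * pi * (rhoFilm - rhoIn) * 1e-6 + 0i)
  k2 <- sqrt(k0^2 - 4 * pi * (rhoOut - rhoIn) * 1e-6 + 0i)
  r01 <- (k0 - k1) / (k0 + k1)
  r12 <- (k1 - k2) / (k1 + k2)
  ph <- exp(2i * k1 * thickness)
  pmin(Mod((r01 + r12 * ph) / (1 + r01 * r12 * ph))^2, 1)
}

# A bare-interface SlabProfile: every slice filled with solvent.
bareInterfaceProfile <- function(sldSubstrate, sldSolvent, nSlices = 10,
                                 d = 2) {
  zLow <- (seq_len(nSlices) - 1) * d
  new("SlabProfile",
      slices = data.frame(zLow = zLow, zHigh = zLow + d, d = d,
                          vProt = 0, sldProt = 0, rhoSlice = 0,
                          occupancy = 0, bulk = sldSolvent,
                          sld = sldSolvent),
      sldSolvent = sldSolvent, sldSubstrate = sldSubstrate,
      rhoBox = 1e-3, rhoNorm = 0, rhoTotal = 0, aBox = 1,
      zInterface = 0)
}

# A uniform-film SlabProfile of the given SLD and total thickness.
filmProfile <- function(sldSubstrate, sldFilm, sldSolvent, thickness,
                        nSlices = 40) {
  d <- thickness / nSlices
  zLow <- (seq_len(nSlices) - 1) * d
  new("SlabProfile",
      slices = data.frame(zLow = zLow, zHigh = zLow + d, d = d,
                          vProt = 0, sldProt = sldFilm, rhoSlice = 0,
                          occupancy = 0, bulk = sldFilm, sld = sldFilm),
      sldSolvent = sldSolvent, sldSubstrate = sldSubstrate,
      rhoBox = 1e-3, rhoNorm = 0, rhoTotal = 0, aBox = 1,
      zInterface = 0)
}

# Rotate a model's coordinates about the z axis (in-plane rotation).
rotateAboutZ <- function(model, angleDeg) {
  a <- angleDeg * pi / 180
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  out <- model
  out@coords <- model@coords %*% t(rz)
  out
}
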