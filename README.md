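# rbrnr — rigid-body orientation modelling for specular neutron reflection

`rbrnr` models the specular neutron reflectivity of proteins adsorbed at
air/water and oil/water interfaces by **rigid-body rotation** of a
residue-level bead structure. Instead of fitting generic slab parameters, it
fits four physically interpretable quantities — two Euler angles
(θ about *x*, then φ about *y*), a penetration depth *z*<sub>pen</sub> of
the interface plane into the protein, and the surface excess Γ — by
co-refining all isotopic contrasts simultaneously.

## The science in one paragraph

Specular neutron reflection measures *R(Q)*, which encodes the
one-dimensional scattering-length-density (SLD) profile normal to an
interface. Contrast variation (H₂O/D₂O mixtures, null-reflecting water,
different non-aqueous phases) re-weights the protein, solvent and substrate
contributions, so several curves measured on the same layer constrain the
structure far more tightly than one. A protein of known shape, rotated
rigidly and sliced into equal layers, predicts those curves with no free
profile parameters beyond (θ, φ, *z*<sub>pen</sub>, Γ): each residue carries
a tabulated volume and a coherent scattering length that interpolates with
solvent H/D composition through its labile hydrogens; the surface excess
fixes the layer occupancy; slices mix protein with solvent above the
interface plane and with the substrate below it. Reflectivity is computed by
the optical matrix (Parratt/Abelès) recursion, validated in the test suite
against closed-form Fresnel and single-film oracles at 1e-10.

Because the profile depends only on rotated *z* coordinates, the model has
an exact degeneracy z(θ, φ) = z(θ+180°, 180°−φ); fitted orientations are
reported in a canonical gauge with φ ∈ [−90°, 90°) (`canonicalAngles()`).

## Worked example

Ground-truth recovery on a synthetic mAb-like Y-shaped protein
(300 residue beads) under three contrasts with 1% relative noise:

```r
library(rbrnr)
model <- makeBeadProtein("yshape", nBeads = 300, seed = 7)
model
#> ProteinModel 'synthetic-yshape': 300 residue beads, 1 chain(s), MW 32,745.95 Da
#>   extents (x, y, z): 111.6 x 129.8 x 32.1 A

truth     <- adsorptionState(30, 45, 10, 2.0)   # theta, phi, zPen, Gamma
contrasts <- syntheticContrasts(model)          # NRW, CMProtein, D2O
sim       <- simulateExperiment(model, truth, contrasts,
                                sigmaRel = 0.01, seed = 11)
problem   <- fitProblem(model, contrasts, sim$curves)

fit <- bestFit(problem, seed = 1)               # DE + lattice rescreen + NM
fit$state
#> AdsorptionState (XY): theta = 29.89 deg, phi = 45.01 deg,
#>   z_pen = 9.98 A, Gamma = 1.997 mg/m^2
fit$chi2                                        # 179.66 over 303 points

recoveryScore(fit$state, truth, model, contrasts)
#> $thetaError          0.113 deg
#> $phiError            0.011 deg
#> $zPenError           0.017 A
#> $gammaError          0.0033 mg/m^2
#> $profileRMS          0.046   (1e-6 A^-2)
#> $profileRMSFraction  0.0072  (fraction of profile dynamic range)
```

Posterior sampling (DRAM, periodic in the angles) and orientation
uncertainty on the torus:

```r
chains <- runMCMC(problem, nSteps = 50000, nBurn = 10000, seed = 1,
                  init = fit$par)
acceptanceRate(chains[[1]])                     # 0.787
pb <- postBurn(chains[[1]])
univariateInterval(pb[, "zPen"])                # mean 9.976, sd 0.082
univariateInterval(pb[, "gamma"])               # mean 1.9968, sd 0.0015

dens <- kdeTorus(pb[, c("theta", "phi")])
hp   <- hpdRegions(dens)
hp
#> HPDRegionSet:
#>   25%: area 1 deg^2 (mass 0.2989)
#>   65%: area 4 deg^2 (mass 0.7103)
#>   95%: area 11 deg^2 (mass 0.9582)
hpdrContains(hp, dens, 0.95, 30, 45)            # TRUE
```

Structural readout of the fitted state:

```r
footprintSummary(model, fit$state@theta, fit$state@phi, fit$state@gamma)
#> FootprintResult: APM convex 6334 A^2, concave 4078 A^2,
#>   from Gamma 2723 A^2 (coverage 2.33)
penetratedFraction(rotateModel(model, fit$state@theta, fit$state@phi),
                   fit$state@zPen)
#> 0.05
```

(Coverage > 1 flags that at this Γ the molecules cannot all lie flat in a
single monolayer at this orientation without lateral overlap — the concave
footprint is the honest per-molecule area, and the layer accommodates the
excess through the tilted, interpenetrating packing the occupancy model
describes.)

## Package layout

| Area | Files |
|------|-------|
| Residue scattering tables, water/solvent SLDs | `R/scattering-params.R` |
| Bead models, PDB I/O, canonical orientation | `R/structure-model.R` |
| Rotation, slicing, SLD profile assembly | `R/rbrm-core.R`, `src/` |
| Optical matrix reflectivity, smearing, χ² | `R/reflectivity.R`, `src/` |
| Global fit (DE + Nelder–Mead) and DRAM MCMC | `R/inference.R` |
| Torus KDE, HPD regions, bands | `R/posterior-analysis.R` |
| Convex/concave footprint, APM | `R/footprint.R` |
| Synthetic proteins and experiments | `R/synthetic-data.R` |
| YAML-driven CLI (`inst/exec/rbrnr`) | `R/cli.R` |
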