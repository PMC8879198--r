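# mapfitr

Template-based model building against cryo-EM density maps, at desk scale.

Medium-resolution cryo-EM maps (say 4–8 Å) rarely support de novo tracing.
The working alternative is template-based: detect remote homologs with
sensitive profile–profile alignment, dock the candidate models rigidly into
the map, keep the candidates that actually fit the density, deform the
survivors flexibly to maximize the fit without destroying their
stereochemistry, and validate the result with map–model agreement metrics.
`mapfitr` implements that whole loop as a reusable R toolkit (S4 classes,
Bioconductor-style interfaces) for structural bioinformaticians who want
each step available, testable and scriptable — with a deterministic
synthetic-fixture generator so everything runs and is verified without a
single download.

## The models at the core

**Simulated density.** A model's density is a sum of atomic Gaussians
integrated exactly over each voxel:
ρ<sub>sim</sub>(i,j,k) = Σ<sub>n</sub> ∫<sub>V<sub>ijk</sub></sub>
exp(−(3/2σ²)·|r − r<sub>n</sub>|²) dr, where σ is the map resolution in Å
(verbatim — no FWHM conversion). The voxel integral is an exact product of
error-function differences.

**Fit score.** CCC = Σ ρ<sub>exp</sub>ρ<sub>sim</sub> /
√(Σ ρ<sub>exp</sub>² · Σ ρ<sub>sim</sub>²), non-centered and
scale-invariant.

**Rigid docking.** Exhaustive z-y-z Euler lattice over rotations; for each
rotation all integer-voxel translations scored at once by 3-D FFT of the
correlation numerator, then exact-CCC rescoring, de-duplication and local
refinement of the top placements. Deterministic.

**Flexible fitting.** Minimizes E<sub>restraint</sub> + E<sub>EM</sub> with
E<sub>EM</sub> = N·k·(1 − CCC) over the Cα coordinates, with exact analytic
gradients. The restraints are structure-based: consecutive-Cα bonds plus
flat-bottomed native-contact terms, preserving the starting fold while the
map bias pulls. Gradient descent (monotone, deterministic) or seeded
Langevin dynamics.

**Validation.** CCmask / CCvolume / CCpeaks / CCbox (centered Pearson over
an atom mask, the top-density regions, and the whole box) and per-residue
SMOC (non-centered Manders overlap over a sliding residue window).

**Template detection.** Profiles are L×20 log-odds matrices; the match
score of two columns is their Pearson correlation; affine-gap DP (glocal or
local) finds the alignment; library scores are calibrated into Z-scores by
regression on log(L<sub>q</sub>·L<sub>t</sub>).

## Worked example

Bend a two-domain fixture at its hinge by 25°, dock it back into the map
simulated from the straight reference at σ = 6 Å, then fit flexibly:

```r
library(mapfitr)

ref    <- makeStructure("two-domain-hinge", 40)
params <- densitySimParams(sigma = 6)
expMap <- simulateDensity(ref, "auto", params)
expMap
#> DensityMap 30 x 19 x 28, spacing (3.00, 3.00, 3.00) A
#>   origin (-26.28, -26.24, -24.00) A, range [0, 116.9]

bent <- perturbModel(ref, list(kind = "hinge", angle = 25), seed = 11)

placements <- rigidFit(expMap, bent, rigidSearchConfig(params, angularStep = 20))
head(placementTable(placements), 3)
#>   rank       ccc rotationDeg translationA
#> 1    1 0.9975359    2.231864    0.8855594
#> 2    2 0.9439703  179.350489   42.1793251
#> 3    3 0.8926429   28.212089    4.7271962

fit  <- flexibleFit(bent, expMap, flexFitConfig(sigma = 6, k = 5, maxSteps = 600))
traj <- fit$trajectory
round(c(cccBefore = traj$ccc[1],            cccAfter = traj$ccc[nrow(traj)],
        rmsdBefore = rmsd(bent, ref),       rmsdAfter = rmsd(fit$model, ref),
        contacts = contactPreservation(fit$model, fit$restraints)), 4)
#>  cccBefore   cccAfter rmsdBefore  rmsdAfter   contacts
#>     0.9792     1.0000     1.3591     0.6702     1.0000

mapModelCC(expMap, fit$model, sigma = 6)
#> MapModelScores: CCmask 1.000  CCvolume 1.000  CCpeaks 1.000  CCbox 1.000 (mask 131 voxels)
```

Reading the numbers: rigid docking alone recovers the bent model's best
rigid pose (CCC 0.998 — good, but the hinge misfit remains, RMSD 1.36 Å to
the reference). Flexible fitting raises the CCC to 1.000 while halving the
RMSD to the reference and keeping 100 % of the native contacts — fit
improved, structure intact. The four CC metrics at 1.000 confirm the
map–model agreement globally and over the masked region.

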