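---
title: "Map-model fitting with mapfitr: models, parameters and design notes"
author: "mapfitr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-model fitting with mapfitr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapfitr)
```

# Scope

`mapfitr` implements the computational core of template-based model building
against cryo-EM density maps: detecting templates by profile-profile
alignment, docking candidate models rigidly into a map, deforming them
flexibly under a map-bias energy, and scoring the final agreement between
map and model. This vignette explains the underlying models, the tunable
parameters and the design decisions, in the package's own words. Every
number quoted here is computed by the test suite or the acceptance script;
the vignette states no empirical claim beyond them.

# Simulated density and the CCC

A model's density on a voxel grid is the sum over heavy atoms of an
isotropic Gaussian kernel,

$$\rho_{sim}(i,j,k) \;=\; \sum_{n=1}^{N} \int_{V_{ijk}}
\exp\!\Big(-\frac{3}{2\sigma^2}\,\lVert r - r_n \rVert^2\Big)\, dr ,$$

integrated exactly over each voxel. Because the kernel factorises per axis,
each voxel integral is a product of three 1-D error-function differences;
no point sampling is involved. Truncation is rectangular at
`truncationRadius * sigma` (default 4σ) around each atom; at that radius
the neglected mass is below one part in 10^5, and the suite checks that the
grid total matches the closed form $N\,(2\pi\sigma^2/3)^{3/2}$ to 0.1 %.

**σ convention.** `sigma` *is* the nominal map resolution in Å, verbatim.
Many packages instead use half the resolution, or convert through the FWHM
($\sigma = r / (2\sqrt{2\ln 2})$). We deliberately do neither; when
comparing against another tool, convert explicitly.

The map-model cross-correlation coefficient is the non-centered overlap

$$\mathrm{CCC} = \frac{\sum \rho_{exp}\,\rho_{sim}}
{\sqrt{\sum \rho_{exp}^2\; \sum \rho_{sim}^2}},$$

which is invariant to rescaling of either map; experimental maps are used
as-is, with no low-pass filtering or normalization. Grid convention
throughout: the origin is the world coordinate of the **center** of voxel
(1,1,1) (indices are 1-based, the R idiom), and a voxel spans half a
spacing either side of its center.

# Rigid-body docking

The 6-D search enumerates a z-y-z Euler-angle lattice (default step 20°,
with the gimbal-degenerate rings at β = 0°/180° reduced to a single γ) and,
for each rotation, scans all integer-voxel translations at once via the 3-D
FFT of the cross-correlation numerator. The denominator term
$\sum\rho_{sim}^2$ is nearly translation-invariant (exactly so up to
boundary truncation), so numerator ranking is a faithful proxy; the top
candidates (default 20) are then re-scored with the exact CCC.

Three refinements beyond the minimal scheme proved necessary in practice
and are part of the method:

* the **as-given input pose** is always evaluated as a candidate, so the
  returned top placement can never score below the unfitted pose;
* near-duplicate placements (rotation within half the angular step *and*
  translation within the peak separation) are merged, so genuinely distinct
  solutions — for example the two symmetry mates of a C2 dimer — surface in
  the top ranks;
* the best three candidates are polished by derivative-free (Nelder-Mead)
  maximization of the exact CCC over the six rigid degrees of freedom
  (`refine = TRUE`), which recovers sub-voxel, sub-degree placements from a
  20° lattice.

The search is fully deterministic: no randomness anywhere, ties in the
translation scan broken by smallest shift norm then lexicographically.

# Flexible fitting

The fitting energy is $E = E_{restraint} + E_{EM}$ with

$$E_{EM} = N \times k\,(1 - \mathrm{CCC}),$$

where $N$ is the number of (heavy) atoms and $k$ the bias strength
(default 1, dimensionless in reduced units). The gradient of $E_{EM}$ is
exact: the quotient rule through the CCC composed with the derivative of
the voxel integrals, which is a difference of face Gaussians per axis —
no numerical differentiation.

The structural term is a Cα structure-based (Gō-like) potential built from
the *starting* structure: harmonic virtual bonds between consecutive Cα
(force constant `kBond = 10`), and flat-bottomed harmonic contacts
(`kContact = 0.2`, half-width `delta = 0.5` Å) between Cα pairs at sequence
separation ≥ 3 within 8 Å. This stands in for an all-atom force field: the
two ingredients the method actually relies on — a CCC bias and maintenance
of the native contact network — are kept faithfully, while remaining
desk-scale, deterministic and seedable. Consequently the package fits Cα
traces, not side chains, and reports no stereochemistry beyond bonds and
contacts.

Two integrators are provided. Gradient descent with backtracking line
search is the default: deterministic, with provably non-increasing total
energy at every accepted step (asserted over whole trajectories in the
suite). Langevin (BAOAB discretization, default temperature 0.1, timestep
0.05, friction 1 in reduced units) adds seeded thermal noise and returns
the lowest-energy visited conformation; it is bit-reproducible for a fixed
seed. Runs stop at `maxSteps` (default 2000) or when the CCC changes by
less than `convergenceDccc` (1e-6) over `convergenceWindow` (50) steps.
Increasing $k$ from 0.1 to 10 monotonically increases the final CCC on the
hinge fixture; $k \to 0$ leaves the start unchanged. (Tools that expose a
map-weight multiplier play the role of $k$ here; there is no second bias
knob.)

# Agreement metrics

Four global correlations and one local profile are computed, mirroring the
two conventions in circulation:

* **CCmask / CCvolume / CCpeaks / CCbox** are *centered* Pearson
  correlations between the experimental map and the model's simulated map
  over, respectively: voxels within a fixed radius (default 3 Å) of any
  atom; the model map's highest-valued voxels of the same count as the
  mask; the union of the model's and the experiment's top voxels; and the
  whole grid. The mask is a union of fixed-radius spheres, not per-element
  atomic radii — a documented simplification.
* **SMOC** is the *non-centered* Manders overlap over a sliding segment of
  `window` residues (default 11, odd; chains shorter than the window use
  the whole chain), masked at `radius` (3 Å) around the segment's atoms.
  It lies in [0, 1] for non-negative maps and is reported per residue.

The coexistence of centered and non-centered conventions is deliberate:
each metric follows its source definition. On a model's own simulated map
all five reach exactly 1, and a single displaced residue produces a SMOC
dip within half a window of the defect — both asserted in the suite.

# Template detection

Profiles are L × 20 position-specific score matrices. `buildProfileFromMSA`
computes, per column, relative residue frequencies among non-gap letters,
adds a pseudocount on the *frequency* scale ($f_a' = (f_a + c)/(1 + 20c)$,
default $c = 1$), and stores log-odds against the uniform background 1/20.
Pseudocounting frequencies rather than counts keeps a column's scores
independent of alignment depth (five identical sequences give the same
profile as one). Columns where the query has a gap are dropped.

The match score between two columns is their Pearson correlation, so any
column representation with variance works. Alignment is affine-gap dynamic
programming (open 1.0, extend 0.1 on the correlation scale — the penalties
are a package default, configurable) in two modes: *glocal* (global with
free end gaps, the template-detection default; at a terminus with overhangs
on both sides, one side's overhang is the free end gap and the other pays
its affine cost) and *local* (Smith-Waterman). Traceback ties prefer match
over gap-in-template over gap-in-query, making the optimum path
deterministic. The DP optimum is verified against exhaustive enumeration of
every monotone alignment for lengths up to 5.

Raw scores are calibrated into Z-scores by regressing library scores on
$\log(L_q L_t)$ and standardizing by the residual standard deviation
(n − 2 denominator); Z-scores are invariant to affine rescaling of the
library scores. Queries without full-length templates can be split into
overlapping fragments (`splitQuery`), with the last window anchored at the
end so coverage is complete.

# Selection pipeline

`scoreCandidates` docks every candidate and records its best CCC, a
secondary-structure similarity against a supplied prediction (computed on
the model side from the Cα trace with P-SEA-style distance bands:
d(i,i+3) ∈ [4.4, 5.8] Å and d(i,i+4) ∈ [5.5, 6.9] Å for helix,
d(i,i+2) ≥ 6.4 Å for strand; a model of the wrong length scores 0), and
any externally supplied per-model quality columns (e.g. verify3d, ddfire),
which are passed through untouched — the package does not reimplement
those scorers. `filterCandidates` applies explicit conjunctive thresholds
(the method's canonical operating point is CCC > 0.75 together with
secondary-structure similarity > 0.75) and ranks by CCC; there is
deliberately no fixed rule for *how many* candidates to keep — thresholds
are explicit instead. `assembleModels` applies placements, relabels chains
uniquely and reports inter-component Cα clashes below 3 Å.

# The synthetic fixture generator

All tests run on generated data. Structures are idealized Cα traces with
exact 3.8 Å spacing: helices with 1.5 Å rise and 100° twist per residue
(the radius then follows from the spacing), joined where needed by exactly
solvable two-residue linkers. Four kinds cover the behaviors the toolkit
must show: a single helix; a three-helix bundle with *unequal* helix
lengths (equal lengths would give the smoothed density spurious two-fold
pseudo-symmetries that confound docking tests); a C2 dimer whose protomer
is an asymmetric two-helix hairpin, with the symmetry exact by
construction; and a two-domain L-shaped hinge fixture whose hinge axis runs
along the central linker bond, so hinge rotations are exactly invertible.

Perturbations produce test conditions: seeded isotropic jitter, seeded
random rigid offsets, and deterministic hinge bends. MSAs are sampled from
a fixed physicochemical exchange table (self-probability 0.3); map noise is
white Gaussian scaled to the map maximum, optionally clamped at zero.

`decoyLibrary` packages the ten-candidate selection experiment: one
near-native model (0.1 Å jitter), three hinge-bent models (15°/25°/35° —
intact secondary structure, degraded fit, built to pass the thresholds),
three wrong-fold models and three heavily jittered models (2.5-4 Å). The
wrong folds are there because, at σ = 5 Å, even 4 Å of jitter still docks
as a blob with CCC ≈ 0.87: perturbation alone cannot produce a
CCC-failing decoy, whereas a wrong fold (the realistic failure mode of
template selection) docks near CCC ≈ 0.6-0.75.

What the generator does *not* emulate: side chains, realistic loop
geometry, B-factor variation, solvent, detector noise correlation, or map
anisotropy. Passing tests therefore demonstrate the correctness and the
qualitative behavior of the algorithms (recovery, monotonicity,
localization, determinism), not accuracy on experimental maps.

# Numerical choices and problem sizes

* Voxel integrals: exact erf products; simulation, EM gradients and atom
  masks are implemented in C++ (the only compiled code in the package).
* Auto-gridding: bounding box + margin (default 4σ), spacing σ/2.
* Rigid search: 20° lattice (≈ 2.9k rotations), top-20 rescoring, top-3
  refinement; fixtures of 40-60 residues on ~25³ grids, which keeps one
  docking run in the tens of seconds.
* Flexible fitting: 40-residue fixtures, a few hundred steps at k = 5 for
  the recovery experiments.
* Degenerate inputs fail loudly: zero maps in the CCC, zero-variance
  Pearson regions, collinear superpositions, coincident bonded atoms,
  non-overlapping starts for flexible fitting (which requires initial
  CCC > 0, i.e. a prior rigid fit).

# Known limitations

Cα-only fitting; orthogonal cells and mode-2 MRC only; no map
segmentation beyond zones and boxes (interactive splitting of a complex
map is out of scope); TM-score uses the standard iterative heuristic and
is exact only where the optimum is attainable (rigid copies), a lower
bound otherwise; external quality scores are inputs, never recomputed.
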