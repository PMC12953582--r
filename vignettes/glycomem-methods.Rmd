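---
title: "Membrane-relative geometry metrics and the COIN-CaR-nMS binding model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-relative geometry metrics and the COIN-CaR-nMS binding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomem)
```

## Scope and model system

`glycomem` quantifies how an immunoglobulin-fold lectin (a Siglec) engages a
ganglioside presented from a lipid bilayer, and how tightly it binds the same
glycan free in solution. The trajectory side of the package measures
membrane-relative geometry from all-atom simulation frames: how the sialylated
headgroup is oriented (and hence how accessible its sialic acid is), whether
the canonical arginine-sialic acid salt bridge is formed, how the Ig V-set
domain sits relative to the bilayer, and how deeply anchoring sidechains
(a tryptophan indole, a lysine) dip below the phosphate surface. The
solution side implements the concentration-independent catch-and-release
native mass spectrometry (COIN-CaR-nMS) occupancy model and fits dissociation
constants from time-resolved ion abundances. A synthetic-data generator
produces trajectories and titration series with known ground truth so every
metric and fit is verifiable without microsecond trajectories.

## The bilayer surface model

All membrane-relative metrics need a definition of "the membrane surface".
The package uses the phosphate plane, the standard proxy for a
phosphatidylcholine bilayer: per frame, the midplane is the mean z of all
selected phosphate marker atoms, leaflets are assigned by the sign of
`z - midplane_z`, and each leaflet surface is the mean z of its own atoms.
The membrane normal defaults to the laboratory +z axis, since bilayers are
conventionally built in the xy plane; a plane-fit normal (smallest principal
component of the pooled phosphate cloud) is available via `normal = "fit"`
for tilted or drifting patches. Periodic-boundary effects are *not* handled:
inputs are assumed imaged and whole, which holds for post-processed
trajectories and for everything the generator emits. This is a documented
limitation, not a silent assumption.

## Glycan headgroup tilt

The headgroup orientation is a single angle: the tilt between the vector
from the C1 atom of the terminal galactose to the centroid of the sialic
acid's C2 and C3 atoms, and the outward membrane normal of the leaflet
holding the glycolipid. Two atoms define the tip, so the centroid is the
symmetric reading of a two-atom tip specification; both atoms are
configurable through `tilt_spec()`. Angles are reported in degrees in
[0, 180], with 0 meaning an upright, fully exposed headgroup. Frames where
the axis vector collapses below 1e-6 Angstrom are masked with a warning
rather than producing spurious angles.

## Ig V-set domain orientation

The domain axis is built from principal component 1 of the C-alpha cloud.
Two conventions are provided because "the principal component of the
dynamics" is genuinely ambiguous:

- `mode = "pooled"` (default): PC1 of the per-frame-centred C-alpha
  coordinates pooled across all frames. Centring removes translation; the
  pooled covariance captures the dominant direction of the ensemble. With
  this convention the axis direction is one vector for the whole
  trajectory, so the tilt trace is constant unless the cloud deforms.
- `mode = "per_frame"`: the geometric principal axis of each frame's cloud,
  giving a frame-resolved orientation trace suitable for a tilt
  distribution.

The per-frame axis runs from the instantaneous centre of mass to an
auxiliary point 10 Angstrom along PC1 (the distance is configurable and
cancels in the angle; it is kept for visualisation). The PC1 sign is fixed
so the axis points away from the membrane (dot product with the normal
non-negative). If the top two covariance eigenvalues coincide within 1e-9
the axis is ambiguous and the operation refuses rather than guessing.

## Salt bridge and occupancy

The arginine-sialic acid salt bridge is scored on the four distances between
the guanidinium NH1/NH2 and the carboxylate O11/O12 atoms. The per-frame
reported distance is by default the *maximum* over the four pairs, and the
bridge counts as formed when that aggregate is at or below 5 Angstrom
(inclusive). A maximum is an unusually strict convention - a salt bridge is
more commonly scored by the minimum pair distance - but it is the convention
this analysis chain is built around; `aggregator = "min"` is available, and
`formed(max)` always implies `formed(min)`, which the test suite asserts.
Occupancy is the mean of the formed indicator over unmasked frames of an
explicit, 0-based, inclusive frame range; the range is explicit because
published occupancies are sensitive to whether restrained equilibration
segments are included, and the caller must own that choice.

## Sidechain insertion

Insertion uses the unweighted centre of mass of one residue's sidechain
heavy atoms (standard per-residue atom-name tables are built in). For the
upper leaflet, depth is `upper_surface_z - COM_z`, so positive depth means
the sidechain sits below the phosphate surface, inside the membrane; the
convention mirrors for the lower leaflet. The insertion percentage is the
occupancy of the `depth > 0` indicator. Selections crossing residues are
rejected.

## KDE mode extraction

Angle distributions are summarised by the mode of a Gaussian kernel density
estimate. The implementation evaluates the exact (un-binned) KDE on a
uniform grid at 0.01-degree resolution spanning the data range padded by
three bandwidths; the mode is the grid argmax, ties resolving to the lowest
grid point. The default bandwidth is Scott's rule, `sd(x) * n^(-1/5)`, the
default of the Python plotting ecosystem whose KDE summaries this mirrors.
For speed the kernel sum is truncated at eight bandwidths, where omitted
contributions are below 1e-14 of the peak density - numerically
indistinguishable from the full sum. Degenerate (zero-variance) inputs
return the single value with a `degenerate` flag; fewer than 10 values is an
error rather than a meaningless density.

## Backbone superposition and model confidence

`kabsch_superpose()` computes the least-squares rigid superposition via SVD
of the cross-covariance of the paired, centred point sets, with the
determinant correction that excludes reflections; superposition is
equal-weight with no outlier trimming, matching how a single plain backbone
RMSD is reported when validating a predicted structure against a crystal
reference. Backbone means N/CA/C/O, with a `ca_only` option since "backbone
atoms" is ambiguous in the literature. Collinear point sets leave a rotation
unconstrained and raise an error. AlphaFold-style confidence values are read
from the B-factor column; `plddt_summary()` bins residues into *disjoint*
confidence classes - very high (pLDDT > 90) and high (70 < pLDDT <= 90) - so
the fractions can be summed, following the AlphaFold database convention
rather than the overlapping verbal bins sometimes quoted.

## The COIN-CaR-nMS occupancy model

In a COIN-CaR-nMS titration, slow in-emitter mixing makes the free-ligand
exposure grow approximately linearly with time, `L(t) = C_L t`. For 1:1
binding with protein at initial concentration `P0`, the fraction of
protein-bound ligand reported through the released-ligand ion channel is

$$
F(t) = DE\,\frac{P_0 + C_L t + K_d -
\sqrt{(K_d - C_L t + P_0)^2 + 4 K_d C_L t}}{2 P_0},
$$

where `DE` is the detection efficiency of the released glycan relative to
the protein ion. `F(0) = 0` exactly, `F` rises monotonically, and
`F -> DE` as `t -> Inf`. The observed fraction bound is the abundance ratio
`Ab_t(L) / Ab_t(P)`, deliberately not clipped at 1 since `DE` can exceed
unity. The linear ramp is the printed model; a caller-supplied exposure
function `L(t)` replaces it when the flux is known to be non-linear.

### Fitting and identifiability

`coin_fit()` minimises the unweighted (optionally weighted) sum of squared
residuals over `(K_d, DE, C_L)` with positivity bounds and `DE <= 5`,
returning a classed model object with the usual `print`, `summary`, `coef`,
`predict`, `fitted`, `residuals`, `plot` and `simulate` methods. Parameter
units are micromolar throughout, with `K_d` also reported in millimolar to
match how native-MS affinities are conventionally quoted.

The objective has a structural ridge that any user of this model should
understand. In the limit `P0 -> 0` the model collapses exactly to
`F = DE * t / (t + K_d / C_L)`: only `DE` and the ratio `K_d / C_L` are
identified, and `K_d` alone enters through a correction of order
`P0 / K_d`. For a weak binder measured at sub-micromolar protein
concentration (e.g. `K_d` of hundreds of micromolar at `P0` below one
micromolar) that correction is ~1e-6 of the signal: exact (noiseless) data
still pin `K_d` - the package recovers it to better than 1e-6 relative - but
realistic noise of 0.01 on the fraction bound leaves `K_d` essentially
unconstrained along the ridge, however good the optimiser. The fit therefore
proceeds in two deterministic stages: a bounded Levenberg-Marquardt pass
(with log-spaced `K_d` restarts and a derivative-free fallback if it fails),
then Brent profile refinement over `log10(K_d)` in which the
well-conditioned `(DE, C_L)` subproblem is refit at each candidate. Profile
refinement is what makes noiseless self-recovery exact; no optimiser can
manufacture information the noisy data do not contain. Standard errors come
from the local quadratic approximation at the optimum and will be honestly
enormous for `K_d` in the ridge regime. When `K_d` is comparable to `P0`
(protein depletion is visible), all three parameters are identified, and
recovery degrades gracefully with noise and improves with the number of
time points - the property suite demonstrates both regimes.

### Nanodisc arithmetic

Nanodisc experiments need two small calculations performed consistently: the
per-disc ganglioside/phospholipid split (mole fraction times the ~200
lipids per disc, rounded to the nearest integer) with totals scaling
linearly in disc concentration, and the disc concentration itself from
scaffold-protein absorbance via Beer-Lambert with the MSP1E1 extinction
coefficient (32,430 per M per cm) and two scaffold copies per disc.

## The synthetic-data generator

The generator emits only what the metrics consume, not physically realistic
lipids: phosphate markers on two jittered planes (64 per leaflet at +/-19
Angstrom with 0.5 Angstrom Gaussian z-jitter by default), a glycolipid
headgroup axis whose polar tilt is drawn from a wrapped normal about a
prescribed mode with uniform azimuth, a rigid C-alpha cloud rotated so its
*empirical* principal axis realises the orientation schedule exactly, a
four-atom salt-bridge geometry in which all four cation-anion pair distances
equal the scheduled value exactly (two perpendicular atom pairs, a
tetrahedral arrangement), and a sidechain set whose centre of mass is placed
at the scheduled depth relative to the *realised* (jittered) per-frame
surface so insertion percentages are exact by construction. Default tilt
modes follow the measured headgroup orientations of the two gangliosides the
study conditions are built around (31.32 and 41.83 degrees for the GM1-like
and GM3-like cases); the angular spread (7 degrees) is a realistic choice
for a lipid headgroup wobbling in a bilayer and is stated once here rather
than tuned. Seeds are mandatory in every recipe so no test is silently
nondeterministic.

What the generator does *not* emulate - lipid chemistry, correlated
dynamics, force-field physics, periodic boundaries - bounds what passing
tests prove: they verify the measurement chain (file formats, selections,
geometry, statistics, fitting) end to end, not the molecular realism of any
particular simulation.

## Numerical choices and problem sizes

- Coordinates in Angstrom, times in nanoseconds (trajectories) and minutes
  (titrations), frames 0-based; PDB coordinates round-trip at the format's
  three-decimal precision.
- KDE grids at 0.01 degrees; modes reported to two decimals in summaries.
- Salt-bridge threshold inclusive at exactly 5.0 Angstrom; boundary
  behaviour is asserted in the tests with a 3-4-5 triangle.
- The test and acceptance workloads use 200-frame schedules, 20,000-frame
  tilt samples and 50-replicate fit studies: large enough that statistical
  bands (0.5 degrees on a KDE mode; 3 sigma / sqrt(n) on surface heights)
  are meaningful, small enough to run on a laptop in seconds.
- Fixture tolerances are exact for schedule-driven quantities (occupancy,
  insertion) and statistical for distribution-driven ones (KDE modes, noisy
  Kd), with the band recorded next to each value in the fixture manifest.

## Known limitations

- No periodic-boundary imaging; no binary trajectory formats (multi-model
  PDB and a columnar frame table are the two dialects).
- The pooled-PC1 domain axis yields a constant orientation for a rigid
  domain; use the per-frame mode for orientation distributions.
- Salt-bridge scoring follows the max-over-pairs convention described
  above; occupancies computed under max and min conventions can differ
  materially, so the aggregator is always recorded in pipeline output.
- `K_d` from COIN data is structurally weakly identified whenever
  `K_d >> P0`; report `K_d / C_L` or fix `C_L` from calibration when that
  regime applies.
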