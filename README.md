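# glycomem

Quantitative analysis of membrane-presented glycan recognition by
immunoglobulin-fold lectins (Siglecs), for structural bioinformaticians and
native-MS practitioners working on glycolipid binding.

Siglecs read sialylated glycans, and for gangliosides the epitope barely
pokes out of the bilayer: whether a receptor can engage it depends on the
headgroup's tilt relative to the membrane normal, on a canonical
arginine-sialic acid salt bridge that may form only intermittently, and on
whether membrane-facing sidechains (a tryptophan, a lysine) dip below the
phosphate surface and anchor the domain. This package measures all of that
from coordinate trajectories, validates predicted structures against
crystallographic references by backbone superposition, and fits binding
affinities from concentration-independent catch-and-release native mass
spectrometry (COIN-CaR-nMS) titrations.

## What it computes

**Trajectory metrics** (multi-model PDB or a columnar frame-table dialect in):

- Bilayer surface model: per-frame leaflet surfaces from phosphate marker
  atoms; membrane normal along lab z or plane-fit.
- Glycan headgroup tilt θ: angle between the terminal-galactose-C1 →
  sialic-acid-C2/C3-centroid vector and the outward leaflet normal.
- Ig V-set domain tilt: angle between the Cα-cloud principal axis (pooled or
  per-frame convention) and the membrane normal.
- Salt-bridge distance and occupancy: aggregate (default max) over the four
  NH1/NH2 × O11/O12 pair distances, formed at ≤ 5 Å inclusive; occupancy is
  the fraction of frames formed over an explicit frame range.
- Sidechain insertion: fraction of frames a sidechain's centre of mass sits
  below the leaflet surface.
- KDE mode extraction: exact Gaussian KDE (Scott bandwidth, 0.01° grid) with
  the mode as grid argmax.

**Structure comparison**: Kabsch least-squares superposition (proper
rotations only) with backbone RMSD, and AlphaFold pLDDT confidence
summaries read from the B-factor column (disjoint bins: pLDDT > 90 very
high, 70 < pLDDT ≤ 90 high).

**COIN-CaR-nMS binding model**: fraction bound `F_t = Ab_t(L)/Ab_t(P)`, the
occupancy curve

    F(t) = DE · (P0 + C_L·t + Kd − sqrt((Kd − C_L·t + P0)² + 4·Kd·C_L·t)) / (2·P0)

and least-squares fitting of `(Kd, DE, C_L)` via `coin_fit()`, a classed
model object with `print`/`summary`/`coef`/`predict`/`plot`/`simulate`/
`residuals` methods. Nanodisc helpers convert scaffold-protein absorbance to
disc concentration and mole fractions to per-disc lipid counts.

**Synthetic data**: seeded generators for bilayer trajectories with
prescribed tilt distributions, salt-bridge and insertion schedules, and for
COIN titrations with known parameters — so every metric and fit is testable
against exact ground truth.

## Worked example

```r
library(glycomem)

# a 2000-frame synthetic system: GM1-like headgroup tilt about 31.32 deg,
# salt bridge scheduled formed for 1370 of 2000 frames
r <- membrane_recipe(n_frames = 2000, seed = 11,
                     bilayer = list(n_per_leaflet = 16),
                     glycolipid = list(tilt_mode = 31.32, tilt_spread = 7),
                     saltbridge = list(schedule = seq_len(2000) <= 1370))
tr <- generate_membrane_trajectory(r)
surf <- fit_bilayer_surface(tr, selection("phosphates", atom_name = "P"))

tilt <- glycan_tilt_series(tr,
  tilt_spec(selection("Gal C1", atom_name = "C1"),
            selection("Neu5Ac C2/C3", atom_name = c("C2", "C3"),
                      residue_name = "SIA")),
  surf)
kde_mode(tilt)
#> kde_result: n = 2000, bandwidth = 1.5380, mode = 30.69

sb <- salt_bridge_series(tr, salt_bridge_spec(
  selection("Arg122 NH1/NH2", atom_name = c("NH1", "NH2"), residue_name = "ARG"),
  selection("Neu5Ac O11/O12", atom_name = c("O11", "O12"), residue_name = "SIA")))
attr(occupancy(sb$formed), "percent")
#> [1] 68.5

# Kd from a noiseless synthetic COIN titration (Kd 500 uM, DE 0.8, C_L 1)
ds <- generate_coin_series(coin_recipe(kd = 500, de = 0.8, cl = 1, p0 = 0.8,
                                       times = seq_len(60), noise_sigma = 0,
                                       seed = 3))
coin_fit(ds)
#> COIN-CaR-nMS occupancy fit
#>   Kd = 500 uM (0.5 mM)   DE = 0.8   C_L = 1 uM/min
#>   [P]0 = 0.8 uM, 60 points, SSE = 5.116e-26, converged: TRUE
```

The KDE mode (30.69°) recovers the generating tilt mode within the sampling
error of 2000 frames; the occupancy is exact because it is schedule-driven;
and the noiseless fit returns the generating parameters to numerical
precision. See the vignette (`vignettes/glycomem-methods.Rmd`) for the
models, conventions and — importantly — when `Kd` is and is not identifiable
from COIN data.

Pipelines can also be driven from a single JSON config
(`run_pipeline("run.json")`, or `inst/cli/glycomem.R --config run.json`
from a shell), which validates inputs up front, writes per-stage metric
CSVs and aggregates headline numbers into a deterministic `summary.json`.

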