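Package: glycomem
Title: Membrane-Relative Trajectory Geometry and Native MS Binding Analysis for Glycolipid Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of how immunoglobulin-fold lectins recognise
    ganglioside headgroups presented from a lipid bilayer. Provides a light
    trajectory container with multi-model PDB and columnar frame-table I/O,
    membrane-relative geometry metrics (bilayer surface model from phosphate
    marker atoms, glycan headgroup tilt, Ig V-set domain orientation,
    salt-bridge distance and occupancy, sidechain membrane-insertion
    percentage, Gaussian kernel density mode extraction), backbone Kabsch
    superposition RMSD with AlphaFold pLDDT confidence summaries, and the
    concentration-independent catch-and-release native mass spectrometry
    (COIN-CaR-nMS) occupancy model with dissociation-constant fitting and
    nanodisc stoichiometry arithmetic. A synthetic-data generator emits
    trajectories and titration series with known ground truth so every metric
    and fit is verifiable without microsecond simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
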