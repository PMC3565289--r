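Package: AffinityProfiler
Title: Receptor-Surrogate QSAR Affinity Estimation and Per-Residue
    Interaction Profiling for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates small-molecule binding affinities with a
    quasi-atomistic receptor-surrogate multi-dimensional QSAR: pose
    ensembles (4D), discrete induced-fit (5D) and solvation (6D)
    scenarios, genetic-algorithm training of 200-member model families,
    consensus scoring and validation (cross-validated r2, predictive r2,
    Y-scrambling). Decomposes binding free energy into interaction,
    strain, desolvation, rotor-entropy and induced-fit terms and converts
    it to pIC50. A companion molecular-dynamics profiler computes dynamic
    per-residue ligand-protein interaction energies (van der Waals +
    electrostatics) along multi-model PDB trajectories, hydrogen-bond
    occupancies, CSV time series and VMD visualization states. Includes
    synthetic generators (toy pockets, ground-truth QSAR datasets,
    scripted trajectories) so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
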