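Package: oligotraj
Title: Trajectory Analysis of Beta-Sheet Oligomer (De)stabilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics-style trajectories of
    beta-sheet-rich peptide oligomers, with or without bound small-molecule
    ligands. Implements the nematic order parameter P2 over chain end-to-end
    vectors, RMSD/RMSF after Kabsch superposition, a hydrogen-bond-ladder
    secondary-structure assignment with beta-content accounting,
    geometric hydrogen-bond detection and residue-pair H-bond maps,
    ligand-residue contact probabilities, pi-stacking geometry
    classification, switched Coulomb plus Lennard-Jones interaction-energy
    traces, two-dimensional free-energy landscapes over (beta-content, Rg)
    with basin detection, RMSD-based k-medoids conformational clustering,
    and binding-site discovery from contact persistence. A synthetic
    generator builds idealized U-bend cross-beta oligomer trajectories with
    controllable orientational disorder, terminal fraying, beta-ladder
    breakage and rigid surface ligands, providing ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
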