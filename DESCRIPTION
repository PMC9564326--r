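Package: glycomd
Title: Analysis of Protein-Glycan Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing molecular dynamics trajectories of
    protein-glycan complexes: ligand pose stability and 2D-RMSD pose
    clustering, glycosidic torsion extraction with CHI strain-energy
    scoring and Cremer-Pople ring puckering, hydrogen-bond occupancy,
    water-density voxel maps and Ca2+-water-sulfate bridge detection,
    single-trajectory MM-GBSA interaction energies with GB-OBC solvation
    and per-group decomposition, quasiharmonic and Karplus-Kushick
    entropy estimation, alanine truncation and residue deletion for
    computational mutagenesis, and assembly of binding free-energy
    reports with run-level statistics. Includes synthetic-data
    generators with closed-form ground truth so every analysis stage is
    testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
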