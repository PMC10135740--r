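Package: trrdf
Title: Time-Resolved Radial Distribution Functions for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes radial distribution functions (RDFs), time-resolved RDFs
    over user-defined trajectory windows, running coordination numbers, and
    distinct-part van Hove correlation functions from molecular dynamics
    trajectories under orthorhombic and triclinic periodic boundary
    conditions. Includes per-residue ion-interaction profiling for proteins
    (Bjerrum-length cutoff conventions, residue distance and contact maps,
    window-to-cluster aggregation), a minimal atom-selection grammar,
    readers for GRO/PDB/DCD trajectories, seeded synthetic-trajectory
    generators with analytically known pair statistics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rhdf5,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
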