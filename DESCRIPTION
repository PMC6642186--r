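Package: lgicsa
Title: Structural Analysis of Ligand-Gated Ion Channel Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for antagonist-bound pentameric ligand-gated
    ion channel structures and their simulation output. Computes per-residue
    9-bit protein-ligand structural interaction fingerprints (apolar,
    face-to-face and edge-to-face aromatic, hydrogen-bond donor/acceptor,
    electrostatic, and one- and two-water-mediated bridges) over coordinate
    frame series; estimates interaction probabilities with uncertainties by
    Dirichlet posterior sampling of a two-state Markov transition matrix;
    post-processes metadynamics hill lists into free-energy profiles and
    Boltzmann-averaged collective variables for binding-pose ranking;
    profiles ion-channel pore radii along the permeation pathway; and
    measures solvent-accessible surface areas and buried subunit interface
    areas. Includes seeded synthetic-fixture generators with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
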