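Package: roacollagen
Title: Simulation and Analysis of Raman Optical Activity Spectra of
    Collagen-Type Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for simulating and analyzing Raman and
    Raman optical activity (ROA) spectra of collagen-type triple-helical
    peptides. Builds idealized polyproline-II single and triple helices from
    triplet sequence notation, derives molecular formulas and monoisotopic
    masses, cuts labeled geometries into overlapping amide-unit fragments,
    transfers per-atom Cartesian property tensors (force field, dipole,
    alpha, G', A derivatives) between geometries via best-fit local
    rotations, performs harmonic normal-mode analysis with Eckart
    projection, synthesizes backscattered SCP Raman/ROA spectra with
    Lorentzian lineshapes and Boltzmann weighting, preprocesses
    experiment-like spectra (iterative polynomial baseline, water-band
    normalization), computes circular intensity difference (CID) couplet
    statistics and marker-band collagen typing, and analyzes backbone
    conformation (Ramachandran free-energy surfaces, triplet segment
    lengths). A seeded synthetic-data module generates toy force fields,
    chiral property-tensor sets with collagen-like CID magnitudes, noisy
    experiment-like spectra and PPII-concentrated dihedral trajectories in
    lieu of quantum-chemistry and molecular-dynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
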