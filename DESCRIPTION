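Package: phycofret
Title: Chromophore Geometry and Forster Energy Transfer in Phycobiliprotein Trimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-to-photophysics analysis for allophycocyanin-type
    (alpha-beta)3 phycobiliprotein trimers. Reads PDB structures and
    trajectories, identifies bilin chromophores and classifies their binding
    pockets as monomeric or interface, computes trajectory observables
    (inter-chromophore distance distributions, side-chain rotamers, contact
    frequencies, salt bridges, RMSD series), converts donor-acceptor
    geometry into Forster energy-transfer rates via the kappa-squared
    orientation factor, and fits time-resolved emission: multi-exponential
    TCSPC decays by iterative reconvolution with a Gaussian instrument
    response, and femtosecond-picosecond transient-absorption kinetics.
    Includes seeded synthetic generators for pseudo-trimer trajectories and
    photon-counting data, and a pipeline orchestrator with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
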