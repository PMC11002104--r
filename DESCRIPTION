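Package: fodm
Title: Hydrophobicity-Field Analysis of Protein Structures (Fuzzy Oil Drop, Modified)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how far the hydrophobicity distribution of a protein
    structure (or any point cloud with per-residue hydrophobicities) departs
    from the micelle-like ordering induced by water. Computes the theoretical
    3D-Gaussian profile T, the observed pairwise-interaction profile O, the
    uniform reference R, the Kullback-Leibler based RD statistic, and fits the
    environment-modification parameter K of the mixture field
    M = T + K * (Tmax - T) (normalized). Supports whole complexes, chains,
    domains as components or individual units, stem/tentacle partitions and
    interface (P-P) residue classes, with synthetic generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
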