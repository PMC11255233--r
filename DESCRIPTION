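Package: pepscreen
Title: High-Density Peptide Array Screening for Cell-Adhesive and
    Cell-Repellent Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, simulation and analysis of high-density peptide
    microarray screens for cell adhesion. Builds combinatorial peptide
    libraries (overlapping protein tilings, single-substitution scans and
    random fragment recombinations), places replicate spots on a randomized
    synthesis-pixel grid, simulates fluorescence scans with known ground
    truth, quantifies spots by median intensity, detects extreme adhesive
    and repellent peptides from the ranked intensity curve, correlates
    intensities with peptide properties (charge, molecular weight,
    hydrophobicity, helix propensity), builds position-by-residue
    substitution matrices, and infers minimal motifs from runs of extreme
    overlapping windows, exporting them as BED residue tracks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
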