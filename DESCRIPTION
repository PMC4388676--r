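Package: staplekit
Title: Design and Characterization of Hydrocarbon-Stapled Helical Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational arm of a stapled-peptide design
    campaign against a helix-mediated protein-protein interface: per-residue
    buried surface area of a peptide bound in a receptor groove
    (Shrake-Rupley solvent accessibility), ranking of i,i+4 staple positions
    that spare interface hot spots, essential-dynamics analysis of C-alpha
    trajectories with the RMSIP convergence statistic, peptide mass chemistry
    with non-standard stapling residues and terminal modifications,
    proteolytic fragment enumeration and LC-MS mass assignment, first-order
    serum decay and one-site fluorescence-polarization binding fits, and
    CD/NMR helicity profiling from mean-residue ellipticity and H-alpha
    secondary chemical shifts. Seeded synthetic-data generators emulate every
    input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
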