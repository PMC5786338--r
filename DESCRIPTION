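Package: ribotasep
Title: Stochastic Modeling and Inference of Translation Dynamics from
    Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates mRNA translation as an extended totally asymmetric
    simple exclusion process (TASEP) with a 10-codon ribosome footprint and
    censoring of closely stacked ribosomes, and infers transcript-specific
    initiation and per-codon elongation rates from ribosome-profiling
    densities and translation-efficiency measurements.  Includes an exact
    master-equation oracle for small systems, metagene averaging of
    footprint densities and elongation rates, windowed nascent-peptide
    feature regression (charge, hydropathy, mRNA structure), ribosome exit
    tunnel entropic and Coulomb potentials, drop-off rate estimation by
    binned exponential decay, and a synthetic data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
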