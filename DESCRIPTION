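Package: panmethyl
Title: Antibody Selectivity Profiling and Lysine Methylome Analysis
Version: 0.1.0
Authors@R:
    person("panmethyl", "developers", email = "panmethyl@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing pan-methyllysine antibodies with
    lysine-oriented peptide library (K-OPL) microarrays and for analysing
    lysine methylation site catalogs from enrichment proteomics. Models the
    combinatorial K-OPL design, processes microarray fluorescence into
    normalized selectivity profiles, summarizes antibody sequence bias with a
    0-100 pan metric score, derives position-specific scoring matrices (PSSMs)
    and scans proteomes with them, calls methylation sites from peptide
    spectral match tables, quantifies novelty against a reference PTM catalog,
    computes log2 frequency-ratio sequence motifs, measures PTM crosstalk
    proximity, runs enrichment-efficiency QC and compartment enrichment
    statistics, and simulates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
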