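Package: coronashift
Title: Perturbation Profiling of the Nanoparticle Protein Corona
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of how the protein corona formed on
    nanoparticles in blood plasma responds to pH and temperature
    perturbation. Implements control-corrected Top3 label-free protein
    quantification from peptide tables, sigmoid (four-parameter logistic)
    profiling of corona abundance across condition series with critical-
    condition estimation and response-class assignment, an amino-acid-index
    dispersion-lessening enrichment statistic with permutation null and
    Benjamini-Hochberg correction, and a correlation-based minimum spanning
    tree of protein properties. Includes a synthetic-data generator that
    emulates peptide-level label-free quantification experiments with known
    ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    minpack.lm,
    seqinr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
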