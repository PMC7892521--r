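Package: cargselex
Title: SELEX-Seq Analysis of MADS-Domain CArG-Box Binding Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for SELEX-seq experiments probing the DNA
    binding specificity of MADS-domain transcription factors. Provides a
    synthetic SELEX simulator with a planted CArG-box binding model, probe
    demultiplexing and contamination QC, Markov background modelling of the
    initial library with cross-replicate order selection, k-mer counting and
    information-gain motif-length selection, relative affinity estimation
    with LOESS integration of selection rounds, affinity-weighted PWM
    discovery by expectation maximization, guided flank analysis, intra-motif
    dependence models with an intra-motif complexity measure, Jensen-Shannon
    motif comparison with difference-logo tables, and CArG-box / A-tract
    enumeration and enrichment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
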