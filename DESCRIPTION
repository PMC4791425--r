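Package: patchseqr
Title: Patch-Seq Integration of Single-Neuron Electrophysiology and
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for Patch-seq studies of neuronal maturation: extraction
    of action-potential and synaptic-current features from raw current- and
    voltage-clamp sweeps, a PCA-derived electrophysiological maturity index
    with not-detected-value imputation, signed weighted gene co-expression
    network construction with topological-overlap module detection and hub
    ranking, maturity-correlated gene clustering, candidate biomarker set
    intersection, and Fisher's-exact gene-set enrichment. Includes a
    synthetic-data generator (integrate-and-fire sweeps with stamped spike
    waveforms and a planted-program expression simulator) so the whole
    pipeline can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
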