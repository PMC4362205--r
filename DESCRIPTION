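Package: selexmotif
Title: Motif Discovery and Binding-Model Analysis for HT-SELEX Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis of high-throughput SELEX (HT-SELEX) experiments, in
    which a DNA-binding protein enriches ligands from a randomized
    oligonucleotide library over successive selection cycles.  Implements
    barcode demultiplexing, strand-merged counting of gapped subsequences,
    seed discovery as local maxima in gapped k-mer space under the Huddinge
    distance, background-corrected multinomial position weight matrix (PWM)
    estimation, pairwise base-dependency (dinucleotide preference) scoring,
    gapped-6-mer motif similarity with clustering and network export,
    protein-domain similarity scoring, barcode and sequence logo and heatmap
    rendering as SVG, and a synthetic SELEX simulator with known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    yaml,
    graphics,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
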