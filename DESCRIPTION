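Package: TXTLseq
Title: Multiplexed Transcriptional Profiling of Barcoded Regulatory
    Sequences in Cell-Free Expression Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies transcriptional activities of thousands of barcoded
    regulatory sequences from pooled cell-free (TXTL) or in vivo DNA-seq and
    RNA-seq experiments. Implements barcode-based read demultiplexing,
    RNA/DNA ratio activity estimation with Z-score normalization,
    transcription start site calling from mRNA 5'-end pileups by iterative
    one-dimensional clustering, sigma70 promoter feature extraction
    (-35/-10 position weight matrices, spacer penalty, 5' mRNA folding),
    cross-validated linear models of promoter strength, cross-species
    comparative analytics (correlation, PCA, hierarchical clustering,
    species-selective promoters, restriction-motif depletion), and a
    synthetic read simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    data.table,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'library-io.R'
    'read-processing.R'
    'quantify.R'
    'tss-calling.R'
    'motif-em.R'
    'folding.R'
    'sequence-features.R'
    'activity-model.R'
    'cross-species.R'
    'depletion.R'
    'simulate.R'
    'pipeline.R'
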