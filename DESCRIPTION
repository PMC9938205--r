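Package: usmag
Title: Abundance, Transcription and Co-Occurrence Analysis of Ultra-Small
    Prokaryote Genome Bins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing ultra-small prokaryote
    (Patescibacteria, Dependentiae, DPANN) communities recovered as
    metagenome-assembled genomes (MAGs) from groundwater. Implements
    single-copy-gene completeness and contamination, estimated genome size,
    cross-sample read-count normalization and enrichment-factor
    classification, modified-TPM metatranscriptome profiling, average
    amino-acid identity (AAI) novelty assessment against a family-level
    band, correlation screens against physicochemistry, Spearman
    co-occurrence networks with Ward-linkage cohort detection, and a
    seeded synthetic-community generator with ground-truth labels for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Transcriptomics, Normalization,
    Clustering, Network
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aai.R'
    'abundance.R'
    'correlation.R'
    'cooccurrence.R'
    'genome-metrics.R'
    'transcription.R'
    'synthetic-data.R'
    'pipeline.R'
    'usmag-package.R'
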