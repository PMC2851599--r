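Package: marker454
Title: Marker Discovery and Transcriptome Characterization from 454 EST Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of the marker-discovery and
    transcriptome-characterization computations used in 454 pyrosequencing EST
    projects on conifers: read quality filtering (mean-quality, long
    microsatellite runs, retroelement similarity), microsatellite (SSR)
    detection with primer design under stringent PCR constraints, pileup-based
    SNP calling with depth and alternate-allele-frequency thresholds,
    retrotransposon abundance screening by sequence similarity and annotation
    keywords, and summarization of tabular similarity-search annotation
    (unique accessions, taxonomy, gene-ontology namespaces, hit-versus-length
    logistic models, ortholog coverage, transcriptome coverage). A synthetic
    transcriptome and read simulator with full ground truth drives testing of
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
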