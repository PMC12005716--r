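Package: karyolg
Title: Ancestral Linkage Groups and Karyotype Evolution from Chromosome-Level Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers ancient linkage groups from ortholog co-occurrence across
    chromosome-level genome assemblies, reconstructs ancestral karyotypes at
    every node of a dated phylogeny by Fitch parsimony on chromosome
    co-localization characters, calls per-branch fusion, fission and
    duplication events, distinguishes duplication from fission using paralog
    evidence, scores how well fused chromosomes are mixed, and estimates
    inter-chromosomal translocation rates between genome pairs. Ships a
    genome-rearrangement simulator with ground-truth event ledgers so the
    whole pipeline is testable end-to-end, including a bundled scenario
    reproducing the karyotype evolutionary route of the chitons
    (Polyplacophora) from a 20-linkage-group molluscan ancestor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ape,
    igraph,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'formats-io.R'
    'mlg-infer.R'
    'karyo-ancestry.R'
    'karyolg-package.R'
    'orthology.R'
    'rates-occupancy.R'
    'sim-evolve.R'
    'scenarios.R'
    'pipeline.R'
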