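Package: novoseqkit
Title: Discovery and Characterization of Novel Sequences in Population-Scale
    Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale novel-sequence (NS) discovery from
    per-individual de novo assembled contigs: contig quality control and
    contaminant removal, CD-HIT-style greedy identity/coverage clustering with
    allele-frequency estimation, k-mer anchor alignment of cluster
    representatives against reference genomes and NS catalogs, repeat-class
    composition with a nonparametric permutation enrichment test, merging of
    per-individual insertion breakpoints by one-dimensional DBSCAN, genomic
    feature enrichment by region simulation and binomial testing, flag-filtered
    unmapped-read mapping statistics with allele-frequency depletion curves,
    and ancestral-deletion analysis against a chimpanzee-like reference with
    chimpanzee-reference-allele carrier frequencies. A fully specified
    synthetic-cohort generator with truth tables makes every stage testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, StructuralVariation, PopulationGenetics
RoxygenNote: 7.3.3
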