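Package: triallele
Title: Triallelic Genome Scans, Reciprocal Allele-Specific Expression and
    Spine-Length Association in Stickleback
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping loci that segregate as three ancient
    haplotype classes (marine plus two freshwater alleles) in threespine
    stickleback. Implements a sliding-window triallelic genome scan
    combining principal-component variance filters with a k-means
    cluster-gain statistic; reciprocal allele-specific-expression testing
    between two F1 crosses (pooled Fisher tests with depth downsampling,
    per-sample log-ratio Mann-Whitney tests, binomial allele tests, and
    permutation enrichment of candidate genes near scan regions);
    spine-length association statistics (phenotype residualization,
    quintile scans, per-marker F-tests, conditional tests, and percent
    variance explained); a three-taxon distance phylogeny with molecular
    clock dating of cloned alleles; and recombination-rate contrasts from
    genetic maps. Includes seeded generators of synthetic genotype
    landscapes, allele-specific count tables, and phenotypes with known
    planted structure, so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Genetics, SNP, GeneExpression, Transcriptomics, Phylogenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
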