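Package: wgspopgen
Title: Downstream Population-Genomic Analysis of Small Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the downstream population-genomic analysis of a small
    whole-genome-sequenced cohort against a panel of reference populations:
    population-resolved allele frequencies from multi-sample VCFs, rare and
    private functional-allele classification with Yates-corrected chi-square
    enrichment testing, frequency-differentiation outlier scans over GWAS
    SNP lists, per-population nucleotide diversity, population-structure
    analyses (subset-polymorphism filtering, LD pruning, PCA, neighbor-joining
    trees, Mantel tests of genetic versus geographic distance), and deletion
    callset algebra (reciprocal-overlap merging, novelty assessment,
    heterozygous-SNP in-silico validation). A seeded multi-population
    genotype and deletion simulator with planted ground truth drives every
    stage so the whole workflow is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
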