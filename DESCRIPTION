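Package: eggwas
Title: Exome-Guided GWAS Evaluation: LD Surveys, Power Simulation and
    Across-Breed Trait Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate exome-guided genome-wide association studies
    (EG-GWAS), in which variants discovered by whole-exome sequencing serve as
    tagSNPs, against conventional array-based GWAS. Provides a synthetic
    multi-breed genotype generator with tunable linkage-disequilibrium decay
    emulating within-breed canine LD, PLINK ped/map, VCF and BED input/output
    with a bi-allelic SNP retention rule, EM-based r2 estimation from unphased
    genotypes with the accompanying LD survey procedures, the Cochran-Armitage
    trend and allelic chi-squared association tests with Bonferroni and max-T
    permutation adjustment, a genotype-first power-simulation engine for
    monogenic recessive traits stratified by causal-variant location, SNP
    density, sample size and tag distance, estimation of the genome fraction
    within high-LD reach of an exome design, and across-breed mapping of
    breed-fixed traits with minimal-sample-size search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
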