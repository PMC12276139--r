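Package: pinepop
Title: Population Genomics and Diagnostic SNP Panel Design for Clonally
    Propagated Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing resequencing-derived SNP genotype matrices
    from germplasm collections of clonally propagated crops such as pineapple
    (Ananas comosus). Implements depth-assisted recalibration of missing
    genotypes, high-quality SNP filtering (minor allele frequency,
    missingness, biallelic), per-accession heterozygosity, per-locus
    inbreeding coefficients (Fis), windowed Tajima's D, ancestry-threshold
    population assignment from ADMIXTURE-style Q matrices, two diagnostic
    SNP panel design workflows (cultivar-diagnostic and homozygous pedigree
    panels), classical multidimensional scaling of panel genotypes, and a
    forward-in-time simulator of partially clonal populations for validating
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
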