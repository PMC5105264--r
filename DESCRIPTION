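Package: genoconcord
Title: Concordance Analysis of SNP-Array Genotypes from Technical Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the reproducibility of SNP-array genotype
    calls from technical replicates, within a platform or across vendors
    (e.g. Illumina BeadChip versus Affymetrix Axiom). Reads genotype call
    sets from PLINK text or long call tables, intersects samples and SNPs,
    reconciles A/B allele coding across strand and labelling conventions,
    applies call-rate exclusions with full accounting, and computes three
    reproducibility statistics (allele-count correlation, genotype
    concordance, allele concordance) per animal, per SNP and overall,
    together with genotype contingency tables and summaries stratified by
    minor allele frequency, genotype quality score and Axiom SNP category.
    Includes a dual-platform genotype simulator with known truth, an
    allele-level error model and quality scores coupled to call
    correctness, plus exact-count fixture builders for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
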