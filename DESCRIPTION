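Package: rohline
Title: Chromosome-Specific Inbreeding from Runs of Homozygosity in Closed Livestock Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inbreeding depression at chromosome resolution in
    closed livestock populations. Reads PLINK genotype files, applies standard
    SNP and phenotype quality control, computes pedigree inbreeding coefficients
    with Henderson's tabular method, detects runs of homozygosity (ROH) with the
    sliding-window method, partitions the genomic inbreeding coefficient FROH by
    chromosome, regresses corrected phenotypes on inbreeding predictors, and
    assesses phenotype prediction accuracy with repeated 80/20 cross-validation,
    chromosome selection and Tukey comparisons. A gene-dropping simulator
    generates closed-line populations with known per-chromosome identity by
    descent for validation and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
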