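Package: hlacheckr
Title: Plausibility Checking of HLA Allele Assignments from SNP Genotype
    Posteriors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how compatible an attributed HLA allele pair is with an
    individual's SNP genotype posterior probabilities in the gene's exonic
    region, by exhaustively comparing the attributed pair against every
    allele pair defined in an HLA allele nucleotide table.  Provides readers
    for IPD-IMGT/HLA-style cDNA nucleotide alignments, IMPUTE2 GEN/SAMPLE
    genotype posteriors, marker maps and HLA assignment tables; a
    randomization-based (shuffled-assignment) cutoff calibration for
    flagging implausible assignments; per-allele imputation accuracy
    evaluation before and after filtering; and a fully seeded synthetic
    cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
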