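Package: casekit
Title: Combined Allele-Specific Expression with TAD-Constrained Candidate
    Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects allelic imbalance in transcribed reporter variants from
    allele-specific RNA-seq read counts across heterozygous samples.  Each
    sample contributes an exact two-sided binomial test against a 0.5
    reference-allele fraction; signed probit deviates are combined into a
    coverage-weighted Stouffer Z-score whose significance is assessed against
    a sign-flip permutation null, with an additional Gaussian-tail p-value
    and Benjamini-Hochberg adjustment across reporters.  Candidate regulatory
    variants in the reporter's topologically associating domain (TAD) are
    assessed by a genotype-subgroup Z comparison (heterozygous-candidate
    versus all-sample Z, with a non-significant homozygous subgroup), and
    annotated with dosage LD r-squared.  Also provides closed-form assay
    quantifications (CRISPR editing efficiency from qPCR, 2^-ddCt relative
    expression, insulin-secretion normalization, dual-luciferase and
    growth-curve normalization), JASPAR position-weight-matrix relative
    scoring of variant alleles, and a synthetic-data generator (phased
    haplotypes under Hardy-Weinberg with block LD, overdispersed coverage,
    cis-acting allelic skew) that makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
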