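Package: sweepscan
Title: Selective-Sweep Scanning and Candidate-Variant Follow-Up for
    Two-Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based detection of selective sweeps from biallelic SNP
    genotypes of two contrasted populations (for example wild versus
    domestic, or broody versus non-broody birds). Computes per-site
    Weir-Cockerham F_ST and nucleotide diversity (theta-pi), aggregates
    them over sliding windows, calls divergent regions as joint top-quantile
    outliers of F_ST and the pi ratio, merges regions, assigns genes, and
    ranks candidate genes. A follow-up stage interrogates candidate SNPs
    inside selected regions: exact tests of allele-frequency differentiation,
    genotype-differentiation flags, genotype-phenotype segregation scoring,
    and composite linkage-disequilibrium r-squared with complete-LD grouping.
    Includes a Balding-Nichols two-population genotype simulator with
    implanted sweeps and phenotype-linked causal SNPs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
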