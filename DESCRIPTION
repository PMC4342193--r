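Package: popgenkit
Title: Bit-Parallel Genotype Kernels, Exact Tests and Relatedness for
    Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for large genotype matrices stored in the packed 2-bit
    PLINK 1 binary format: file input/output (.bed/.bim/.fam, lossy VCF
    import), word-level identity-by-state and genotype-correlation kernels
    built on bit population counts, early-termination exact tests
    (Hardy-Weinberg, Fisher 2x2 and 2x3, each with mid-p modes), genomic
    relationship matrices via partial-sum lookup tables, linkage
    disequilibrium pruning and D-prime confidence-interval haplotype block
    estimation, max(T) permutation association testing, a deterministic
    synthetic-data generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
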