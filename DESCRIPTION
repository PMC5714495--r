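Package: divscan
Title: Windowed Genome Scans of Differentiation Between Hybridizing Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scan analysis for pairs of hybridizing species sampled in
    allopatry and sympatry. Partitions biallelic SNPs into shared, private and
    fixed categories under per-population depth filters, computes nucleotide
    diversity, Watterson's theta, Tajima's D, Hudson FST, DXY and composite LD
    r2 in non-overlapping 10-kb windows, detects clustered differentiation
    islands from Z-standardized FST with a binomial clustering test, and
    classifies coding effects (synonymous, nonsynonymous, splice) of fixed
    differences from GFF3 gene models. Includes a Balding-Nichols
    divergence-with-admixture simulator that emits VCF/BED/GFF3/FASTA fixtures
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
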