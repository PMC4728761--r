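Package: asbscan
Title: Allele-Specific Binding SNP Discovery from ChIP-Seq Allelic Imbalance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies heterozygous SNPs showing allele-specific
    transcription factor binding (AS-SNPs) from ChIP-seq read data over a
    diploid sample. The pipeline builds a sample-specific alternative
    genome by substituting alternative alleles into the reference, counts
    reads supporting each allele at heterozygous sites, scores allelic
    imbalance with an exact two-sided binomial test corrected by the
    Benjamini-Hochberg procedure, removes candidates in assembly gaps,
    blacklisted regions and copy-number variants, annotates survivors
    with population allele frequencies, and links them to GWAS catalog
    SNPs through linkage-disequilibrium proxies computed on a phased
    haplotype panel. A synthetic-data generator with a full ground-truth
    table makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
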