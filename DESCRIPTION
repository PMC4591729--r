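Package: ssrpoly
Title: Microsatellite Length-Polymorphism Detection from Spanning Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotypes perfect microsatellites (simple sequence repeats, SSRs)
    from short-read alignments and flags length polymorphisms across
    genotypes.  Reads a MISA-like catalog of perfect repeat loci, selects
    reads that span each locus with non-repeat flanking sequence on both
    sides, counts repeat units in read space so that insertion and deletion
    alleles are measured directly, and calls homozygous and heterozygous
    alleles under user-defined read-support thresholds.  A read simulator
    builds references with planted repeats and emits pre-aligned reads with
    correct CIGAR strings for non-reference alleles, so the whole pipeline is
    testable without an external aligner.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    optparse,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
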