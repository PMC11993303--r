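Package: covstats
Title: Coverage Statistics for Contigs and Genomes from Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calculates per-contig and per-genome read-coverage statistics
    from coordinate-sorted SAM/BAM alignments using Mosdepth-style delta
    arrays, whose prefix sums yield per-base depth. Supports alignment
    filtering by percent identity, aligned length and fraction of the read
    aligned (per read or jointly per pair), the metric suite used in
    metagenomic binning and community profiling (mean, trimmed mean,
    variance, MetaBAT-adjusted depth, covered fraction/bases, read counts,
    reads per base, RPKM, TPM), per-genome aggregation with a minimum
    covered-fraction presence gate, and relative-abundance estimation scaled
    by the aligned-read fraction. Includes a seeded synthetic fixture
    generator with exact per-base depth truth and an independent brute-force
    pileup oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rsamtools,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
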