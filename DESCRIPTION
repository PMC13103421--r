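Package: wgbsfuse
Title: Targeted Gene Fusion Detection from Whole-Genome Bisulfite
    Sequencing Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects known gene fusions between two target gene loci from
    whole-genome bisulfite sequencing (WGBS) alignments.  Classifies
    read-pair evidence into split read pairs (a chimeric read whose
    supplementary alignment, recorded in the SA tag, reaches the partner
    gene) and discordant read pairs (mates mapping to the two different
    target genes), localizes fusion breakpoints from soft-clip boundaries
    of primary and supplementary CIGAR strings, and aggregates unique
    breakpoint coordinate pairs with their support.  Includes coverage
    profiling around breakpoints, seeded read-pair downsampling,
    genome-wide chimeric-pair background scans, bisulfite conversion-rate
    quality control, replicate concordance, and probit-regression
    estimation of the limit of detection from dilution-series detection
    outcomes.  A built-in simulator generates toy two-gene references with
    planted fusion junctions, directional bisulfite-converted paired-end
    reads at configurable dilution, and oracle alignments with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    digest,
    jsonlite,
    stats,
    graphics,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
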