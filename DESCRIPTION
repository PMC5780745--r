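Package: phasr
Title: Discovery of Phased Secondary siRNA (phasiRNA) Loci from Small RNA
    and Degradome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects PHAS loci and their phased secondary small interfering
    RNAs (phasiRNAs) on a transcriptome from small RNA sequencing reads.
    Candidate windows of ten phasiRNA cycles (21 or 24 nt) are scored with an
    upper-tail hypergeometric phasing P-value and a log phase score,
    significant windows are extended, merged and filtered by
    Benjamini-Hochberg corrected P-value and phase score, and the phased
    reads of each locus are reported as serially named phasiRNAs.  Degradome
    (PARE) reads are used to identify miRNA triggers of the loci and targets
    of the phasiRNAs through an ungapped complementarity scan with the
    valid-read criterion (degradome 5' ends opposite small RNA positions
    9-11).  A seeded simulator generates transcriptomes with implanted
    phased read stacks, trigger miRNAs and degradome cleavage peaks so the
    whole pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
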