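Package: readmerge
Title: Bayesian Adaptor Trimming and Merging of Overlapping Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint adaptor trimming and merging of overlapping paired-end
    (and single-end) Illumina sequencing reads by Bayesian maximum a
    posteriori inference over the original molecule length. For every
    candidate fragment length the likelihood of the observed bases and
    quality scores is computed from an explicit error model (adaptor
    match terms, overlap terms marginalised over the unknown template
    base, and a no-overlap hypothesis), combined with a uniform or
    log-normal fragment-length prior, and the best-supported length is
    selected subject to a likelihood-ratio ambiguity guard. Overlapping
    bases are collapsed into consensus calls with PHRED-scaled posterior
    error probabilities. Includes a log-normal prior fitted from observed
    fragment lengths, FASTQ and unaligned BAM input/output, a read-pair
    simulator with configurable substitution error profiles for
    validation, and a command-line interface. Designed for libraries in
    which molecules are shorter than the read length, as is typical for
    ancient or forensic DNA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rsamtools,
    IRanges,
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
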