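Package: spaceracq
Title: CRISPR Spacer Acquisition Amplicon Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-throughput amplicon sequencing of
    expanded CRISPR arrays from Escherichia coli type I-E spacer
    acquisition experiments. Provides repeat-anchored spacer extraction
    from FASTQ reads (mean-quality filtering, two-repeat detection with
    a mismatch budget, fixed-length inter-repeat insert extraction),
    exact mapping of spacers onto a circular donor plasmid on both
    strands, PAM extraction and strand classification relative to a
    priming protospacer, reclassification of derived (shifted and
    inverted) spacers to their AAG-PAM parent protospacers, and
    per-sample adaptation statistics (PAM preference, strand bias,
    derived-spacer fraction, per-protospacer usage and its correlation
    between samples). A synthetic-data generator simulates primed and
    naive acquisition with configurable PAM recognition bias, strand
    bias, derived-spacer emission and protospacer hotspot weights, and
    renders expanded-array amplicon reads with ground truth. A designer
    builds terminator-based unit-sized crRNA expression cassettes
    (repeat hairpin plus U-tract intrinsic terminator) for arbitrary
    PAM-flanked targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
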