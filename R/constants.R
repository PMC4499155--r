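#' Sequence constants used throughout the package
#'
#' `crispr_repeat_ecoli` is the 29-nt consensus repeat of the *E. coli* K-12
#' type I-E CRISPR arrays. Its internal palindrome forms the hairpin that,
#' followed by a U-tract, acts as an intrinsic transcription terminator in
#' the unit-sized crRNA constructs built by [build_construct()].
#'
#' `promoter_t7a1` and `promoter_trp` are the canonical bacterial promoter
#' sequences (up to the transcription start site, +1 excluded) offered by
#' [design_config()]. The designer only concatenates them; it never predicts
#' promoter strength.
#'
#' @format Character scalars (DNA, 5'->3').
#' @name seq_constants
NULL

#' @rdname seq_constants
#' @export
crispr_repeat_ecoli <- "GTGTTCCCCGCGCCAGCGGGGATAAACCG"

#' @rdname seq_constants
#' @export
promoter_t7a1 <- "AAAAAGAGTATTGACTTAAAGTCTAACCTATAGGATACTTACAGCC"

#' @rdname seq_constants
#' @export
promoter_trp <- "AAATGAGCTGTTGACAATTAATCATCGAACTAGTTAACTAGTACGCAAG"

# Fixed leader/tail context for rendered amplicons. The leader begins with the
# forward primer annealing site at the leader-proximal end of the array; the
# tail stands in for the first pre-existing spacer's downstream context ending
# in the reverse primer site. Both are fixed so rendered reads are
# reproducible, and were chosen free of repeat-like 29-mers (<= 2 mismatches).
default_leader <- "AAGGTTGGTGGGTTGTTTTTATGGCTTATAAACCTTACAGTTCCAGAACTTC"
default_tail <- "ACCTTGGCAAACCCATCAAGACGCCTTCGTTAATGACG"
default_preexisting_spacer <- "GCGGGATCGTCACCCTCAGCAGCGAAAGACAGT"
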