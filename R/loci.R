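# Stranded-locus arithmetic on circular references.
#
# A protospacer locus is (start0, strand): start0 is the 0-based coordinate,
# on the plus-strand coordinate system, of the 5' end of the protospacer as
# read on its own strand. A plus-strand locus of length L occupies
# [start0, start0 + L); a minus-strand locus occupies [start0 - L + 1,
# start0 + 1) and is read right-to-left as the reverse complement.

mod_pos <- function(i, n) ((i %% n) + n) %% n

# 5'-end coordinate shifted by k along the locus' own strand (k > 0 moves
# downstream, i.e. away from the PAM).
shift_by <- function(start0, strand, k, n) {
  ifelse(strand == "+", mod_pos(start0 + k, n), mod_pos(start0 - k, n))
}

# Protospacer sequence read 5'->3' on its own strand.
proto_seq <- function(ref, start0, strand, len) {
  ref <- as_circ_seq(ref)
  n <- ref$length
  out <- character(length(start0))
  for (i in seq_along(start0)) {
    if (strand[i] == "+") {
      out[i] <- circ_slice(ref, start0[i], len)
    } else {
      out[i] <- revcomp(circ_slice(ref, mod_pos(start0[i] - len + 1L, n), len))
    }
  }
  out
}

# Trinucleotide immediately 5'-adjacent to the locus on its own strand.
pam_at <- function(ref, start0, strand, pam_len = 3L) {
  ref <- as_circ_seq(ref)
  n <- ref$length
  out <- character(length(start0))
  for (i in seq_along(start0)) {
    if (strand[i] == "+") {
      out[i] <- circ_slice(ref, mod_pos(start0[i] - pam_len, n), pam_len)
    } else {
      out[i] <- revcomp(circ_slice(ref, mod_pos(start0[i] + 1L, n), pam_len))
    }
  }
  out
}

# All loci on both strands whose PAM equals `pam` (default AAG). Works on
# the doubled sequence so PAM/protospacer pairs wrapping the origin are
# included for circular references.
pam_loci <- function(ref, pam = "AAG") {
  ref <- as_circ_seq(ref)
  n <- ref$length
  subject <- if (ref$circular) paste0(ref$seq, substr(ref$seq, 1L, nchar(pam))) else ref$seq
  plus_pam <- scan_hamming(subject, pam, 0L)
  plus_pam <- plus_pam[plus_pam < n]
  minus_pat <- revcomp(pam)
  minus_pam <- scan_hamming(subject, minus_pat, 0L)
  minus_pam <- minus_pam[minus_pam < n]
  bind_rows(
    tibble(start0 = mod_pos(plus_pam + nchar(pam), n), strand = "+"),
    tibble(start0 = mod_pos(minus_pam - 1L, n), strand = "-")
  )
}
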