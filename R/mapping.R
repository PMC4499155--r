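#' Map a spacer exactly onto a plasmid, both strands
#'
#' Finds every exact occurrence of `spacer` on both strands of the
#' reference, including matches wrapping the origin of a circular
#' reference (search runs on the doubled sequence). A hit's `start0` is the
#' 0-based coordinate, in plus-strand coordinates, of the match's 5' end as
#' read on the hit strand; a minus-strand match therefore occupies
#' `[start0 - L + 1, start0 + 1)`.
#'
#' @param spacer DNA string (no `N`s map).
#' @param plasmid A [circ_seq()] or [make_plasmid()] reference.
#' @return Tibble with columns `start0`, `strand`, `pam` (trinucleotide 5'
#'   of the match on its strand) and `pam_is_aag`.
#' @export
map_exact <- function(spacer, plasmid) {
  plasmid <- as_circ_seq(plasmid)
  n <- plasmid$length
  L <- nchar(spacer)
  if (L > n) abort("map_exact: spacer longer than reference")
  subject <- if (plasmid$circular) paste0(plasmid$seq, substr(plasmid$seq, 1L, L - 1L)) else plasmid$seq
  plus <- scan_hamming(subject, spacer, 0L)
  plus <- plus[plus < n | !plasmid$circular]
  minus_raw <- scan_hamming(subject, revcomp(spacer), 0L)
  minus_raw <- minus_raw[minus_raw < n | !plasmid$circular]
  hits <- bind_rows(
    tibble(start0 = plus, strand = "+"),
    tibble(start0 = mod_pos(minus_raw + L - 1L, n), strand = "-")
  )
  if (nrow(hits) == 0L) {
    return(tibble(
      start0 = integer(), strand = character(),
      pam = character(), pam_is_aag = logical()
    ))
  }
  hits <- arrange(hits, .data$start0, .data$strand)
  hits$pam <- pam_at(plasmid, hits$start0, hits$strand)
  hits$pam_is_aag <- hits$pam == "AAG"
  hits
}

#' PAM of a mapped hit
#'
#' The trinucleotide immediately 5'-adjacent to a protospacer on the hit
#' strand, wrapping circularly.
#'
#' @param plasmid Reference sequence.
#' @param start0 0-based 5'-end coordinate(s) of the hit(s).
#' @param strand `"+"` or `"-"` per hit.
#' @return Character vector of trinucleotides.
#' @export
get_pam <- function(plasmid, start0, strand) {
  pam_at(as_circ_seq(plasmid), start0, strand)
}

#' Strand class of a hit relative to the priming protospacer
#'
#' During priming, the strand bearing the priming protospacer is displaced
#' in the R-loop and is the preferred donor of new spacers. A hit is
#' `"displaced"` iff its strand equals the priming protospacer's strand,
#' else `"target"`.
#'
#' @param strand Character vector of hit strands.
#' @param priming_strand The priming protospacer's strand.
#' @return Character vector over `{"displaced", "target"}`.
#' @export
assign_strand_class <- function(strand, priming_strand = "+") {
  ifelse(strand == priming_strand, "displaced", "target")
}

# Classify one spacer sequence against the plasmid. Decision cascade:
#   (a) no exact hit in either orientation        -> unmapped
#   (b) some hit has an AAG PAM                   -> direct_aag
#   (c) else, reverse complement hits an AAG PAM  -> inverted
#   (d) else, AAG PAM at offset k (|k| <= window,
#       same strand); minimal |k|, tie -> k < 0   -> shifted
#   (e) else                                      -> non_aag
# Inversion is checked before shift because an inverted spacer preserves
# the exact protospacer window, the stronger evidence of origin.
classify_one <- function(spacer, plasmid, shift_window, check_inversion_first = TRUE) {
  n <- plasmid$length
  out <- list(
    mapped = FALSE, start0 = NA_integer_, strand = NA_character_,
    pam = NA_character_, label = "unmapped", shift_k = NA_integer_,
    parent_start0 = NA_integer_, parent_strand = NA_character_, ambiguous = FALSE
  )
  hits <- map_exact(spacer, plasmid)
  if (nrow(hits) == 0L) return(out)
  out$mapped <- TRUE
  out$ambiguous <- nrow(hits) > 1L
  aag <- hits[hits$pam_is_aag, , drop = FALSE]
  if (nrow(aag) > 0L) {
    out$label <- "direct_aag"
    out$start0 <- aag$start0[1]
    out$strand <- aag$strand[1]
    out$pam <- aag$pam[1]
    out$parent_start0 <- aag$start0[1]
    out$parent_strand <- aag$strand[1]
    return(out)
  }
  out$start0 <- hits$start0[1]
  out$strand <- hits$strand[1]
  out$pam <- hits$pam[1]

  try_inverted <- function(out) {
    rc <- map_exact(revcomp(spacer), plasmid)
    rc_aag <- rc[rc$pam_is_aag, , drop = FALSE]
    if (nrow(rc_aag) == 0L) return(NULL)
    out$label <- "inverted"
    out$parent_start0 <- rc_aag$start0[1]
    out$parent_strand <- rc_aag$strand[1]
    out
  }
  try_shifted <- function(out) {
    for (m in seq_len(shift_window)) {
      for (j in c(m, -m)) { # j = +m first: shift_k = -j, ties favour upstream
        for (h in seq_len(nrow(hits))) {
          cand <- shift_by(hits$start0[h], hits$strand[h], j, n)
          if (pam_at(plasmid, cand, hits$strand[h]) == "AAG") {
            out$label <- "shifted"
            out$shift_k <- -j
            out$start0 <- hits$start0[h]
            out$strand <- hits$strand[h]
            out$pam <- hits$pam[h]
            out$parent_start0 <- cand
            out$parent_strand <- hits$strand[h]
            return(out)
          }
        }
      }
    }
    NULL
  }
  checks <- if (check_inversion_first) list(try_inverted, try_shifted) else list(try_shifted, try_inverted)
  for (f in checks) {
    res <- f(out)
    if (!is.null(res)) return(res)
  }
  out$label <- "non_aag"
  out$parent_start0 <- out$start0
  out$parent_strand <- out$strand
  out
}

#' Classify called spacers against the donor plasmid
#'
#' Maps each spacer exactly (both strands, circular wrap included), assigns
#' a derived class and a strand class. Labels: `direct_aag` (a hit with an
#' AAG PAM), `inverted` (no AAG hit, but the reverse complement hits an
#' AAG-PAM locus), `shifted` (an AAG PAM sits at offset `k`,
#' `1 <= |k| <= shift_window`, on the hit strand; minimal `|k|` wins, ties
#' resolved to upstream/negative `k`), `non_aag` (mapped, no AAG within
#' reach) and `unmapped`. Spacers mapping to several loci carry an
#' `ambiguous` flag and are classified by the most favourable label in the
#' order direct > inverted > shifted > non-AAG.
#'
#' For derived spacers the parent locus (`parent_start0`, `parent_strand`)
#' is the AAG protospacer of origin; downstream statistics credit usage and
#' strand to the parent, so an inverted spacer counts toward the strand its
#' protospacer was excised from, not the strand its sequence matches.
#' `strand_class` is `"displaced"` iff the source strand equals the priming
#' protospacer's strand.
#'
#' Classification depends only on the spacer sequence, so it is computed
#' once per distinct spacer and joined back; the result is deterministic
#' and invariant to input order.
#'
#' @param calls A `spacer_calls` object or a calls tibble with columns
#'   `read_id` and `spacer`.
#' @param plasmid A [make_plasmid()] reference (priming annotation needed
#'   for `strand_class`).
#' @param shift_window Maximum `|k|` considered for shifted spacers.
#' @param check_inversion_first If `FALSE`, the shift test runs before the
#'   inversion test in the cascade.
#' @return The calls tibble with columns `mapped`, `start0`, `start1`
#'   (1-based inclusive 5' end), `strand`, `pam`, `label`, `shift_k`,
#'   `parent_start0`, `parent_strand`, `ambiguous`, `strand_class`.
#' @export
classify_spacers <- function(calls, plasmid, shift_window = 5L,
                             check_inversion_first = TRUE) {
  if (inherits(calls, "spacer_calls")) calls <- calls$calls
  stopifnot(all(c("read_id", "spacer") %in% names(calls)))
  if (nrow(calls) == 0L) {
    empty <- as_tibble(classify_one("A", circ_seq("ACGT"), 1L))[0, ]
    empty$spacer <- character(0)
    out <- dplyr::bind_cols(calls, empty[, setdiff(names(empty), names(calls))])
    out$strand_class <- character(0)
    out$start1 <- integer(0)
    return(out)
  }
  uniq <- unique(calls$spacer)
  cls <- purrr::map(uniq, function(sp) {
    as_tibble(classify_one(sp, plasmid, shift_window, check_inversion_first))
  })
  cls <- bind_rows(cls)
  cls$spacer <- uniq
  out <- left_join(calls, cls, by = "spacer")
  priming <- plasmid$priming_strand %||% "+"
  source_strand <- ifelse(out$label == "inverted", out$parent_strand, out$strand)
  out$strand_class <- ifelse(
    out$mapped, assign_strand_class(source_strand, priming), NA_character_
  )
  out$start1 <- out$start0 + 1L
  dplyr::relocate(out, "start1", .after = "start0")
}
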