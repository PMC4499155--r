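#' Configuration for terminator-based crRNA expression cassettes
#'
#' A unit-sized crRNA cassette is `promoter + 5' handle + spacer + repeat +
#' (T)n`. Transcription starts at the first base of the 5' handle (the +1
#' of the promoter), and the palindromic repeat followed by the T-tract
#' mimics a factor-independent (intrinsic) transcription terminator, so the
#' transcript is released without any processing factor. The mature crRNA
#' species is `5' handle + spacer + 3' handle` where the handles are the
#' last `handle5_len` and first `handle3_len` nt of the repeat; with the
#' defaults (7 + 33 + 21) the mature species is 61 nt.
#'
#' @param repeat_seq Repeat sequence (default: 29-nt *E. coli* I-E repeat).
#' @param handle5_len Length of the repeat-derived 5' handle (default 7).
#' @param spacer_len Spacer length (default 33).
#' @param handle3_len Length of the repeat-derived 3' handle retained in
#'   the mature species (default 21).
#' @param u_tract_len Number of T residues after the repeat (default 8; at
#'   least 4 for a functional terminator).
#' @param promoter `"T7A1"`, `"trp"`, or a custom DNA string.
#' @return A `design_config` list.
#' @export
design_config <- function(repeat_seq = crispr_repeat_ecoli,
                          handle5_len = 7L, spacer_len = 33L,
                          handle3_len = 21L, u_tract_len = 8L,
                          promoter = c("T7A1", "trp")) {
  if (is.character(promoter) && length(promoter) == 1L && !promoter %in% c("T7A1", "trp")) {
    promoter_name <- "custom"
    promoter_seq <- toupper(promoter)
  } else {
    promoter_name <- match.arg(promoter)
    promoter_seq <- switch(promoter_name, T7A1 = promoter_t7a1, trp = promoter_trp)
  }
  if (u_tract_len < 4L) abort("design_config: u_tract_len must be >= 4 for a functional terminator")
  if (handle5_len > nchar(repeat_seq) || handle3_len > nchar(repeat_seq)) {
    abort("design_config: handles cannot exceed the repeat length")
  }
  structure(
    list(
      repeat_seq = toupper(repeat_seq), handle5_len = as.integer(handle5_len),
      spacer_len = as.integer(spacer_len), handle3_len = as.integer(handle3_len),
      u_tract_len = as.integer(u_tract_len),
      promoter_name = promoter_name, promoter_seq = promoter_seq,
      mature_len = as.integer(handle5_len + spacer_len + handle3_len)
    ),
    class = "design_config"
  )
}

#' Find PAM-flanked candidate targets in a genome
#'
#' Scans both strands for every window of `spacer_len` nt whose immediately
#' 5'-adjacent trinucleotide equals `pam`. Coordinates are reported 1-based
#' inclusive (`start1`..`end1`, ascending on the plus-strand axis) next to
#' the 0-based 5'-end coordinate used internally. On a linear genome only
#' windows whose PAM and spacer fit entirely within the sequence are
#' reported; on a circular genome matches may wrap the origin.
#'
#' @param genome A [circ_seq()] or DNA string (`circular` flag respected;
#'   plain strings are treated as linear).
#' @param pam PAM trinucleotide (default `"AAG"`).
#' @param spacer_len Candidate spacer length.
#' @return Tibble with `genome`, `start0`, `start1`, `end1`, `strand`,
#'   `pam`, `spacer`.
#' @export
find_targets <- function(genome, pam = "AAG", spacer_len = 33L) {
  if (is.character(genome)) genome <- circ_seq(genome, circular = FALSE)
  n <- genome$length
  if (n < spacer_len + nchar(pam)) abort("find_targets: genome shorter than spacer + PAM")
  plen <- nchar(pam)
  subject <- if (genome$circular) paste0(genome$seq, substr(genome$seq, 1L, spacer_len + plen)) else genome$seq
  # plus strand: PAM at p -> spacer 5' end at p + plen
  pp <- scan_hamming(subject, toupper(pam), 0L)
  pp <- pp[pp < n | !genome$circular]
  plus0 <- pp + plen
  if (!genome$circular) plus0 <- plus0[plus0 + spacer_len <= n]
  plus0 <- mod_pos(plus0, n)
  # minus strand: revcomp(pam) at plus positions [c, c+plen); spacer 5' end at c-1
  mp <- scan_hamming(subject, revcomp(toupper(pam)), 0L)
  mp <- mp[mp < n | !genome$circular]
  minus0 <- mp - 1L
  if (!genome$circular) minus0 <- minus0[minus0 - spacer_len + 1L >= 0L]
  minus0 <- mod_pos(minus0, n)
  out <- bind_rows(
    tibble(start0 = as.integer(plus0), strand = "+"),
    tibble(start0 = as.integer(minus0), strand = "-")
  )
  if (nrow(out) == 0L) {
    return(tibble(
      genome = character(), start0 = integer(), start1 = integer(),
      end1 = integer(), strand = character(), pam = character(), spacer = character()
    ))
  }
  out <- arrange(out, .data$start0, .data$strand)
  out$spacer <- proto_seq(genome, out$start0, out$strand, spacer_len)
  tibble(
    genome = genome$name,
    start0 = out$start0,
    start1 = ifelse(out$strand == "+", out$start0 + 1L, out$start0 - spacer_len + 2L),
    end1 = ifelse(out$strand == "+", out$start0 + spacer_len, out$start0 + 1L),
    strand = out$strand,
    pam = toupper(pam),
    spacer = out$spacer
  )
}

#' Build a terminator-based unit-sized crRNA construct
#'
#' Assembles the DNA cassette `promoter + handle5 + spacer + repeat +
#' T(u_tract_len)` for one candidate target, and derives the transcript and
#' mature crRNA species. The transcript runs from the cassette's +1 (first
#' base of the 5' handle) through the repeat into the U-tract; because
#' intrinsic terminators typically release within the U-tract, the
#' terminated length is reported as a range (4 to `u_tract_len` uridines).
#' The mature species is `handle5 + spacer + handle3`.
#'
#' @param target One-row tibble from [find_targets()], or a plain spacer
#'   string.
#' @param config A [design_config()].
#' @return A `crrna_construct` list with fields `promoter_name`,
#'   `dna_cassette`, `transcript` (RNA, full U-tract), `mature_crrna`
#'   (RNA), `transcript_len_range` and the target annotation.
#' @export
build_construct <- function(target, config = design_config()) {
  if (is.character(target)) {
    target <- tibble(
      genome = NA_character_, start0 = NA_integer_, start1 = NA_integer_,
      end1 = NA_integer_, strand = NA_character_, pam = NA_character_,
      spacer = toupper(target)
    )
  }
  stopifnot(nrow(target) == 1L)
  spacer <- target$spacer
  if (nchar(spacer) != config$spacer_len) {
    abort(paste0(
      "build_construct: spacer length ", nchar(spacer),
      " does not match config spacer_len ", config$spacer_len
    ))
  }
  rep <- config$repeat_seq
  handle5 <- substr(rep, nchar(rep) - config$handle5_len + 1L, nchar(rep))
  handle3 <- substr(rep, 1L, config$handle3_len)
  u_tract <- strrep("T", config$u_tract_len)
  transcribed <- paste0(handle5, spacer, rep, u_tract)
  body_len <- nchar(handle5) + nchar(spacer) + nchar(rep)
  structure(
    list(
      promoter_name = config$promoter_name,
      dna_cassette = paste0(config$promoter_seq, transcribed),
      transcript = chartr("T", "U", transcribed),
      mature_crrna = chartr("T", "U", paste0(handle5, spacer, handle3)),
      transcript_len_range = c(body_len + 4L, body_len + config$u_tract_len),
      target = target,
      config = config
    ),
    class = "crrna_construct"
  )
}

#' @export
print.crrna_construct <- function(x, ...) {
  cat("<crrna_construct> promoter ", x$promoter_name, "\n", sep = "")
  if (!is.na(x$target$genome)) {
    cat(
      "  target: ", x$target$genome, " ", x$target$start1, "-", x$target$end1,
      " (", x$target$strand, "), PAM ", x$target$pam, "\n",
      sep = ""
    )
  }
  cat("  mature crRNA (", nchar(x$mature_crrna), " nt): ", x$mature_crrna, "\n", sep = "")
  cat(
    "  terminated transcript: ", x$transcript_len_range[1], "-",
    x$transcript_len_range[2], " nt\n",
    sep = ""
  )
  invisible(x)
}

#' Structural check of the intrinsic terminator
#'
#' Finds the longest self-complementary stem the repeat region can form
#' (complementary-extension scan over all pairings with a loop of at least
#' 3 nt; no thermodynamics) and counts the U-tract. The terminator passes
#' iff the stem is at least 4 bp and the U-tract at least 4 U.
#'
#' @param construct A `crrna_construct`, or a repeat DNA string (then
#'   `u_tract_len` supplies the tract length).
#' @param u_tract_len U-tract length when `construct` is a plain repeat.
#' @return One-row tibble: `stem_len`, `palindromicity`, `u_tract_len`,
#'   `pass`.
#' @export
check_terminator <- function(construct, u_tract_len = NULL) {
  if (inherits(construct, "crrna_construct")) {
    rep <- construct$config$repeat_seq
    u_len <- construct$config$u_tract_len
  } else {
    rep <- toupper(construct)
    u_len <- u_tract_len %||% 0L
  }
  stem <- longest_stem(rep)
  tibble(
    stem_len = stem,
    palindromicity = 2 * stem / nchar(rep),
    u_tract_len = as.integer(u_len),
    pass = stem >= 4L && u_len >= 4L
  )
}

# Longest stem: max t such that positions (i..i+t-1) pair with
# (j-t+1..j) in reverse complement, with an unpaired loop of >= 3 nt.
longest_stem <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(ch)
  best <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(n, i + 1L)) {
      t <- 0L
      while (i + t <= j - t - min_loop - 1L &&
        comp[[ch[i + t]]] == ch[j - t]) {
        t <- t + 1L
      }
      if (t > best) best <- t
    }
  }
  best
}

#' Design crRNA constructs for every PAM-flanked target in a genome
#'
#' Pipeline convenience: [find_targets()] then [build_construct()] per
#' candidate, returned as one tibble row per construct.
#'
#' @inheritParams find_targets
#' @param config A [design_config()].
#' @return Tibble with target coordinates (1-based inclusive), `spacer`,
#'   `dna_cassette`, `transcript`, `mature_crrna`, `mature_len` and the
#'   terminator check columns.
#' @export
design_crrnas <- function(genome, pam = "AAG", config = design_config()) {
  targets <- find_targets(genome, pam = pam, spacer_len = config$spacer_len)
  if (nrow(targets) == 0L) {
    return(mutate(targets,
      dna_cassette = character(), transcript = character(),
      mature_crrna = character(), mature_len = integer(),
      stem_len = integer(), u_tract_len = integer(), terminator_pass = logical()
    ))
  }
  rows <- purrr::map(seq_len(nrow(targets)), function(i) {
    cons <- build_construct(targets[i, ], config)
    term <- check_terminator(cons)
    mutate(targets[i, ],
      dna_cassette = cons$dna_cassette,
      transcript = cons$transcript,
      mature_crrna = cons$mature_crrna,
      mature_len = nchar(cons$mature_crrna),
      stem_len = term$stem_len,
      u_tract_len = term$u_tract_len,
      terminator_pass = term$pass
    )
  })
  bind_rows(rows)
}

#' Write designed cassettes as FASTA
#'
#' @param designs Tibble from [design_crrnas()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_constructs_fasta <- function(designs, path) {
  nm <- sprintf(
    "%s_%d_%d_%s", designs$genome, designs$start1, designs$end1,
    ifelse(designs$strand == "+", "fwd", "rev")
  )
  write_fasta(setNames(designs$dna_cassette, nm), path)
}
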