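#' Read a FASTQ file into a tibble of reads
#'
#' Parses a Sanger/Phred+33 FASTQ file (one record per four lines) into a
#' tibble with one row per read. Quality strings are kept in their encoded
#' form; use [phred_ints()] to decode them.
#'
#' @param path Path to an existing FASTQ file.
#' @return A tibble with columns `read_id` (text before the first whitespace
#'   of the `@` header), `bases` (uppercase DNA over `A,C,G,T,N`) and
#'   `quals` (Phred+33 encoded string, same length as `bases`).
#' @details A record whose quality string length differs from its sequence
#'   length, or a file whose line count is not a multiple of four, raises an
#'   error naming the offending record. Quality autodetection is deliberately
#'   not performed: the encoding is fixed to Phred+33.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), bases = character(), quals = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(paste0("truncated FASTQ: ", length(lines), " lines is not a multiple of 4"))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bases <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  if (any(!startsWith(hdr, "@"))) {
    abort(paste0("malformed FASTQ header at record ", which(!startsWith(hdr, "@"))[1]))
  }
  if (any(!startsWith(plus, "+"))) {
    abort(paste0("malformed FASTQ separator at record ", which(!startsWith(plus, "+"))[1]))
  }
  read_id <- sub("\\s.*$", "", sub("^@", "", hdr))
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad) > 0L) {
    abort(paste0(
      "FASTQ record '", read_id[bad[1]], "': sequence length ",
      nchar(bases[bad[1]]), " != quality length ", nchar(quals[bad[1]])
    ))
  }
  badc <- grepl("[^ACGTN]", bases)
  if (any(badc)) {
    abort(paste0("FASTQ record '", read_id[which(badc)[1]], "': non-ACGTN base"))
  }
  tibble(read_id = read_id, bases = bases, quals = quals)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: emits four lines per record with Phred+33
#' qualities. Round-trips written by this function re-read byte-identically.
#'
#' @param reads Tibble with columns `read_id`, `bases`, `quals`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "bases", "quals") %in% names(reads)))
  if (any(nchar(reads$bases) != nchar(reads$quals))) {
    abort("bases and quals must have equal lengths in every record")
  }
  out <- character(4L * nrow(reads))
  if (nrow(reads) > 0L) {
    out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
    out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$bases
    out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quals
  }
  writeLines(out, path)
  invisible(path)
}

#' Decode or encode Phred+33 quality strings
#'
#' @param quals Character vector of Phred+33 strings.
#' @param scores List (or single vector) of integer Phred scores in `[0, 60]`.
#' @return `phred_ints()`: a list of integer vectors. `phred_chars()`: a
#'   character vector of encoded strings.
#' @export
phred_ints <- function(quals) {
  lapply(quals, function(q) if (nchar(q) == 0L) integer(0) else utf8ToInt(q) - 33L)
}

#' @rdname phred_ints
#' @export
phred_chars <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) {
    if (length(s) == 0L) return("")
    if (any(s < 0L | s > 60L)) abort("Phred scores must lie in [0, 60]")
    intToUtf8(as.integer(s) + 33L)
  }, character(1))
}

#' Mean Phred score per read
#'
#' @param quals Character vector of Phred+33 quality strings.
#' @return Numeric vector of per-read mean scores (`NaN` for empty reads).
#' @export
mean_phred <- function(quals) {
  vapply(phred_ints(quals), function(s) mean(s), numeric(1))
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Tibble with columns `name` (header up to first whitespace) and
#'   `seq` (uppercase sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) > 0L && !hdr[1]) abort("FASTA must start with a '>' header")
  grp <- cumsum(hdr)
  name <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(
    split(lines[!hdr], grp[!hdr]),
    function(x) toupper(paste(x, collapse = "")),
    character(1)
  )
  tibble(name = name, seq = unname(seqs[as.character(seq_along(name))]))
}

#' Write named sequences to FASTA
#'
#' @param x Tibble with columns `name` and `seq`, or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- tibble(name = names(x), seq = unname(x))
  out <- unlist(purrr::map2(x$name, x$seq, function(nm, s) {
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the alphabet `A,C,G,T,N`; `N` maps to
#' `N`. Any other character is an error.
#'
#' @param seq Character vector of DNA strings (may include `""`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) abort("revcomp: sequence contains non-ACGTN characters")
  vapply(chartr("ACGTN", "TGCAN", seq), function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a (possibly circular) named sequence
#'
#' @param seq DNA string over `A,C,G,T` (non-empty).
#' @param name Sequence name.
#' @param circular Logical flag; circular sequences wrap in [circ_slice()]
#'   and in exact mapping.
#' @return An object of class `circ_seq`: a list with fields `name`, `seq`,
#'   `circular` and `length`.
#' @export
circ_seq <- function(seq, name = "seq", circular = TRUE) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) abort("circ_seq: sequence must be non-empty")
  if (grepl("[^ACGT]", seq)) abort("circ_seq: alphabet is restricted to A,C,G,T")
  structure(
    list(name = name, seq = seq, circular = isTRUE(circular), length = nchar(seq)),
    class = "circ_seq"
  )
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(
    "<circ_seq> ", x$name, ": ", x$length, " nt, ",
    if (x$circular) "circular" else "linear", "\n",
    sep = ""
  )
  invisible(x)
}

as_circ_seq <- function(x, circular = TRUE) {
  if (inherits(x, "circ_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(circ_seq(x, circular = circular))
  abort("expected a circ_seq or a single DNA string")
}

#' Extract a slice from a circular (or linear) sequence
#'
#' Uses 0-based start coordinates. On a circular sequence the slice wraps
#' past the end (equivalent to slicing the doubled sequence); on a linear
#' sequence a slice extending past the end is an error.
#'
#' @param ref A [circ_seq()] (or plain DNA string, treated as circular).
#' @param start 0-based start index in `[0, length)`.
#' @param length Slice length, at most the sequence length.
#' @return The DNA substring.
#' @export
circ_slice <- function(ref, start, length) {
  ref <- as_circ_seq(ref)
  n <- ref$length
  if (start < 0 || start >= n) abort("circ_slice: start out of range")
  if (length < 0 || length > n) abort("circ_slice: length out of range")
  if (length == 0L) return("")
  end <- start + length # 0-based exclusive
  if (end <= n) {
    return(substr(ref$seq, start + 1L, end))
  }
  if (!ref$circular) {
    abort("circ_slice: slice runs past the end of a linear sequence")
  }
  paste0(substr(ref$seq, start + 1L, n), substr(ref$seq, 1L, end - n))
}

#' Hamming distance between equal-length DNA strings
#'
#' Counts positions at which the two strings differ. `N` never matches
#' anything, including another `N` (conservative behaviour for spacer
#' calling from base-called reads).
#'
#' @param a,b DNA strings of equal length.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming: strings must have equal length")
  if (nchar(a) == 0L) return(0L)
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  nn <- charToRaw("N")
  sum(ra != rb | ra == nn | rb == nn)
}

# All 0-based start positions in `subject` where `pattern` matches with at
# most `max_mm` mismatches (overlaps included; N is always a mismatch).
# This sliding Hamming scan is the workhorse behind repeat finding, exact
# mapping and PAM scanning.
scan_hamming <- function(subject, pattern, max_mm = 0L) {
  sb <- charToRaw(subject)
  pb <- charToRaw(pattern)
  L <- length(pb)
  n <- length(sb) - L + 1L
  if (n < 1L) return(integer(0))
  nn <- charToRaw("N")
  mm <- integer(n)
  for (i in seq_len(L)) {
    s_i <- sb[i:(i + n - 1L)]
    mm <- mm + (s_i != pb[i] | s_i == nn | pb[i] == nn)
  }
  which(mm <= max_mm) - 1L
}

#' Write genomic hits as BED6
#'
#' Emits a 6-column BED file (0-based, half-open) from a tibble of stranded
#' hits as produced by [map_exact()] or [classify_spacers()]. For a hit on
#' the minus strand, `start0` is the 5' end of the match on that strand, so
#' the BED interval is `[start0 - L + 1, start0 + 1)`. Features wrapping the
#' origin of a circular reference are written with `chromEnd` beyond the
#' sequence length (the usual doubled-origin convention for circular
#' replicons).
#'
#' @param hits Tibble with columns `start0`, `strand` and optionally `name`
#'   and `score`.
#' @param path Output path.
#' @param chrom Reference name used in column 1.
#' @param match_len Feature length in nt.
#' @param ref_len Reference length (used to normalise wrapped starts).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(hits, path, chrom, match_len, ref_len) {
  left <- ifelse(hits$strand == "+", hits$start0, hits$start0 - match_len + 1L)
  left <- ((left %% ref_len) + ref_len) %% ref_len
  nm <- if ("name" %in% names(hits)) hits$name else paste0("hit", seq_len(nrow(hits)))
  sc <- if ("score" %in% names(hits)) hits$score else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, left, left + match_len, nm, sc, hits$strand)
  writeLines(lines, path)
  invisible(path)
}
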