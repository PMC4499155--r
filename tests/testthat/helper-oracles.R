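# Independent oracles used across the suite. These deliberately avoid the
# package's own scanning code paths: per-character loops, doubled-string
# slicing and Biostrings where noted.

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# position-by-position mismatch count; N never matches
brute_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

# all-positions scan + greedy non-overlap post-filter (0-based starts)
brute_repeat_scan <- function(read, rep, max_mm) {
  L <- nchar(rep)
  n <- nchar(read) - L + 1
  cand <- integer(0)
  for (s in seq_len(max(n, 0))) {
    if (brute_hamming(substr(read, s, s + L - 1), rep) <= max_mm) {
      cand <- c(cand, s - 1L)
    }
  }
  sel <- integer(0)
  next_ok <- 0L
  for (s in cand) {
    if (s >= next_ok) {
      sel <- c(sel, s)
      next_ok <- s + L
    }
  }
  sel
}

# exact occurrences on both strands of a circular sequence via substring
# equality on the doubled string; returns tibble(start0, strand) in the
# package's 5'-end convention
brute_map_positions <- function(spacer, seq) {
  n <- nchar(seq)
  L <- nchar(spacer)
  doubled <- paste0(seq, substr(seq, 1, L - 1))
  hits <- list()
  for (s in seq_len(n)) {
    if (substr(doubled, s, s + L - 1) == spacer) {
      hits[[length(hits) + 1]] <- c(s - 1L, 1L)
    }
  }
  rc <- spaceracq::revcomp(spacer)
  for (s in seq_len(n)) {
    if (substr(doubled, s, s + L - 1) == rc) {
      hits[[length(hits) + 1]] <- c((s - 1L + L - 1L) %% n, 2L)
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start0 = integer(), strand = character()))
  }
  m <- do.call(rbind, hits)
  out <- tibble::tibble(start0 = m[, 1], strand = c("+", "-")[m[, 2]])
  dplyr::arrange(out, start0, strand)
}

# exhaustive base-pairing enumeration of the longest hairpin stem with a
# loop of at least min_loop nt
brute_stem <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairs <- c(A = "T", T = "A", C = "G", G = "C")
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      t <- 0
      while (TRUE) {
        a <- i + t
        b <- j - t
        if (b - a - 1 < min_loop) break
        if (pairs[[ch[a]]] != ch[b]) break
        t <- t + 1
      }
      best <- max(best, t)
    }
  }
  best
}

# fabricate a minimal adaptation_report carrying only a usage table
fake_report <- function(counts, starts = seq_along(counts), sample = "fake") {
  structure(
    list(sample = sample, usage = tibble::tibble(
      start0 = as.integer(starts), strand = "+", count = as.integer(counts)
    )),
    class = "adaptation_report"
  )
}

# perfect-quality FASTQ tibble from bare sequences
perfect_reads <- function(bases, prefix = "r") {
  tibble::tibble(
    read_id = paste0(prefix, seq_along(bases)),
    bases = bases,
    quals = vapply(nchar(bases), function(n) strrep("I", n), character(1))
  )
}
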