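#' Repeat model: thresholds for spacer extraction
#'
#' Bundles the parameters of repeat-anchored spacer extraction: the repeat
#' sequence, the mismatch budget for recognising a repeat copy in a read,
#' the exact inter-repeat insert length accepted as a spacer, and the read
#' quality threshold.
#'
#' @param repeat_seq Repeat sequence (default: the 29-nt *E. coli* type I-E
#'   repeat).
#' @param max_mismatches Maximum Hamming distance for a repeat match
#'   (default 2; must be below a quarter of the repeat length).
#' @param spacer_len Exact insert length emitted as a spacer (default 33).
#' @param min_mean_qual Minimum quality for a read to pass filtering
#'   (default 20, inclusive).
#' @param qual_mode `"mean"` (default): threshold applies to the read's mean
#'   Phred score; `"min"`: every base must reach the threshold.
#' @return A `repeat_model` list.
#' @export
repeat_model <- function(repeat_seq = crispr_repeat_ecoli,
                         max_mismatches = 2L,
                         spacer_len = 33L,
                         min_mean_qual = 20,
                         qual_mode = c("mean", "min")) {
  qual_mode <- match.arg(qual_mode)
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L || max_mismatches >= nchar(repeat_seq) / 4) {
    abort("repeat_model: max_mismatches must satisfy 0 <= mm < repeat length / 4")
  }
  if (spacer_len <= 0L) abort("repeat_model: spacer_len must be positive")
  structure(
    list(
      repeat_seq = toupper(repeat_seq), max_mismatches = max_mismatches,
      spacer_len = as.integer(spacer_len), min_mean_qual = min_mean_qual,
      qual_mode = qual_mode
    ),
    class = "repeat_model"
  )
}

#' Quality-filter reads
#'
#' Keeps reads whose mean Phred score is at least `min_mean_qual`
#' (inclusive); order is preserved. With `qual_mode = "min"` the threshold
#' applies to every base instead.
#'
#' @param reads Tibble from [read_fastq()].
#' @param model A [repeat_model()].
#' @return The filtered tibble.
#' @export
filter_quality <- function(reads, model = repeat_model()) {
  if (nrow(reads) == 0L) return(reads)
  keep <- switch(model$qual_mode,
    mean = mean_phred(reads$quals) >= model$min_mean_qual,
    min = vapply(
      phred_ints(reads$quals),
      function(s) length(s) > 0L && min(s) >= model$min_mean_qual, logical(1)
    )
  )
  reads[keep, , drop = FALSE]
}

#' Find repeat copies in a read
#'
#' Scans the read left to right for occurrences of the repeat with Hamming
#' distance at most `max_mismatches` (`N` never matches). Matching is
#' greedy and non-overlapping: after accepting a match at `s`, scanning
#' resumes at `s + repeat length`, so when two candidate matches overlap
#' the leftmost wins.
#'
#' @param bases A read sequence (or a `ReadRecord`-style one-row tibble).
#' @param model A [repeat_model()].
#' @return Sorted integer vector of 0-based match starts.
#' @export
find_repeats <- function(bases, model = repeat_model()) {
  if (is.data.frame(bases)) bases <- bases$bases[[1]]
  cand <- scan_hamming(bases, model$repeat_seq, model$max_mismatches)
  rlen <- nchar(model$repeat_seq)
  sel <- integer(0)
  next_ok <- 0L
  for (s in cand) {
    if (s >= next_ok) {
      sel <- c(sel, s)
      next_ok <- s + rlen
    }
  }
  sel
}

#' Extract fixed-length spacers between consecutive repeat matches
#'
#' For each consecutive pair of repeat matches, the inter-repeat gap is
#' emitted as a spacer call iff its length equals `spacer_len` exactly.
#' Reads with fewer than two matches yield nothing; other gap lengths are
#' silently dropped.
#'
#' @param bases Read sequence.
#' @param starts Sorted, non-overlapping 0-based repeat match starts from
#'   [find_repeats()].
#' @param model A [repeat_model()].
#' @param read_id Read identifier carried into the calls.
#' @return Tibble with columns `read_id`, `insert_index` (0 =
#'   leader-proximal gap), `spacer`, `repeat1_start`, `repeat2_start`
#'   (0-based).
#' @export
extract_spacers <- function(bases, starts, model = repeat_model(), read_id = "read") {
  core <- extract_core(bases, starts, model, read_id)
  if (is.null(core)) {
    return(tibble(
      read_id = character(), insert_index = integer(), spacer = character(),
      repeat1_start = integer(), repeat2_start = integer()
    ))
  }
  as_tibble(core)
}

# plain-list fast path shared with call_spacers (no tibble per read)
extract_core <- function(bases, starts, model, read_id) {
  if (length(starts) < 2L) return(NULL)
  rlen <- nchar(model$repeat_seq)
  s1 <- starts[-length(starts)]
  s2 <- starts[-1]
  ok <- (s2 - (s1 + rlen)) == model$spacer_len
  if (!any(ok)) return(NULL)
  list(
    read_id = rep(read_id, sum(ok)),
    insert_index = which(ok) - 1L,
    spacer = substring(bases, s1[ok] + rlen + 1L, s2[ok]),
    repeat1_start = s1[ok],
    repeat2_start = s2[ok]
  )
}

#' Call spacers from a FASTQ sample
#'
#' Full read-to-spacer extraction: quality filtering, two-repeat detection
#' with the mismatch budget, and extraction of inserts of exactly
#' `spacer_len` nt between consecutive repeat copies.
#'
#' @param reads A FASTQ path or a reads tibble from [read_fastq()].
#' @param model A [repeat_model()].
#' @param strict_two_repeats If `TRUE`, only reads with exactly two repeat
#'   matches yield calls; by default reads with more matches yield one call
#'   per qualifying gap.
#' @return A `spacer_calls` object: list with `calls` (tibble as in
#'   [extract_spacers()]) and `qc` (one-row tibble: `n_reads`,
#'   `n_pass_qual`, `n_two_repeats`, `n_calls`). `tidy()` returns the
#'   calls, `glance()` the QC row.
#' @export
call_spacers <- function(reads, model = repeat_model(), strict_two_repeats = FALSE) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n_reads <- nrow(reads)
  passed <- filter_quality(reads, model)
  starts <- lapply(passed$bases, find_repeats, model = model)
  n_two <- sum(lengths(starts) >= 2L)
  usable <- if (strict_two_repeats) lengths(starts) == 2L else lengths(starts) >= 2L
  idx <- which(usable)
  cores <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    cores[[j]] <- extract_core(passed$bases[i], starts[[i]], model, passed$read_id[i])
  }
  cores <- cores[!vapply(cores, is.null, logical(1))]
  calls <- if (length(cores) > 0L) {
    tibble(
      read_id = unlist(lapply(cores, `[[`, "read_id")),
      insert_index = unlist(lapply(cores, `[[`, "insert_index")),
      spacer = unlist(lapply(cores, `[[`, "spacer")),
      repeat1_start = unlist(lapply(cores, `[[`, "repeat1_start")),
      repeat2_start = unlist(lapply(cores, `[[`, "repeat2_start"))
    )
  } else {
    extract_spacers("", integer(0), model)
  }
  structure(
    list(
      calls = calls,
      qc = tibble(
        n_reads = n_reads, n_pass_qual = nrow(passed),
        n_two_repeats = n_two, n_calls = nrow(calls)
      ),
      model = model
    ),
    class = "spacer_calls"
  )
}

#' @export
print.spacer_calls <- function(x, ...) {
  cat("<spacer_calls>\n")
  cat(
    "  reads:", x$qc$n_reads, "| pass quality:", x$qc$n_pass_qual,
    "| >=2 repeats:", x$qc$n_two_repeats, "| calls:", x$qc$n_calls, "\n"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spacer_calls <- function(x, ...) x$calls

#' @exportS3Method generics::glance
glance.spacer_calls <- function(x, ...) x$qc
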