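#' Generate a synthetic circular donor plasmid with a priming protospacer
#'
#' Draws a uniform-random circular sequence and designates one locus as the
#' priming protospacer, forcing the trinucleotide immediately 5' of it (on
#' its strand) to `AAG` so that the priming locus always carries a
#' functional PAM. The strand bearing the priming protospacer is the strand
#' displaced in the R-loop during target recognition, and therefore the
#' preferred spacer donor during primed acquisition.
#'
#' @param length Plasmid length in nt (at least 500).
#' @param seed Integer seed; the same seed always yields the same plasmid.
#'   The seed is retained on the object and also anchors the per-locus
#'   hotspot weights used by [simulate_acquisitions()].
#' @param priming_spacer_len Length of the priming protospacer.
#' @param name Plasmid name.
#' @return A `plasmid_ref` (also a [circ_seq()]) with fields
#'   `priming_start0`, `priming_len`, `priming_strand` and `seed`.
#' @export
make_plasmid <- function(length = 3000L, seed = 1L, priming_spacer_len = 33L,
                         name = "synthetic_plasmid") {
  length <- as.integer(length)
  if (length < 500L) abort("make_plasmid: length must be >= 500")
  if (priming_spacer_len + 3L > length) abort("make_plasmid: plasmid too short for protospacer + PAM")
  dat <- with_seed(as.integer(seed), {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    start0 <- sample.int(length, 1L) - 1L
    list(bases = bases, start0 = start0)
  })
  bases <- dat$bases
  pam_pos <- mod_pos(dat$start0 - 3:1, length) + 1L # 1-based positions of A,A,G
  bases[pam_pos] <- c("A", "A", "G")
  p <- circ_seq(paste(bases, collapse = ""), name = name, circular = TRUE)
  p$priming_start0 <- dat$start0
  p$priming_len <- as.integer(priming_spacer_len)
  p$priming_strand <- "+"
  p$seed <- as.integer(seed)
  class(p) <- c("plasmid_ref", class(p))
  p
}

#' @export
print.plasmid_ref <- function(x, ...) {
  cat(
    "<plasmid_ref> ", x$name, ": ", x$length, " nt circular; priming protospacer ",
    x$priming_start0, "..", x$priming_start0 + x$priming_len - 1L,
    " (0-based, ", x$priming_strand, " strand, AAG PAM)\n",
    sep = ""
  )
  invisible(x)
}

# Deterministic per-locus log-normal hotspot weights for the AAG loci of a
# plasmid. Anchored to the plasmid's own seed so that two simulations on the
# same plasmid share hotspots regardless of their sampling seeds.
hotspot_weights <- function(plasmid, loci, dispersion) {
  anchor <- (plasmid$seed %||% (sum(utf8ToInt(plasmid$seq)) %% 1000003L)) + 424243L
  with_seed(as.integer(anchor), rlnorm(nrow(loci), meanlog = 0, sdlog = dispersion))
}

#' Simulate spacer-acquisition events on a donor plasmid
#'
#' Draws `n_events` acquisition events under the sampling scheme: (1) the
#' source strand is the displaced strand with probability `strand_bias`;
#' (2) with probability `p_aag_recognition` the event recognises an AAG-PAM
#' protospacer on that strand, drawn with fixed log-normal hotspot weights,
#' otherwise a uniform non-AAG locus; (3) an AAG recognition is emitted as a
#' derived spacer with probability `p_derived` — inverted (reverse
#' complement of the protospacer) with probability
#' `p_invert_given_derived`, else shifted by `k` uniform on
#' +/-1..+/-`shift_window` along the same strand — and otherwise emitted
#' exactly. Non-AAG recognitions are always emitted exactly.
#'
#' Hotspot weights are a fixed property of the plasmid (drawn once from the
#' plasmid seed), so replicate simulations with different `seed`s share the
#' same per-protospacer usage landscape.
#'
#' @param plasmid A [make_plasmid()] object (needs a priming annotation).
#' @param profile A [sample_profile()].
#' @param spacer_len Emitted spacer length.
#' @return A tibble of truth events: `event_id`, `source_start0`,
#'   `source_strand`, `emission_class` (`direct`, `shifted`, `inverted`,
#'   `non_aag`), `shift_k` (`NA` unless shifted) and `spacer`.
#' @export
simulate_acquisitions <- function(plasmid, profile, spacer_len = 33L) {
  stopifnot(inherits(plasmid, "plasmid_ref"))
  n <- profile$n_events
  nlen <- plasmid$length
  aag <- pam_loci(plasmid, "AAG")
  if (!all(c("+", "-") %in% aag$strand)) {
    abort("simulate_acquisitions: plasmid lacks AAG loci on one strand")
  }
  aag$weight <- hotspot_weights(plasmid, aag, profile$hotspot_dispersion)
  displaced <- plasmid$priming_strand
  target <- if (displaced == "+") "-" else "+"
  # non-AAG starts per strand
  non_aag_starts <- lapply(c(`+` = "+", `-` = "-"), function(s) {
    setdiff(0:(nlen - 1L), aag$start0[aag$strand == s])
  })

  ev <- with_seed(profile$seed, {
    strand <- ifelse(runif(n) < profile$strand_bias, displaced, target)
    is_aag <- runif(n) < profile$p_aag_recognition
    u_derived <- runif(n)
    u_invert <- runif(n)
    kdraw <- sample(c(-(profile$shift_window:1), 1:profile$shift_window), n, replace = TRUE)
    start0 <- integer(n)
    for (s in c("+", "-")) {
      on_s <- strand == s
      idx_aag <- which(on_s & is_aag)
      pool <- which(aag$strand == s)
      if (length(idx_aag) > 0L) {
        start0[idx_aag] <- aag$start0[sample(pool, length(idx_aag),
          replace = TRUE, prob = aag$weight[pool]
        )]
      }
      idx_non <- which(on_s & !is_aag)
      if (length(idx_non) > 0L) {
        start0[idx_non] <- sample(non_aag_starts[[s]], length(idx_non), replace = TRUE)
      }
    }
    list(
      strand = strand, is_aag = is_aag, start0 = start0,
      u_derived = u_derived, u_invert = u_invert, kdraw = kdraw
    )
  })

  derived <- ev$is_aag & ev$u_derived < profile$p_derived
  inverted <- derived & ev$u_invert < profile$p_invert_given_derived
  shifted <- derived & !inverted
  class <- rep("direct", n)
  class[!ev$is_aag] <- "non_aag"
  class[shifted] <- "shifted"
  class[inverted] <- "inverted"
  shift_k <- ifelse(shifted, ev$kdraw, NA_integer_)

  emit_start <- ifelse(shifted, shift_by(ev$start0, ev$strand, ev$kdraw, nlen), ev$start0)
  spacer <- proto_seq(plasmid, emit_start, ev$strand, spacer_len)
  spacer[inverted] <- revcomp(spacer[inverted])

  tibble(
    event_id = seq_len(n),
    source_start0 = ev$start0,
    source_strand = ev$strand,
    emission_class = class,
    shift_k = as.integer(shift_k),
    spacer = spacer
  )
}

#' Amplicon array context for read rendering
#'
#' Describes the fixed part of an expanded-array amplicon: the leader, the
#' repeat, the first pre-existing spacer and the downstream tail. A rendered
#' read is `leader + repeat + new spacer + repeat + preexisting spacer +
#' tail`, mirroring PCR products from the leader-proximal end of an array
#' that gained a single spacer.
#'
#' @param leader,tail Non-empty flanking sequences.
#' @param repeat_seq Repeat sequence (>= 20 nt).
#' @param preexisting_spacers Character vector of pre-existing spacers; the
#'   first is included in rendered reads.
#' @return An `array_model` list.
#' @export
array_model <- function(leader = default_leader,
                        repeat_seq = crispr_repeat_ecoli,
                        preexisting_spacers = default_preexisting_spacer,
                        tail = default_tail) {
  if (nchar(repeat_seq) < 20L) abort("array_model: repeat must be >= 20 nt")
  if (nchar(leader) == 0L || nchar(tail) == 0L) abort("array_model: leader and tail must be non-empty")
  if (length(preexisting_spacers) < 1L) abort("array_model: need at least one pre-existing spacer")
  structure(
    list(
      leader = toupper(leader), repeat_seq = toupper(repeat_seq),
      preexisting_spacers = toupper(preexisting_spacers), tail = toupper(tail)
    ),
    class = "array_model"
  )
}

#' Render truth events as expanded-array amplicon reads
#'
#' Produces one read per event with the structure `leader + repeat + spacer
#' + repeat + first pre-existing spacer + tail`, applies uniform per-base
#' substitution errors at `profile$error_rate`, and draws Phred qualities
#' such that a fraction `pass_fraction` of reads passes the default mean
#' quality filter (passing reads draw per-base scores in 30..40, failing
#' reads in 5..15). Rendering is deterministic given the profile seed.
#'
#' @param events Truth tibble from [simulate_acquisitions()].
#' @param array An [array_model()].
#' @param profile The [sample_profile()] used for the simulation.
#' @param pass_fraction Fraction of reads rendered with filter-passing
#'   qualities.
#' @return A list with `reads` (tibble: `read_id`, `bases`, `quals`) and
#'   `truth` (the events tibble with a `read_id` column prepended).
#' @export
render_reads <- function(events, array = array_model(), profile, pass_fraction = 1) {
  if (nrow(events) == 0L) abort("render_reads: events must be non-empty")
  n <- nrow(events)
  read_id <- sprintf("%s_read_%06d", profile$name, events$event_id)
  bases <- paste0(
    array$leader, array$repeat_seq, events$spacer, array$repeat_seq,
    array$preexisting_spacers[1], array$tail
  )
  lens <- nchar(bases)
  rendered <- with_seed(profile$seed + 500009L, {
    if (profile$error_rate > 0) {
      n_err <- rbinom(n, lens, profile$error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(lens[i], n_err[i])
        ch <- strsplit(bases[i], "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(
          ch[pos],
          function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
          character(1)
        )
        bases[i] <- paste(ch, collapse = "")
      }
    }
    pass <- runif(n) < pass_fraction
    quals <- character(n)
    for (grp in list(which(pass), which(!pass))) {
      if (length(grp) == 0L) next
      rng <- if (identical(grp, which(pass))) 30:40 else 5:15
      total <- sum(lens[grp])
      draws <- sample(rng, total, replace = TRUE)
      stops <- cumsum(lens[grp])
      starts <- c(1L, utils::head(stops, -1L) + 1L)
      quals[grp] <- vapply(
        seq_along(grp),
        function(j) intToUtf8(draws[starts[j]:stops[j]] + 33L),
        character(1)
      )
    }
    list(bases = bases, quals = quals)
  })
  list(
    reads = tibble(read_id = read_id, bases = rendered$bases, quals = rendered$quals),
    truth = dplyr::bind_cols(tibble(read_id = read_id), events)
  )
}

#' Simulate a complete sample: plasmid events rendered as reads
#'
#' Convenience wrapper chaining [simulate_acquisitions()] and
#' [render_reads()].
#'
#' @inheritParams simulate_acquisitions
#' @inheritParams render_reads
#' @return A list with `reads`, `truth`, `plasmid` and `profile`.
#' @export
simulate_sample <- function(plasmid, profile, array = array_model(),
                            spacer_len = 33L, pass_fraction = 1) {
  events <- simulate_acquisitions(plasmid, profile, spacer_len = spacer_len)
  r <- render_reads(events, array, profile, pass_fraction = pass_fraction)
  list(reads = r$reads, truth = r$truth, plasmid = plasmid, profile = profile)
}

#' Write a simulated sample's outputs to disk
#'
#' Writes the reads as FASTQ, the truth table as TSV and the plasmid as
#' FASTA next to each other.
#'
#' @param sim Result of [simulate_sample()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sample <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, paste0(sim$profile$name, ".fastq")))
  utils::write.table(
    sim$truth, file.path(dir, paste0(sim$profile$name, "_truth.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_fasta(
    setNames(sim$plasmid$seq, sim$plasmid$name),
    file.path(dir, paste0(sim$plasmid$name, ".fasta"))
  )
  invisible(dir)
}
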