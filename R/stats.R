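#' Summarise classified spacers into a per-sample adaptation report
#'
#' Computes the Figure-style per-sample statistics over classified calls.
#' Unmapped calls count toward `n_calls` but are excluded from every other
#' denominator, matching the convention of reporting statistics only for
#' spacers derived from the priming-protospacer plasmid.
#'
#' * `pam_preference_raw`: fraction of mapped calls labelled `direct_aag`.
#' * `pam_preference_reclassified`: fraction labelled `direct_aag`,
#'   `shifted` or `inverted` — i.e. derived spacers credited to their
#'   AAG-PAM parent protospacers.
#' * `derived_fraction`: fraction labelled `shifted` or `inverted`; by
#'   construction of the label partition, `reclassified - raw ==
#'   derived_fraction` exactly.
#' * `strand_bias`: fraction of mapped calls whose source strand (parent
#'   strand for derived spacers) is the displaced strand.
#' * `usage`: per-locus counts keyed on `(start0, strand)` of the source
#'   protospacer; derived spacers credit their parent locus, so
#'   `sum(usage$count) == n_mapped`.
#'
#' With no mapped calls all fractions are `NA`, never 0.
#'
#' @param classified Tibble from [classify_spacers()].
#' @param sample Sample name carried into the report.
#' @return An `adaptation_report` object. `glance()` returns the scalar
#'   statistics as one row; `tidy()` returns the usage table;
#'   `autoplot()` draws the per-locus usage track.
#' @export
summarize_adaptation <- function(classified, sample = "sample") {
  n_calls <- nrow(classified)
  m <- classified[!is.na(classified$mapped) & classified$mapped, , drop = FALSE]
  n_mapped <- nrow(m)
  frac <- function(x) if (n_mapped == 0L) NA_real_ else sum(x) / n_mapped
  usage <- if (n_mapped == 0L) {
    tibble(start0 = integer(), strand = character(), count = integer())
  } else {
    m %>%
      count(start0 = .data$parent_start0, strand = .data$parent_strand, name = "count") %>%
      arrange(.data$start0, .data$strand)
  }
  structure(
    list(
      sample = sample,
      n_calls = n_calls,
      n_mapped = n_mapped,
      pam_preference_raw = frac(m$label == "direct_aag"),
      pam_preference_reclassified = frac(m$label %in% c("direct_aag", "shifted", "inverted")),
      derived_fraction = frac(m$label %in% c("shifted", "inverted")),
      strand_bias = frac(m$strand_class == "displaced"),
      n_ambiguous = if (n_mapped == 0L) 0L else sum(m$ambiguous),
      usage = usage
    ),
    class = "adaptation_report"
  )
}

#' @export
print.adaptation_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("<adaptation_report> ", x$sample, "\n", sep = "")
  cat("  calls: ", x$n_calls, " (mapped: ", x$n_mapped, ", ambiguous: ", x$n_ambiguous, ")\n", sep = "")
  cat("  AAG PAM preference: raw ", pct(x$pam_preference_raw),
    ", reclassified ", pct(x$pam_preference_reclassified), "\n",
    sep = ""
  )
  cat("  derived spacers: ", pct(x$derived_fraction),
    " | displaced-strand bias: ", pct(x$strand_bias), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::glance
glance.adaptation_report <- function(x, ...) {
  tibble(
    sample = x$sample, n_calls = x$n_calls, n_mapped = x$n_mapped,
    pam_preference_raw = x$pam_preference_raw,
    pam_preference_reclassified = x$pam_preference_reclassified,
    derived_fraction = x$derived_fraction,
    strand_bias = x$strand_bias,
    n_ambiguous = x$n_ambiguous
  )
}

#' @exportS3Method generics::tidy
tidy.adaptation_report <- function(x, ...) {
  mutate(x$usage, sample = x$sample, .before = 1L)
}

#' Usage track plot for an adaptation report
#'
#' Bar heights give how often a spacer arising from a protospacer at each
#' position was observed; strands are drawn above (displaced donor loci on
#' `+`) and below (`-`) the axis, the tabular analogue of a circular usage
#' map.
#'
#' @param object An `adaptation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.adaptation_report <- function(object, ...) {
  u <- mutate(object$usage,
    signed = ifelse(.data$strand == "+", .data$count, -.data$count)
  )
  ggplot2::ggplot(u, ggplot2::aes(x = .data$start0, y = .data$signed, fill = .data$strand)) +
    ggplot2::geom_col(width = 3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "protospacer 5' position (0-based)",
      y = "spacer count (+ strand up, - strand down)",
      title = paste0("Protospacer usage: ", object$sample),
      fill = "strand"
    ) +
    ggplot2::theme_minimal()
}

#' Pearson correlation of per-protospacer usage between two samples
#'
#' Aligns the two usage tables on the union of loci (absent locus = 0) and
#' returns the Pearson product-moment correlation of the counts. Undefined
#' (zero variance in either vector, or no loci) correlations are returned
#' as `NA`.
#'
#' @param a,b `adaptation_report` objects.
#' @return A single numeric correlation in `[-1, 1]`, or `NA`.
#' @export
usage_correlation <- function(a, b) {
  u <- full_join(
    rename(a$usage, count_a = "count"),
    rename(b$usage, count_b = "count"),
    by = c("start0", "strand")
  ) %>%
    mutate(
      count_a = tidyr::replace_na(.data$count_a, 0L),
      count_b = tidyr::replace_na(.data$count_b, 0L)
    )
  if (nrow(u) < 2L) return(NA_real_)
  if (stats::sd(u$count_a) == 0 || stats::sd(u$count_b) == 0) return(NA_real_)
  cor(u$count_a, u$count_b, method = "pearson")
}

#' Efficiency of plaquing (EOP)
#'
#' Ratio of plaque counts on the tested lawn to those on the sensitive
#' (non-targeting) control lawn. When no plaques form on the tested lawn
#' the EOP is 0 and the result carries a `detection_limit` attribute equal
#' to `1 / plaques_control` (the value is a `< 1/control` upper bound).
#'
#' @param plaques_test,plaques_control Non-negative plaque counts; the
#'   control must be positive.
#' @return Numeric ratio.
#' @export
eop <- function(plaques_test, plaques_control) {
  if (plaques_control <= 0) abort("eop: control plaque count must be positive")
  out <- plaques_test / plaques_control
  if (plaques_test == 0) attr(out, "detection_limit") <- 1 / plaques_control
  out
}

#' Efficiency of transformation (EOT) and fold change
#'
#' `eot()` is transformant colonies per microgram of plasmid DNA;
#' `fold_change()` is the ratio of two efficiencies (e.g. protospacer
#' plasmid over empty vector).
#'
#' @param colonies Non-negative colony count.
#' @param dna_micrograms Positive DNA mass in micrograms.
#' @return Colonies per microgram.
#' @export
eot <- function(colonies, dna_micrograms) {
  if (dna_micrograms <= 0) abort("eot: DNA mass must be positive")
  colonies / dna_micrograms
}

#' @rdname eot
#' @param x,reference Two efficiencies; `reference` must be positive.
#' @export
fold_change <- function(x, reference) {
  if (reference <= 0) abort("fold_change: reference must be positive")
  x / reference
}
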