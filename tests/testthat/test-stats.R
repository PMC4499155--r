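# minimal classified tibble builder for hand-counted summaries
classified_row <- function(label, strand_class = "displaced", parent = 10L) {
  tibble::tibble(
    read_id = paste0("r", sample.int(1e6, 1)), spacer = "X", mapped = TRUE,
    start0 = parent, strand = "+", pam = "AAG", label = label,
    shift_k = NA_integer_, parent_start0 = parent, parent_strand = "+",
    ambiguous = FALSE, strand_class = strand_class
  )
}

test_that("summarize_adaptation computes the hand-counted fractions", {
  withr::with_seed(70, {
    calls <- dplyr::bind_rows(
      lapply(rep("direct_aag", 6), classified_row),
      lapply(rep("shifted", 2), classified_row),
      lapply("inverted", classified_row),
      lapply("non_aag", classified_row)
    )
  })
  r <- summarize_adaptation(calls, "hand")
  expect_equal(r$n_calls, 10L)
  expect_equal(r$n_mapped, 10L)
  expect_equal(r$pam_preference_raw, 0.6)
  expect_equal(r$pam_preference_reclassified, 0.9)
  expect_equal(r$derived_fraction, 0.3)
})

test_that("all-direct displaced calls give unit fractions and zero derived", {
  withr::with_seed(71, calls <- dplyr::bind_rows(lapply(rep("direct_aag", 5), classified_row)))
  r <- summarize_adaptation(calls)
  expect_equal(r$pam_preference_raw, 1)
  expect_equal(r$pam_preference_reclassified, 1)
  expect_equal(r$derived_fraction, 0)
  expect_equal(r$strand_bias, 1)
})

test_that("an empty call list reports NA fractions, never 0", {
  r <- summarize_adaptation(classified_row("direct_aag")[0, ], "empty")
  expect_equal(r$n_calls, 0L)
  expect_true(is.na(r$pam_preference_raw))
  expect_true(is.na(r$strand_bias))
  expect_true(is.na(r$derived_fraction))
})

test_that("reclassified - raw equals the derived fraction exactly, and usage sums to n_mapped", {
  p <- make_plasmid(2500, seed = 12)
  prof <- sample_profile(name = "ident", n_events = 1500, p_derived = 0.07, seed = 29)
  sim <- simulate_sample(p, prof)
  cl <- classify_spacers(call_spacers(sim$reads), p)
  r <- summarize_adaptation(cl, "ident")
  expect_equal(
    r$pam_preference_reclassified - r$pam_preference_raw,
    r$derived_fraction,
    tolerance = 1e-12
  )
  # the identity is exact at the count level by the label partition
  m <- dplyr::filter(cl, mapped)
  expect_identical(
    sum(m$label %in% c("direct_aag", "shifted", "inverted")) - sum(m$label == "direct_aag"),
    sum(m$label %in% c("shifted", "inverted"))
  )
  expect_equal(sum(r$usage$count), r$n_mapped)
  expect_gte(r$pam_preference_reclassified, r$pam_preference_raw)
})

test_that("usage_correlation matches the closed-form Pearson formula", {
  expect_equal(usage_correlation(fake_report(c(1, 2, 3)), fake_report(c(1, 2, 3))), 1)
  expect_equal(usage_correlation(fake_report(c(1, 2, 3)), fake_report(c(3, 2, 1))), -1)
  # hand calculation for (1,2,4) vs (2,2,5): r = 5 / (2 * sqrt(7))
  expect_equal(
    usage_correlation(fake_report(c(1, 2, 4)), fake_report(c(2, 2, 5))),
    5 / (2 * sqrt(7))
  )
  a <- fake_report(c(4, 1, 2))
  b <- fake_report(c(2, 2, 5))
  expect_equal(usage_correlation(a, b), usage_correlation(b, a))
  expect_true(is.na(usage_correlation(fake_report(c(2, 2, 2)), fake_report(c(1, 2, 3)))))
  # disjoint loci still align on the union
  d1 <- fake_report(c(3, 1), starts = c(1, 2))
  d2 <- fake_report(c(2, 2), starts = c(2, 3))
  expect_true(abs(usage_correlation(d1, d2)) <= 1)
})

test_that("EOP is the plaque-count ratio with a detection limit at zero", {
  expect_equal(eop(100, 100), 1)
  expect_equal(eop(1, 10000), 1e-4)
  z <- eop(0, 10000)
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "detection_limit"), 1e-4)
  expect_error(eop(5, 0), "positive")
})

test_that("EOT is colonies per microgram and fold change is a plain ratio", {
  expect_equal(eot(500, 0.01), 5e4)
  expect_equal(eot(0, 0.01), 0)
  expect_error(eot(10, 0), "positive")
  # 100-fold interference fixture: protospacer plasmid vs empty vector
  expect_equal(fold_change(eot(50, 0.01), eot(5000, 0.01)), 0.01)
})

test_that("report accessors expose scalars and usage tidily", {
  withr::with_seed(72, calls <- dplyr::bind_rows(
    lapply(rep("direct_aag", 3), classified_row),
    lapply("shifted", classified_row)
  ))
  r <- summarize_adaptation(calls, "acc")
  g <- glance(r)
  expect_equal(nrow(g), 1L)
  expect_equal(g$derived_fraction, 0.25)
  td <- tidy(r)
  expect_true(all(c("sample", "start0", "strand", "count") %in% names(td)))
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("adaptation reports survive a JSON round trip", {
  withr::with_seed(73, calls <- dplyr::bind_rows(
    lapply(rep("direct_aag", 4), classified_row),
    lapply("inverted", classified_row)
  ))
  r <- summarize_adaptation(calls, "json")
  f <- withr::local_tempfile(fileext = ".json")
  write_report(r, f)
  r2 <- read_report(f)
  expect_equal(r2$pam_preference_raw, r$pam_preference_raw)
  expect_equal(r2$derived_fraction, r$derived_fraction)
  expect_equal(as.data.frame(r2$usage), as.data.frame(r$usage))
})
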