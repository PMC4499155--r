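#' Write classified spacer calls as TSV
#'
#' Columns follow the classification table of [classify_spacers()]; both
#' the internal 0-based and the 1-based inclusive 5'-end coordinates are
#' included.
#'
#' @param classified Tibble from [classify_spacers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classified <- function(classified, path) {
  utils::write.table(classified, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an adaptation report as JSON
#'
#' Serialises the scalar statistics and the per-locus usage table of an
#' `adaptation_report`. Requires the jsonlite package.
#'
#' @param report An [summarize_adaptation()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_report requires the jsonlite package")
  }
  x <- unclass(report)
  x$usage <- as.data.frame(x$usage)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an adaptation report back from JSON
#'
#' @param path Path written by [write_report()].
#' @return An `adaptation_report`.
#' @export
read_report <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("read_report requires the jsonlite package")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$usage <- as_tibble(as.data.frame(x$usage))
  structure(x, class = "adaptation_report")
}
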